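#' Principal component analysis of pharmacokinetic endpoints
#'
#' Z-scores each endpoint column, eigendecomposes the correlation matrix,
#' and orders the components by decreasing eigenvalue. Loadings are the
#' eigenvectors; the explained-variance percentages are the eigenvalues as
#' a share of their total; scores are the standardized data projected onto
#' the loadings. The sign of each eigenvector is fixed by making its
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param x numeric matrix or data.frame, subjects in rows and endpoints in
#'   columns (>= 3 rows, no constant column).
#' @param ln if `TRUE`, log-transform before z-scoring (requires positive
#'   values).
#' @return an object of class `pca_result`: list with `loadings`
#'   (endpoints x components), `explained_variance_pct`, `scores`
#'   (subjects x components) and `eigenvalues`.
#' @export
#' @examples
#' co <- simulate_cohort(drug_profile("amlodipine"), 200, seed = 3)
#' ep <- nca_endpoint_matrix(co)
#' res <- run_pca(ep)
#' res$explained_variance_pct
run_pca <- function(x, ln = FALSE) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 3)
  if (ln) {
    if (any(x <= 0)) stop("ln = TRUE requires positive values",
                          call. = FALSE)
    x <- log(x)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant endpoint column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  load <- eig$vectors
  # deterministic sign: largest-magnitude loading of each component > 0
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  ev <- pmax(eig$values, 0)
  structure(list(
    loadings = load,
    eigenvalues = ev,
    explained_variance_pct = ev / sum(ev) * 100,
    scores = z %*% load), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", nrow(x$loadings), "endpoints\n")
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = " "),
      "\n")
  invisible(x)
}

#' Angle between two endpoints in the biplot plane
#'
#' Angle (degrees) between the (PC1, PC2) loading vectors of two endpoints.
#' Nearly opposite endpoints (about 180 degrees) vary inversely; nearly
#' perpendicular ones (about 90 degrees) are unrelated in the plane of the
#' two dominant components.
#'
#' @param result a [run_pca()] result with >= 2 components.
#' @param pair character vector of two endpoint names.
#' @return angle in degrees, in `[0, 180]`.
#' @export
loading_angles <- function(result, pair) {
  stopifnot(inherits(result, "pca_result"), length(pair) == 2,
            ncol(result$loadings) >= 2)
  miss <- setdiff(pair, rownames(result$loadings))
  if (length(miss)) {
    stop("unknown endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v1 <- result$loadings[pair[1], 1:2]
  v2 <- result$loadings[pair[2], 1:2]
  if (euclidean_norm(v1) == 0 || euclidean_norm(v2) == 0) {
    stop("zero-length loading vector", call. = FALSE)
  }
  angle_between(v1, v2)$theta_deg
}

#' Endpoint matrix of a single-arm cohort
#'
#' Non-compartmental endpoints (AUC, AUCinf, Cmax, Tmax, AS) for each
#' profile of a [simulate_cohort()] result, as the subjects-by-endpoints
#' matrix PCA expects.
#'
#' @param cohort list with `times` and `conc` as from [simulate_cohort()].
#' @return numeric matrix with columns
#'   `auc, auc_inf, cmax, tmax, as_slope`.
#' @export
nca_endpoint_matrix <- function(cohort) {
  ep <- nca_matrix(cohort$times, cohort$conc)
  if (anyNA(ep$auc_inf)) {
    stop("terminal rate constant could not be estimated for ",
         sum(is.na(ep$auc_inf)), " profile(s); AUCinf incomplete",
         call. = FALSE)
  }
  as.matrix(ep[, c("auc", "auc_inf", "cmax", "tmax", "as_slope")])
}
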