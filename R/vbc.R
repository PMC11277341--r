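#' Standardize an endpoint vector
#'
#' Z-scores the values: subtract the mean, divide by the sample standard
#' deviation (denominator K - 1). Standardization makes endpoints with
#' different units comparable before angles are estimated; it preserves the
#' shape of the distribution.
#'
#' @param values numeric vector, length >= 3, finite, non-constant.
#' @return vector with mean 0 and sample standard deviation 1.
#' @export
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
standardize <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 3) {
    stop("at least 3 values are required to standardize", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) stop("cannot standardize a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Dot product of two endpoint vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sum(a * b)`.
#' @export
dot_product <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  sum(a * b)
}

#' Euclidean norm of an endpoint vector
#'
#' @param a numeric vector.
#' @return `sqrt(sum(a^2))`.
#' @export
euclidean_norm <- function(a) sqrt(sum(a^2))

#' Angle between two endpoint vectors
#'
#' The cosine of the angle is the dot product divided by the product of the
#' Euclidean norms. When `a` and `b` are standardized versions of raw
#' endpoint vectors, this cosine equals the Pearson correlation of the raw
#' values. The cosine is clamped to `[-1, 1]` (tolerance for floating-point
#' overshoot) before the arc cosine, so the angle lies in `[0, 180]` degrees
#' and its sine in `[0, 1]`.
#'
#' @param a,b numeric vectors of equal length with positive norms
#'   (typically standardized endpoint values of one period-by-treatment
#'   cell).
#' @return list with `cos_theta`, `theta_deg`, `sin_theta`.
#' @export
angle_between <- function(a, b) {
  na <- euclidean_norm(a)
  nb <- euclidean_norm(b)
  if (na == 0 || nb == 0) {
    stop("cannot measure an angle to a zero-norm vector", call. = FALSE)
  }
  ct <- min(1, max(-1, dot_product(a, b) / (na * nb)))
  theta <- acos(ct)
  list(cos_theta = ct, theta_deg = theta * 180 / pi, sin_theta = sin(theta))
}

#' Project endpoint values onto the axis perpendicular to the anchor
#'
#' Multiplies each raw value by the sine of the angle between the endpoint
#' and the anchor: `B_y = B * sin(theta)`. Since `sin(theta) <= 1` the
#' projection never inflates a value, and as a positive linear scaling it
#' preserves the shape of the distribution and the ordering of subjects.
#' An endpoint (anti)parallel to the anchor has an empty perpendicular
#' component: a sine below `sin_floor` is an error rather than a
#' near-zero output that would be meaningless downstream.
#'
#' @param values_raw positive raw endpoint values.
#' @param angle an angle as returned by [angle_between()].
#' @param sin_floor degenerate-parallel tolerance (default 1e-6).
#' @return `values_raw * angle$sin_theta`.
#' @export
#' @examples
#' a <- angle_between(standardize(c(1, 2, 4)), standardize(c(5, 1, 3)))
#' decompose(c(10, 12, 9), a)
decompose <- function(values_raw, angle, sin_floor = 1e-6) {
  stopifnot(all(values_raw > 0))
  if (angle$sin_theta < sin_floor) {
    stop("endpoint is (anti)parallel to the anchor (sin theta < ",
         format(sin_floor), "): its perpendicular component is empty",
         call. = FALSE)
  }
  values_raw * angle$sin_theta
}

#' VBC configuration
#'
#' @param anchor endpoint column used as the anchor (E1); default `"auc"`.
#' @param decompose endpoint columns to project onto axes perpendicular to
#'   the anchor; default `c("cmax", "as_slope")`.
#' @param sin_floor degenerate-parallel tolerance passed to [decompose()].
#' @param pooling `"cell"` (default): angles are estimated within each
#'   period-by-treatment cell and each observation is scaled by its own
#'   cell's sine; `"pooled"`: a single angle per endpoint is estimated from
#'   all observations at once (sensitivity analysis).
#' @return an object of class `vbc_config`.
#' @export
vbc_config <- function(anchor = "auc", decompose = c("cmax", "as_slope"),
                       sin_floor = 1e-6, pooling = c("cell", "pooled")) {
  pooling <- match.arg(pooling)
  if (anchor %in% decompose) {
    stop("the anchor endpoint cannot be decomposed against itself",
         call. = FALSE)
  }
  structure(list(anchor = anchor, decompose = decompose,
                 sin_floor = sin_floor, pooling = pooling),
            class = "vbc_config")
}

#' Vector-based comparison transform of an endpoint table
#'
#' For each period-by-treatment cell and each endpoint to be decomposed:
#' standardize the endpoint and the anchor within the cell, estimate the
#' angle between them, and multiply each subject's raw endpoint value in
#' that cell by the cell's `sin(theta)`. The anchor endpoint passes through
#' unchanged. Z-scores are used only to estimate angles; the decomposed
#' values stay on the natural scale of the endpoint so that the downstream
#' log-transformed crossover analysis applies unchanged.
#'
#' @param endpoints an endpoint table from [build_endpoint_table()] (or any
#'   data.frame with `period`, `treatment` and the endpoint columns).
#' @param config a [vbc_config()].
#' @return the input table with one added column per decomposed endpoint,
#'   suffixed `_perp`, plus an `angles` attribute: a data.frame
#'   `endpoint, anchor, period, treatment, cos_theta, theta_deg, sin_theta`
#'   with one row per endpoint and cell.
#' @export
#' @examples
#' p <- drug_profile("irbesartan")
#' d <- trial_design(24, p$schedule)
#' trial <- simulate_trial(d, p$model, p$model, variability_spec(), seed = 1)
#' ep <- build_endpoint_table(trial)
#' dec <- vbc_transform(ep, vbc_config())
#' attr(dec, "angles")
vbc_transform <- function(endpoints, config = vbc_config()) {
  stopifnot(inherits(config, "vbc_config"))
  need <- c(config$anchor, config$decompose)
  miss <- setdiff(need, names(endpoints))
  if (length(miss)) {
    stop("endpoint columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (any(endpoints[[col]] <= 0 | !is.finite(endpoints[[col]]))) {
      stop("endpoint '", col, "' must be positive and finite for the ",
           "vector decomposition", call. = FALSE)
    }
  }
  if (config$pooling == "cell") {
    cells <- unique(endpoints[, c("period", "treatment"), drop = FALSE])
  } else {
    cells <- data.frame(period = NA, treatment = NA)
  }
  out <- endpoints
  angles <- vector("list", nrow(cells) * length(config$decompose))
  k <- 0
  for (ci in seq_len(nrow(cells))) {
    in_cell <- if (config$pooling == "cell") {
      endpoints$period == cells$period[ci] &
        endpoints$treatment == cells$treatment[ci]
    } else rep(TRUE, nrow(endpoints))
    z_anchor <- tryCatch(
      standardize(endpoints[[config$anchor]][in_cell]),
      error = function(e) stop(
        "anchor '", config$anchor, "' in cell (period ", cells$period[ci],
        ", treatment ", cells$treatment[ci], "): ", conditionMessage(e),
        call. = FALSE))
    for (ep in config$decompose) {
      ang <- tryCatch({
        z <- standardize(endpoints[[ep]][in_cell])
        angle_between(z, z_anchor)
      }, error = function(e) stop(
        "endpoint '", ep, "' in cell (period ", cells$period[ci],
        ", treatment ", cells$treatment[ci], "): ", conditionMessage(e),
        call. = FALSE))
      newcol <- paste0(ep, "_perp")
      if (!newcol %in% names(out)) out[[newcol]] <- NA_real_
      out[[newcol]][in_cell] <- tryCatch(
        decompose(endpoints[[ep]][in_cell], ang, config$sin_floor),
        error = function(e) stop(
          "endpoint '", ep, "' in cell (period ", cells$period[ci],
          ", treatment ", cells$treatment[ci], "): ", conditionMessage(e),
          call. = FALSE))
      k <- k + 1
      angles[[k]] <- data.frame(
        endpoint = ep, anchor = config$anchor,
        period = cells$period[ci], treatment = cells$treatment[ci],
        cos_theta = ang$cos_theta, theta_deg = ang$theta_deg,
        sin_theta = ang$sin_theta, stringsAsFactors = FALSE)
    }
  }
  attr(out, "angles") <- do.call(rbind, angles)
  out
}
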