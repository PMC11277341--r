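#' Area under the concentration-time curve to the last quantifiable sample
#'
#' Linear trapezoidal rule over all consecutive intervals from the first
#' sample up to the last sample with a positive concentration.
#'
#' @param times strictly increasing sampling times (h).
#' @param concs concentrations (>= 0), same length as `times`.
#' @return area (concentration x h).
#' @export
#' @examples
#' auc_last(c(0, 1, 2), c(0, 10, 5))  # 12.5
auc_last <- function(times, concs) {
  check_profile(times, concs)
  if (length(times) < 2) stop("at least 2 samples are required", call. = FALSE)
  last <- last_positive(concs)
  if (last < 2) return(0)
  idx <- seq_len(last)
  sum(diff(times[idx]) * (concs[idx][-1] + concs[idx][-last]) / 2)
}

last_positive <- function(concs) {
  pos <- which(concs > 0)
  if (length(pos) == 0) 0L else max(pos)
}

check_profile <- function(times, concs) {
  stopifnot(length(times) == length(concs))
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression of the terminal concentrations on time. Candidate
#' points are those strictly after Tmax with positive concentration (zeros
#' are excluded since their logarithm is undefined, and the Tmax point is
#' never included). Starting from the last three candidate points, earlier
#' points are added one at a time while the adjusted R-squared does not
#' decrease. The fit with the best adjusted R-squared under this rule is
#' returned.
#'
#' @param times,concs the profile.
#' @return list with `lambda_z` (1/h; `NA` when fewer than three usable
#'   points remain or the fitted slope is non-negative), `n_points`, and
#'   `adj_r_squared`.
#' @export
lambda_z <- function(times, concs) {
  check_profile(times, concs)
  imax <- which.max(concs)
  usable <- which(seq_along(concs) > imax & concs > 0)
  k <- length(usable)
  if (k < 3) {
    return(list(lambda_z = NA_real_, n_points = 0L,
                adj_r_squared = NA_real_))
  }
  x <- times[usable]
  y <- log(concs[usable])
  best <- NULL
  for (np in 3:k) {
    idx <- (k - np + 1):k
    fit <- loglin_fit(x[idx], y[idx])
    if (!is.null(best) && fit$adj_r2 < best$adj_r2 - 1e-12) break
    best <- c(fit, n = np)
  }
  if (best$slope >= 0) {
    return(list(lambda_z = NA_real_, n_points = as.integer(best$n),
                adj_r_squared = best$adj_r2))
  }
  list(lambda_z = -best$slope, n_points = as.integer(best$n),
       adj_r_squared = best$adj_r2)
}

# least-squares line through (x, y) with adjusted R^2; small-n hand
# formulas to keep the per-profile cost low in Monte Carlo runs
loglin_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  res <- y - my - slope * (x - mx)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = slope, adj_r2 = adj)
}

#' Extrapolate the AUC to infinite time
#'
#' `auc + clast/lambda_z`, using the observed last positive concentration.
#'
#' @param auc AUC to the last quantifiable sample.
#' @param clast_observed last positive concentration.
#' @param lambda_z terminal rate constant (1/h); `NA` propagates.
#' @return list with `auc_inf` and `extrap_frac`, the extrapolated fraction
#'   of the total area.
#' @export
auc_inf <- function(auc, clast_observed, lambda_z) {
  if (is.na(lambda_z)) {
    return(list(auc_inf = NA_real_, extrap_frac = NA_real_))
  }
  stopifnot(lambda_z > 0, clast_observed > 0)
  tail_area <- clast_observed / lambda_z
  total <- auc + tail_area
  list(auc_inf = total, extrap_frac = tail_area / total)
}

#' Maximum concentration and its time
#'
#' @param times,concs the profile.
#' @return list with `cmax` and `tmax`; ties are broken to the earliest
#'   time.
#' @export
cmax_tmax <- function(times, concs) {
  check_profile(times, concs)
  i <- which.max(concs)  # which.max returns the first maximum
  list(cmax = concs[i], tmax = times[i])
}

#' Average slope of the absorption phase
#'
#' The mean of the successive chord slopes of the concentration-time curve
#' from the first sample up to the first occurrence of the maximum
#' concentration:
#' \deqn{AS = \frac{1}{m}\sum_{i=1}^{m}
#'       \frac{C_i - C_{i-1}}{t_i - t_{i-1}},}
#' where sample `m` is the first at Cmax. This endpoint summarizes how
#' steeply the profile rises and tracks the absorption rate; it moves
#' inversely to Tmax. Alternative published definitions can be supplied via
#' `strategy`.
#'
#' @param times,concs the profile.
#' @param strategy either `"chord_mean"` (default) or a function
#'   `(times, concs, m)` returning a slope, where `m` is the index of the
#'   first Cmax occurrence.
#' @return slope (concentration/h).
#' @export
#' @examples
#' average_slope(c(0, 1, 2, 3), c(0, 4, 10, 2))  # (4 + 6)/2 = 5
average_slope <- function(times, concs, strategy = "chord_mean") {
  check_profile(times, concs)
  m <- which.max(concs)
  if (m == 1) {
    stop("Cmax occurs at the first sample: no ascending phase to average",
         call. = FALSE)
  }
  if (is.function(strategy)) return(strategy(times, concs, m))
  idx <- seq_len(m)
  mean(diff(concs[idx]) / diff(times[idx]))
}

# vectorized endpoint computation for a (profiles x times) matrix; the
# scalar operations above are the reference implementations
nca_matrix <- function(times, cm) {
  out <- nca_core(times, cm)
  np <- nrow(cm)
  lz <- npts <- ex <- aucinf <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    fit <- lambda_z(times, cm[i, ])
    lz[i] <- fit$lambda_z
    if (!is.na(lz[i])) {
      clast <- cm[i, last_positive(cm[i, ])]
      ai <- auc_inf(out$auc[i], clast, lz[i])
      aucinf[i] <- ai$auc_inf
      ex[i] <- ai$extrap_frac
    }
  }
  data.frame(auc = out$auc, auc_inf = aucinf, cmax = out$cmax,
             tmax = out$tmax, as_slope = out$as_slope, lambda_z = lz,
             extrap_frac = ex)
}

# terminal-phase-free endpoint core; the Monte Carlo hot path
nca_core <- function(times, cm) {
  np <- nrow(cm); nt <- ncol(cm)
  dt <- diff(times)
  rows <- seq_len(np)
  # rowwise cumulative sums via an upper-triangular ones matrix keep the
  # Monte Carlo hot path free of per-row loops
  tri <- upper.tri(diag(nt - 1), diag = TRUE) * 1
  dtm <- matrix(dt, np, nt - 1, byrow = TRUE)
  areas <- (cm[, -1, drop = FALSE] + cm[, -nt, drop = FALSE]) / 2 * dtm
  cum_area <- areas %*% tri
  lastpos <- nt + 1L - max.col(cm[, nt:1, drop = FALSE] > 0,
                               ties.method = "first")
  lastpos[rowSums(cm > 0) == 0] <- 1L
  auc <- ifelse(lastpos > 1, cum_area[cbind(rows, pmax(lastpos - 1, 1))], 0)
  imax <- max.col(cm, ties.method = "first")
  cmax <- cm[cbind(rows, imax)]
  tmax <- times[imax]
  # mean chord slope up to the first Cmax occurrence
  slopes <- (cm[, -1, drop = FALSE] - cm[, -nt, drop = FALSE]) / dtm
  cum <- slopes %*% tri
  as_slope <- ifelse(imax > 1,
                     cum[cbind(rows, pmax(imax - 1, 1))] /
                       (imax - 1), NA_real_)
  list(auc = auc, cmax = cmax, tmax = tmax, as_slope = as_slope)
}

#' Compute the endpoint table of a trial dataset
#'
#' Applies non-compartmental analysis to every subject-by-period profile:
#' AUC to the last quantifiable sample, AUC extrapolated to infinity, Cmax,
#' Tmax, the average slope of the absorption phase, the terminal rate
#' constant, and the extrapolated area fraction. Profiles whose terminal
#' rate constant cannot be estimated keep a missing `auc_inf` only; no
#' profile is dropped and the extrapolated fraction is reported but never
#' used to exclude.
#'
#' @param dataset long-format trial data as produced by [simulate_trial()]
#'   or [read_concentration_csv()].
#' @return data.frame with one row per subject x period:
#'   `subject, sequence, period, treatment, auc, auc_inf, cmax, tmax,
#'   as_slope, lambda_z, extrap_frac`.
#' @export
build_endpoint_table <- function(dataset) {
  req <- c("subject", "sequence", "period", "treatment", "time_h", "conc")
  stopifnot(all(req %in% names(dataset)))
  key <- interaction(dataset$subject, dataset$period, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(dataset)), key), function(idx) {
    d <- dataset[idx, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    if (all(d$conc == 0)) {
      stop("profile subject ", d$subject[1], " period ", d$period[1],
           " has all-zero concentrations", call. = FALSE)
    }
    ep <- nca_matrix(d$time_h, matrix(d$conc, nrow = 1))
    cbind(d[1, c("subject", "sequence", "period", "treatment")], ep)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}
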