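#' Crossover ANOVA for a 2x2 bioequivalence trial
#'
#' Fixed-effects least-squares analysis of the log-transformed endpoint on
#' sequence, subject-within-sequence, period and treatment. For balanced
#' complete data this fit reduces to the classical period-difference form:
#' with `d_i` the period-1 minus period-2 log difference of subject `i`,
#' the T - R effect is `(mean(d, TR) - mean(d, RT)) / 2`, the residual sum
#' of squares is `sum((d_i - mean(d, seq(i)))^2) / 2`, and the residual
#' degrees of freedom are `n - 2`. Incomplete subjects are an error; no
#' imputation is attempted.
#'
#' @param data data.frame with columns `subject`, `sequence` (`"TR"` or
#'   `"RT"`), `period` (1 or 2), `treatment` (`"T"` or `"R"`) and `value`
#'   (> 0; the log transform is applied internally).
#' @return list with `effect_ln` (T - R on the log scale), `mse_ln`
#'   (residual mean square), `df` (residual degrees of freedom), and the
#'   per-sequence sizes `n1` (TR), `n2` (RT).
#' @export
anova_2x2 <- function(data) {
  req <- c("subject", "sequence", "period", "treatment", "value")
  stopifnot(all(req %in% names(data)))
  if (any(data$value <= 0)) {
    stop("values must be positive for the log-scale analysis",
         call. = FALSE)
  }
  tab <- table(data$subject)
  if (any(tab != 2)) {
    stop("incomplete subjects (must appear in exactly two periods): ",
         paste(names(tab)[tab != 2], collapse = ", "), call. = FALSE)
  }
  d1 <- data[data$period == 1, ]
  d2 <- data[data$period == 2, ]
  if (nrow(d1) != nrow(d2)) stop("periods are unbalanced", call. = FALSE)
  m <- match(d1$subject, d2$subject)
  if (anyNA(m)) stop("subjects missing a period", call. = FALSE)
  d2 <- d2[m, ]
  bad <- !((d1$sequence == "TR" & d1$treatment == "T" &
              d2$treatment == "R") |
           (d1$sequence == "RT" & d1$treatment == "R" &
              d2$treatment == "T"))
  if (any(bad)) {
    stop("treatment labels inconsistent with sequence for subject(s): ",
         paste(unique(d1$subject[bad]), collapse = ", "), call. = FALSE)
  }
  d <- log(d1$value) - log(d2$value)
  is_tr <- d1$sequence == "TR"
  n1 <- sum(is_tr); n2 <- sum(!is_tr)
  if (n1 < 2 || n2 < 2) {
    stop("each sequence needs at least 2 subjects", call. = FALSE)
  }
  # period-1 difference is +(T-R) in TR and -(T-R) in RT
  effect <- (mean(d[is_tr]) - mean(d[!is_tr])) / 2
  sse <- (sum((d[is_tr] - mean(d[is_tr]))^2) +
            sum((d[!is_tr] - mean(d[!is_tr]))^2)) / 2
  df <- n1 + n2 - 2L
  list(effect_ln = effect, mse_ln = sse / df, df = df, n1 = n1, n2 = n2)
}

#' 90% confidence interval and 80-125% bioequivalence decision
#'
#' The two-sided 90% confidence interval of the T/R geometric mean ratio is
#' `exp(effect +/- t(0.95, df) * sqrt(mse * (1/n1 + 1/n2) / 2))`.
#' Bioequivalence is accepted when the whole interval lies within
#' 80-125%; the comparison uses unrounded bounds.
#'
#' @param effect_ln treatment effect (T - R) on the log scale.
#' @param mse_ln residual mean square from [anova_2x2()].
#' @param df residual degrees of freedom (>= 1).
#' @param n1,n2 subjects per sequence.
#' @param endpoint optional endpoint label carried into the result.
#' @return one-row data.frame: `endpoint, gmr, ci_lower, ci_upper, mse_ln,
#'   df, pass`.
#' @export
#' @examples
#' ci90_decision(log(1.02), 0.04, 22, 12, 12)
ci90_decision <- function(effect_ln, mse_ln, df, n1, n2,
                          endpoint = NA_character_) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stopifnot(mse_ln >= 0, n1 >= 1, n2 >= 1)
  se <- sqrt(mse_ln * (1 / n1 + 1 / n2) / 2)
  hw <- stats::qt(0.95, df) * se
  lo <- exp(effect_ln - hw)
  hi <- exp(effect_ln + hw)
  data.frame(endpoint = endpoint, gmr = exp(effect_ln),
             ci_lower = lo, ci_upper = hi, mse_ln = mse_ln, df = df,
             pass = lo >= 0.80 & hi <= 1.25, stringsAsFactors = FALSE)
}

#' Assess bioequivalence for a set of endpoints
#'
#' Runs the crossover ANOVA and the 90% CI decision for each requested
#' endpoint column of an endpoint table (raw or VBC-decomposed). Each
#' endpoint is tested at its own nominal level; no multiplicity adjustment
#' is applied.
#'
#' @param table endpoint table with `subject`, `sequence`, `period`,
#'   `treatment` and the endpoint columns.
#' @param endpoints character vector of endpoint column names.
#' @return data.frame with one row per endpoint
#'   (`endpoint, gmr, ci_lower, ci_upper, mse_ln, df, pass`).
#' @export
assess_endpoints <- function(table, endpoints) {
  miss <- setdiff(endpoints, names(table))
  if (length(miss)) {
    stop("unknown endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(endpoints, function(ep) {
    df <- data.frame(subject = table$subject, sequence = table$sequence,
                     period = table$period, treatment = table$treatment,
                     value = table[[ep]], stringsAsFactors = FALSE)
    fit <- anova_2x2(df)
    ci90_decision(fit$effect_ln, fit$mse_ln, fit$df, fit$n1, fit$n2,
                  endpoint = ep)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(endpoint = character(), gmr = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      mse_ln = numeric(), df = integer(),
                      pass = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
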