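# Fixture builders and independent oracles shared across test files.

# random balanced 2x2 crossover endpoint fixture on the natural scale
random_be_fixture <- function(n = 12, seed = 1, gmr = 1,
                              sw = 0.2, sb = 0.15) {
  set.seed(seed)
  subj <- rep(rnorm(n, log(100), sb), each = 2)
  seqs <- rep(rep(c("TR", "RT"), each = n / 2), each = 2)
  period <- rep(1:2, n)
  treatment <- ifelse((seqs == "TR") == (period == 1), "T", "R")
  lnv <- subj + ifelse(treatment == "T", log(gmr), 0) +
    0.03 * (period == 2) + rnorm(2 * n, 0, sw)
  data.frame(subject = rep(seq_len(n), each = 2), sequence = seqs,
             period = period, treatment = treatment, value = exp(lnv),
             stringsAsFactors = FALSE)
}

# brute-force least-squares oracle for the crossover ANOVA: explicit
# design-matrix fit of ln(value) on sequence, subject-within-sequence,
# period and treatment
be_lm_oracle <- function(data) {
  d <- data
  d$subject <- factor(d$subject)
  d$period <- factor(d$period)
  d$treatment <- factor(d$treatment, levels = c("R", "T"))
  fit <- lm(log(value) ~ subject + period + treatment, data = d)
  list(effect_ln = unname(coef(fit)[["treatmentT"]]),
       mse_ln = sum(residuals(fit)^2) / fit$df.residual,
       df = fit$df.residual)
}

# classical two-one-sided-t oracle: 90% CI from per-subject period
# differences halved, compared between sequences
be_tost_oracle <- function(data) {
  d1 <- data[data$period == 1, ]
  d2 <- data[data$period == 2, ]
  d2 <- d2[match(d1$subject, d2$subject), ]
  x <- (log(d1$value) - log(d2$value)) / 2
  tt <- t.test(x[d1$sequence == "TR"], x[d1$sequence == "RT"],
               var.equal = TRUE, conf.level = 0.90)
  exp(as.numeric(tt$conf.int))
}

# endpoint table with known per-cell structure for VBC tests
random_endpoint_table <- function(n = 24, seed = 1, rho = 0) {
  set.seed(seed)
  seqs <- rep(rep(c("TR", "RT"), each = n / 2), each = 2)
  period <- rep(1:2, n)
  treatment <- ifelse((seqs == "TR") == (period == 1), "T", "R")
  m <- 2 * n
  z1 <- rnorm(m)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  data.frame(subject = rep(seq_len(n), each = 2), sequence = seqs,
             period = period, treatment = treatment,
             auc = exp(log(100) + 0.2 * z1),
             cmax = exp(log(10) + 0.25 * z2),
             as_slope = exp(log(2) + 0.3 * rnorm(m)),
             stringsAsFactors = FALSE)
}
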