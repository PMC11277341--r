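#' Stochastic variability specification
#'
#' Variability is introduced on every structural model parameter as
#' independent lognormal random effects: a between-subject effect shared by
#' both periods and a within-subject (inter-occasion) effect drawn per
#' period. For a coefficient of variation `c` the lognormal standard
#' deviation is `sqrt(log(1 + c^2))`. Measured concentrations additionally
#' carry a proportional residual error.
#'
#' @param bsv_cv between-subject CV (fraction; default 0.15).
#' @param wsv_cv within-subject CV (fraction; default 0.20).
#' @param residual_cv proportional residual-error CV (fraction;
#'   default 0.05).
#' @return an object of class `variability_spec`.
#' @export
variability_spec <- function(bsv_cv = 0.15, wsv_cv = 0.20,
                             residual_cv = 0.05) {
  if (bsv_cv < 0 || wsv_cv < 0 || residual_cv < 0) {
    stop("coefficients of variation must be non-negative", call. = FALSE)
  }
  structure(list(bsv_cv = bsv_cv, wsv_cv = wsv_cv,
                 residual_cv = residual_cv),
            class = "variability_spec")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' 2x2 crossover trial design
#'
#' Two-treatment, two-period, two-sequence (TR/RT) design with balanced
#' allocation: the first half of the subjects receives sequence TR, the
#' second half RT.
#'
#' @param n_subjects even number of subjects (default 24).
#' @param schedule strictly increasing sampling times (h), first time 0.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 24, schedule) {
  if (n_subjects < 2 || n_subjects %% 2 != 0) {
    stop("n_subjects must be an even number >= 2 for a balanced 2x2 design",
         call. = FALSE)
  }
  stopifnot(length(schedule) >= 2, schedule[1] == 0,
            all(diff(schedule) > 0))
  structure(list(n_subjects = n_subjects, schedule = schedule,
                 sequences = rep(c("TR", "RT"), each = n_subjects / 2),
                 n_periods = 2L),
            class = "trial_design")
}

# names of the structural parameters that receive random effects
varied_parameters <- function(model) {
  if (model$model_kind == "one_compartment") c("ka", "cl", "v1")
  else c("ka", "cl", "v1", "q", "v2", "tlag")
}

#' Draw individual pharmacokinetic parameters
#'
#' Each parameter P of subject i in period j is
#' `P_pop * exp(eta_i) * exp(kappa_ij)` with
#' `eta ~ N(0, log(1 + bsv_cv^2))` and `kappa ~ N(0, log(1 + wsv_cv^2))`,
#' independent across parameters. Dose and bioavailability are treated as
#' fixed. A lag time of zero stays zero under the multiplicative model.
#'
#' @param model a [pk_model()] giving the population values.
#' @param var a [variability_spec()].
#' @param n_subjects number of subjects.
#' @param n_periods number of periods (occasions) per subject.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers that manage seeding themselves stay reproducible).
#' @return data.frame with columns `subject`, `period` and one column per
#'   structural parameter.
#' @export
draw_individual_params <- function(model, var, n_subjects, n_periods = 2,
                                   seed = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(var, "variability_spec"),
            n_subjects >= 1, n_periods >= 1)
  if (!is.null(seed)) set.seed(seed)
  pars <- varied_parameters(model)
  sd_b <- cv_to_sdlog(var$bsv_cv)
  sd_w <- cv_to_sdlog(var$wsv_cv)
  n <- n_subjects * n_periods
  out <- data.frame(subject = rep(seq_len(n_subjects), each = n_periods),
                    period = rep(seq_len(n_periods), times = n_subjects))
  for (p in pars) {
    eta <- rep(stats::rnorm(n_subjects, 0, sd_b), each = n_periods)
    kappa <- stats::rnorm(n, 0, sd_w)
    out[[p]] <- model[[p]] * exp(eta + kappa)
  }
  out
}

# Evaluate the closed-form model rowwise for a parameter data.frame:
# returns an (nrow(params) x length(times)) concentration matrix.
conc_matrix <- function(model_kind, dose, f_abs, params, times) {
  nt <- length(times)
  tm <- matrix(times, nrow = nrow(params), ncol = nt, byrow = TRUE)
  if (model_kind == "one_compartment") {
    k10 <- params$cl / params$v1
    coef <- f_abs * dose * params$ka / (params$v1 * (params$ka - k10))
    coef * (exp(-k10 * tm) - exp(-params$ka * tm))
  } else {
    k10 <- params$cl / params$v1
    k12 <- params$q / params$v1
    k21 <- params$q / params$v2
    s <- k10 + k12 + k21
    d <- sqrt(s^2 - 4 * k10 * k21)
    a <- (s + d) / 2
    b <- (s - d) / 2
    ka <- params$ka
    tt <- pmax(tm - params$tlag, 0)
    cc <- f_abs * dose * ka / params$v1 *
      ((k21 - a) / ((ka - a) * (b - a)) * exp(-a * tt) +
       (k21 - b) / ((ka - b) * (a - b)) * exp(-b * tt) +
       (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * tt))
    cc[tm <= params$tlag] <- 0
    cc
  }
}

# Internal fast path shared by simulate_trial() and the power engine.
# Returns meta (subject/sequence/period/treatment per profile) plus the
# concentration matrix (profiles x sampling times).
simulate_trial_matrix <- function(design, model_T, model_R, var) {
  n <- design$n_subjects
  pars <- varied_parameters(model_R)
  sd_b <- cv_to_sdlog(var$bsv_cv)
  sd_w <- cv_to_sdlog(var$wsv_cv)
  meta <- data.frame(
    subject = rep(seq_len(n), each = 2L),
    sequence = rep(design$sequences, each = 2L),
    period = rep(1:2, times = n),
    stringsAsFactors = FALSE)
  meta$treatment <- ifelse(
    (meta$sequence == "TR") == (meta$period == 1L), "T", "R")
  params <- data.frame(row.names = seq_len(2L * n))
  for (p in pars) {
    eta <- rep(stats::rnorm(n, 0, sd_b), each = 2L)
    kappa <- stats::rnorm(2L * n, 0, sd_w)
    pop <- ifelse(meta$treatment == "T", model_T[[p]], model_R[[p]])
    params[[p]] <- pop * exp(eta + kappa)
  }
  cm <- conc_matrix(model_R$model_kind, model_R$dose, model_R$f_abs,
                    params, design$schedule)
  if (var$residual_cv > 0) {
    eps <- matrix(stats::rnorm(length(cm), 0, var$residual_cv), nrow(cm))
    cm <- pmax(cm * (1 + eps), 0)
  }
  list(meta = meta, times = design$schedule, conc = cm)
}

#' Simulate a 2x2 crossover bioequivalence trial
#'
#' Generates individual parameters for each subject and period (test and
#' reference models may differ, typically only in `ka`), evaluates the
#' concentration-time profiles at the design's sampling schedule, and adds
#' proportional residual error, clamping negative measurements to zero.
#'
#' @param design a [trial_design()].
#' @param model_T,model_R [pk_model()] objects for the test and reference
#'   products. They must share the same structural model, dose and
#'   bioavailability.
#' @param var a [variability_spec()].
#' @param seed integer seed for reproducibility.
#' @return long-format data.frame with columns
#'   `subject, sequence, period, treatment, time_h, conc`, ordered by
#'   subject, period, time.
#' @export
#' @examples
#' p <- drug_profile("hydrochlorothiazide")
#' d <- trial_design(24, p$schedule)
#' trial <- simulate_trial(d, p$model, p$model, variability_spec(), seed = 7)
#' head(trial)
simulate_trial <- function(design, model_T, model_R, var, seed) {
  stopifnot(inherits(design, "trial_design"),
            inherits(model_T, "pk_model"), inherits(model_R, "pk_model"),
            model_T$model_kind == model_R$model_kind)
  set.seed(seed)
  sim <- simulate_trial_matrix(design, model_T, model_R, var)
  nt <- length(sim$times)
  out <- data.frame(
    subject = rep(sim$meta$subject, each = nt),
    sequence = rep(sim$meta$sequence, each = nt),
    period = rep(sim$meta$period, each = nt),
    treatment = rep(sim$meta$treatment, each = nt),
    time_h = rep(sim$times, times = nrow(sim$meta)),
    conc = as.vector(t(sim$conc)),
    stringsAsFactors = FALSE)
  out[order(out$subject, out$period, out$time_h), , drop = FALSE]
}

#' Simulate a single-arm cohort on the reference product
#'
#' Generates one profile per subject (a single occasion; between- and
#' within-subject effects both apply) from one drug profile. Used for
#' exploratory analyses of endpoint interrelationships such as PCA, which
#' precede the crossover comparison.
#'
#' @param profile a [drug_profile()] (or a list with `model` and
#'   `schedule`).
#' @param n_subjects cohort size (default 200).
#' @param var a [variability_spec()].
#' @param seed integer seed.
#' @return list with `times` and the `conc` matrix (subjects x times).
#' @export
simulate_cohort <- function(profile, n_subjects = 200,
                            var = variability_spec(), seed) {
  set.seed(seed)
  model <- profile$model
  pars <- varied_parameters(model)
  sd_tot <- sqrt(cv_to_sdlog(var$bsv_cv)^2 + cv_to_sdlog(var$wsv_cv)^2)
  params <- data.frame(row.names = seq_len(n_subjects))
  for (p in pars) {
    params[[p]] <- model[[p]] * exp(stats::rnorm(n_subjects, 0, sd_tot))
  }
  cm <- conc_matrix(model$model_kind, model$dose, model$f_abs,
                    params, profile$schedule)
  if (var$residual_cv > 0) {
    eps <- matrix(stats::rnorm(length(cm), 0, var$residual_cv), nrow(cm))
    cm <- pmax(cm * (1 + eps), 0)
  }
  list(times = profile$schedule, conc = cm)
}
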