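#' Define a population pharmacokinetic model
#'
#' Constructs the structural oral-absorption model from which virtual
#' concentration-time profiles are generated. Two structures are supported:
#' a one-compartment model with first-order absorption and elimination, and
#' a two-compartment model with first-order absorption delayed by a lag time.
#'
#' @param model_kind `"one_compartment"` or `"two_compartment_lag"`.
#' @param dose administered dose (mass units; concentrations inherit
#'   mass/volume).
#' @param f_abs absolute bioavailability, in (0, 1].
#' @param ka first-order absorption rate constant (1/h).
#' @param cl clearance (L/h).
#' @param v1 central volume of distribution (L).
#' @param q inter-compartmental clearance (L/h); two-compartment only.
#' @param v2 peripheral volume (L); two-compartment only.
#' @param tlag absorption lag time (h, >= 0); two-compartment only.
#'
#' @return An object of class `pk_model`.
#' @export
#' @examples
#' m <- pk_model("one_compartment", dose = 10, f_abs = 0.64,
#'               ka = 0.8, cl = 25, v1 = 1800)
#' predict_concentration(m, c(0, 1, 5, 24))
pk_model <- function(model_kind = c("one_compartment", "two_compartment_lag"),
                     dose, f_abs, ka, cl, v1,
                     q = NULL, v2 = NULL, tlag = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(dose > 0, f_abs > 0, f_abs <= 1, ka > 0, cl > 0, v1 > 0)
  k10 <- cl / v1
  if (model_kind == "one_compartment") {
    if (abs(ka - k10) < 1e-10 * max(ka, k10)) {
      stop("degenerate model: ka equals k10 (flip-flop kinetics); ",
           "the bi-exponential solution is undefined", call. = FALSE)
    }
    m <- list(model_kind = model_kind, dose = dose, f_abs = f_abs,
              ka = ka, cl = cl, v1 = v1)
  } else {
    if (is.null(q) || is.null(v2) || is.null(tlag)) {
      stop("two_compartment_lag requires q, v2 and tlag", call. = FALSE)
    }
    stopifnot(q > 0, v2 > 0, tlag >= 0)
    mac <- macro_rates(k10, q / v1, q / v2)
    if (min(abs(ka - mac)) < 1e-10 * ka) {
      stop("degenerate model: ka equals a disposition macro-rate ",
           "(flip-flop kinetics); the tri-exponential solution is undefined",
           call. = FALSE)
    }
    m <- list(model_kind = model_kind, dose = dose, f_abs = f_abs,
              ka = ka, cl = cl, v1 = v1, q = q, v2 = v2, tlag = tlag)
  }
  class(m) <- "pk_model"
  m
}

# alpha/beta hybrid rate constants of the two-compartment disposition
macro_rates <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  d <- sqrt(s^2 - 4 * k10 * k21)
  c(alpha = (s + d) / 2, beta = (s - d) / 2)
}

#' @export
print.pk_model <- function(x, ...) {
  cat("<pk_model>", x$model_kind, "\n")
  cat("  dose:", x$dose, " F:", x$f_abs, " ka:", x$ka,
      " CL:", x$cl, " V1:", x$v1, "\n")
  if (x$model_kind == "two_compartment_lag") {
    cat("  Q:", x$q, " V2:", x$v2, " tlag:", x$tlag, "\n")
  }
  invisible(x)
}

#' Predict drug concentration at given times
#'
#' Evaluates the closed-form solution of the model's disposition equations
#' after a single oral dose. For the one-compartment model this is the
#' classical Bateman function
#' \deqn{C(t) = \frac{F D k_a}{V_1 (k_a - k_{10})}
#'       \left(e^{-k_{10} t} - e^{-k_a t}\right),}
#' with \eqn{k_{10} = CL/V_1}. For the two-compartment model with lag the
#' tri-exponential oral solution is used, shifted by the lag time (the
#' concentration is zero at or before `tlag`). An ODE integration route
#' (via \pkg{deSolve}) is available as a numerical cross-check.
#'
#' @param model a [pk_model()].
#' @param t vector of times (h), all >= 0.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @return numeric vector of concentrations at `t`.
#' @export
predict_concentration <- function(model, t, method = c("closed_form", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "pk_model"), all(t >= 0))
  if (method == "ode") return(predict_concentration_ode(model, t))
  with(model, {
    if (model_kind == "one_compartment") {
      k10 <- cl / v1
      f_abs * dose * ka / (v1 * (ka - k10)) * (exp(-k10 * t) - exp(-ka * t))
    } else {
      k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
      mac <- macro_rates(k10, k12, k21)
      a <- mac[["alpha"]]; b <- mac[["beta"]]
      tt <- pmax(t - tlag, 0)
      cc <- f_abs * dose * ka / v1 *
        ((k21 - a) / ((ka - a) * (b - a)) * exp(-a * tt) +
         (k21 - b) / ((ka - b) * (a - b)) * exp(-b * tt) +
         (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * tt))
      cc[t <= tlag] <- 0
      cc
    }
  })
}

# numerical route: integrate the compartmental mass-balance ODEs
predict_concentration_ode <- function(model, t) {
  k10 <- model$cl / model$v1
  tlag <- if (model$model_kind == "two_compartment_lag") model$tlag else 0
  # absorption depot is charged at t = tlag
  t_int <- sort(unique(c(0, pmax(t - tlag, 0))))
  if (model$model_kind == "one_compartment") {
    rhs <- function(time, y, p) {
      list(c(-p$ka * y[1], p$ka * y[1] - p$k10 * y[2]))
    }
    y0 <- c(depot = model$f_abs * model$dose, central = 0)
    p <- list(ka = model$ka, k10 = k10)
  } else {
    k12 <- model$q / model$v1; k21 <- model$q / model$v2
    rhs <- function(time, y, p) {
      list(c(-p$ka * y[1],
             p$ka * y[1] - (p$k10 + p$k12) * y[2] + p$k21 * y[3],
             p$k12 * y[2] - p$k21 * y[3]))
    }
    y0 <- c(depot = model$f_abs * model$dose, central = 0, peripheral = 0)
    p <- list(ka = model$ka, k10 = k10, k12 = k12, k21 = k21)
  }
  sol <- deSolve::lsoda(y0, t_int, rhs, p, rtol = 1e-10, atol = 1e-12)
  conc <- sol[, "central"] / model$v1
  conc[match(pmax(t - tlag, 0), t_int)] * as.numeric(t > tlag | tlag == 0)
}

#' Analytic time of maximum concentration (one-compartment model)
#'
#' @param model a one-compartment [pk_model()].
#' @return Tmax in hours, `log(ka/k10)/(ka - k10)`.
#' @export
tmax_analytic <- function(model) {
  stopifnot(inherits(model, "pk_model"),
            model$model_kind == "one_compartment")
  k10 <- model$cl / model$v1
  log(model$ka / k10) / (model$ka - k10)
}

#' Bundled surrogate drug profiles
#'
#' Three named parameter sets spanning slow, fast, and moderate oral
#' absorption, each bundled with a sampling schedule suited to its kinetics.
#' They are synthetic stand-ins calibrated so that the predicted time of
#' peak concentration falls in the range characteristic of the drug class
#' they are named after: `"amlodipine"` (one-compartment, Tmax about 5 h),
#' `"irbesartan"` (two-compartment with lag, Tmax 1-2 h), and
#' `"hydrochlorothiazide"` (two-compartment with lag, Tmax 1-4 h). They are
#' not literature parameter estimates for the actual drugs.
#'
#' @param name one of `"amlodipine"`, `"irbesartan"`,
#'   `"hydrochlorothiazide"`.
#' @return a list with elements `name`, `model` (a [pk_model()]) and
#'   `schedule` (sampling times in hours, starting at 0).
#' @export
#' @examples
#' p <- drug_profile("irbesartan")
#' predict_concentration(p$model, p$schedule)
drug_profile <- function(name = c("amlodipine", "irbesartan",
                                  "hydrochlorothiazide")) {
  name <- match.arg(name)
  fast_schedule <- c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 3, 4, 6, 8,
                     12, 24, 36, 48)
  slow_schedule <- c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 24, 48, 72, 96, 144)
  switch(name,
    amlodipine = list(
      name = name,
      model = pk_model("one_compartment", dose = 10, f_abs = 0.64,
                       ka = 0.8, cl = 25, v1 = 1800),
      schedule = slow_schedule),
    irbesartan = list(
      name = name,
      model = pk_model("two_compartment_lag", dose = 150, f_abs = 0.7,
                       ka = 2.0, cl = 12, v1 = 30, q = 10, v2 = 60,
                       tlag = 0.25),
      schedule = fast_schedule),
    hydrochlorothiazide = list(
      name = name,
      model = pk_model("two_compartment_lag", dose = 25, f_abs = 0.7,
                       ka = 0.7, cl = 20, v1 = 80, q = 6, v2 = 100,
                       tlag = 0.4),
      schedule = fast_schedule)
  )
}
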