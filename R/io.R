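#' Read a long-format concentration-time CSV
#'
#' Expects the exact header
#' `subject,sequence,period,treatment,time_h,conc` and validates the 2x2
#' structure: numeric times and concentrations, no duplicated
#' (subject, period, time) rows, every subject present in both periods,
#' and treatment labels consistent with the sequence.
#'
#' @param path CSV file path.
#' @return validated trial dataset (data.frame), ordered by subject,
#'   period, time.
#' @export
read_concentration_csv <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  want <- c("subject", "sequence", "period", "treatment", "time_h", "conc")
  if (!identical(header, want)) {
    stop("malformed header: expected '", paste(want, collapse = ","),
         "', found '", paste(header, collapse = ","), "'", call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("period", "time_h", "conc")) {
    if (!is.numeric(d[[col]])) {
      stop("non-numeric values in column '", col, "'", call. = FALSE)
    }
  }
  if (any(d$conc < 0)) stop("negative concentrations", call. = FALSE)
  if (!all(d$sequence %in% c("TR", "RT"))) {
    stop("sequence must be 'TR' or 'RT'", call. = FALSE)
  }
  if (!all(d$treatment %in% c("T", "R"))) {
    stop("treatment must be 'T' or 'R'", call. = FALSE)
  }
  key <- paste(d$subject, d$period, d$time_h)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicated (subject, period, time) rows at data line(s): ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  per_subj <- tapply(d$period, d$subject, function(p) length(unique(p)))
  if (any(per_subj != 2)) {
    stop("subject(s) without both periods: ",
         paste(names(per_subj)[per_subj != 2], collapse = ", "),
         call. = FALSE)
  }
  ok <- (d$sequence == "TR" & ((d$period == 1) == (d$treatment == "T"))) |
        (d$sequence == "RT" & ((d$period == 1) == (d$treatment == "R")))
  if (!all(ok)) {
    stop("treatment labels inconsistent with sequence/period at data ",
         "line(s): ", paste(utils::head(which(!ok), 10), collapse = ", "),
         call. = FALSE)
  }
  d[order(d$subject, d$period, d$time_h), , drop = FALSE]
}

#' Write a trial dataset (or any result table) to CSV
#'
#' Values are written at full precision (15 significant digits) so that
#' read/write round-trips preserve them; row order is deterministic.
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 15, scientific = FALSE,
                                trim = TRUE))
  })
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a scenario configuration (YAML or JSON)
#'
#' The configuration names a bundled drug profile or gives explicit model
#' parameters, plus design, variability, grid and trial counts. All fields
#' have defaults matching the package's standard study conditions
#' (n = 24 crossover subjects, BSV 15%, WSV 20%, grid 1.0-2.0 by 0.1,
#' 1000 trials).
#'
#' @param path YAML (or JSON) file.
#' @return a [scenario_spec()] plus `seed`/`pca_n` fields when present.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  profile <- if (!is.null(cfg$drug)) {
    drug_profile(cfg$drug)
  } else {
    m <- cfg$model
    list(name = if (is.null(cfg$name)) "custom" else cfg$name,
         model = do.call(pk_model, m),
         schedule = as.numeric(cfg$schedule))
  }
  var <- do.call(variability_spec, if (is.null(cfg$variability)) list()
                 else cfg$variability)
  vbc <- if (is.null(cfg$anchor)) vbc_config() else vbc_config(cfg$anchor)
  sc <- scenario_spec(
    profile,
    n_subjects = if (is.null(cfg$n_subjects)) 24 else cfg$n_subjects,
    var = var,
    ka_ratio_grid = if (is.null(cfg$ka_ratio_grid)) seq(1, 2, by = 0.1)
                    else as.numeric(cfg$ka_ratio_grid),
    n_trials = if (is.null(cfg$n_trials)) 1000 else cfg$n_trials,
    vbc = vbc)
  sc$seed <- cfg$seed
  sc$pca_n <- if (is.null(cfg$pca_n)) 200 else cfg$pca_n
  sc
}

#' Run a pipeline stage and write its artifacts
#'
#' Single entry point behind the command-line script: dispatches one of
#' `simulate`, `nca`, `decompose`, `be`, `power`, `pca`, writes the stage's
#' CSV outputs into `out_dir`, and records a manifest (seed, configuration
#' hash, package version) so every stochastic artifact is reproducible.
#'
#' @param command one of `"simulate"`, `"nca"`, `"decompose"`, `"be"`,
#'   `"power"`, `"pca"`.
#' @param scenario a [scenario_spec()] (from [read_scenario()]) for the
#'   stochastic commands, or `NULL` for table-driven ones.
#' @param input input CSV path for `nca`, `decompose` and `be`.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed (mandatory for `simulate`, `power`, `pca`).
#' @param endpoints endpoint columns tested by `be`.
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "nca", "decompose", "be",
                                     "power", "pca"),
                         scenario = NULL, input = NULL, out_dir = ".",
                         seed = NULL,
                         endpoints = c("auc", "cmax_perp",
                                       "as_slope_perp")) {
  command <- match.arg(command)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  needs_seed <- command %in% c("simulate", "power", "pca")
  if (needs_seed && is.null(seed)) {
    stop("a seed is mandatory for stochastic commands", call. = FALSE)
  }
  paths <- list()
  out <- function(name) file.path(out_dir, name)
  if (command == "simulate") {
    ds <- simulate_trial(scenario$design, scenario$profile$model,
                         scenario$profile$model, scenario$var, seed = seed)
    paths$dataset <- write_result_csv(ds, out("dataset.csv"))
  } else if (command == "nca") {
    ds <- read_concentration_csv(input)
    paths$endpoints <- write_result_csv(build_endpoint_table(ds),
                                        out("endpoints.csv"))
  } else if (command == "decompose") {
    ep <- utils::read.csv(input, stringsAsFactors = FALSE)
    dec <- vbc_transform(ep, if (is.null(scenario)) vbc_config()
                         else scenario$vbc)
    paths$decomposed <- write_result_csv(dec, out("decomposed.csv"))
    paths$angles <- write_result_csv(attr(dec, "angles"),
                                     out("angles.csv"))
  } else if (command == "be") {
    ep <- utils::read.csv(input, stringsAsFactors = FALSE)
    res <- assess_endpoints(ep, endpoints)
    res[c("gmr", "ci_lower", "ci_upper", "mse_ln")] <-
      lapply(res[c("gmr", "ci_lower", "ci_upper", "mse_ln")], round, 4)
    paths$be <- write_result_csv(res, out("be_results.csv"))
  } else if (command == "power") {
    pc <- power_sweep(scenario, seed = seed)
    paths$power <- write_result_csv(pc, out("power_curve.csv"))
  } else if (command == "pca") {
    co <- simulate_cohort(scenario$profile, scenario$pca_n %||% 200,
                          scenario$var, seed = seed)
    res <- run_pca(nca_endpoint_matrix(co))
    paths$loadings <- write_result_csv(
      data.frame(endpoint = rownames(res$loadings), res$loadings),
      out("pca_loadings.csv"))
    paths$explained <- write_result_csv(
      data.frame(component = seq_along(res$eigenvalues),
                 eigenvalue = res$eigenvalues,
                 explained_pct = res$explained_variance_pct),
      out("pca_explained.csv"))
    paths$scores <- write_result_csv(as.data.frame(res$scores),
                                     out("pca_scores.csv"))
  }
  manifest <- list(command = command, seed = seed,
                   package = "vbcbe",
                   version = as.character(utils::packageVersion("vbcbe")),
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
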