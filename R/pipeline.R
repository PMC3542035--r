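#' Experiment configuration
#'
#' Bundles everything one end-to-end run needs: the synthetic cohort (or a
#' manifest directory), the view groupings and classifier variants, baseline
#' and sensitivity switches, and the master seed. Stage seeds are fanned out
#' deterministically from the master seed by stage-name hashing, so a single
#' integer reproduces the whole run.
#'
#' @param cohort a [cohort_config()], a `thyroid_cohort`, or a path to a
#'   serialized cohort directory.
#' @param groups view groupings to evaluate.
#' @param variants discriminant variants to evaluate.
#' @param baselines run the threshold and decision-tree baselines?
#' @param classification run the grouped discriminant evaluation?
#' @param sensitivity `NULL` to skip, otherwise a list of perturbation grids
#'   (see [shift_grid()]); by default a coarse shift grid plus a coarse size
#'   grid (step 5 px keeps the default run fast — pass step-1 grids for the
#'   full protocol).
#' @param sensitivity_variant variant used for classification surfaces.
#' @param seed master integer seed.
#' @param output_dir directory for the report bundle.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, groups = c("LO", "RO", "LRO", "LD",
                                                 "RD", "RLD", "RLOD"),
                              variants = discriminant_variants,
                              baselines = TRUE, classification = TRUE,
                              sensitivity = list(
                                shift = shift_grid(seq(-20L, 20L, by = 5L),
                                                   seq(-20L, 20L, by = 5L)),
                                size = size_grid(seq(-20L, 20L, by = 5L),
                                                 seq(-20L, 20L, by = 5L))),
                              sensitivity_variant = "linear", seed,
                              output_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(output_dir)) stop("output_dir is mandatory")
  if (!isTRUE(classification) && !isTRUE(baselines) &&
      is.null(sensitivity))
    stop("at least one of classification, baselines or sensitivity ",
         "must be enabled")
  structure(list(cohort = cohort, groups = groups, variants = variants,
                 baselines = baselines, classification = classification,
                 sensitivity = sensitivity,
                 sensitivity_variant = sensitivity_variant,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

# stage seed = master seed stirred with a stage-name hash (32-bit safe)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435 + h) %% 2147483647)
}

resolve_cohort <- function(cohort, seed) {
  if (inherits(cohort, "thyroid_cohort")) cohort
  else if (inherits(cohort, "cohort_config")) generate_cohort(cohort)
  else if (is.character(cohort) && dir.exists(cohort)) read_cohort(cohort)
  else stop("cohort must be a cohort_config, thyroid_cohort or directory")
}

log_stage <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run a full experiment
#'
#' Executes the enabled stages — simulate, preprocess + features, grouped
#' discriminant evaluation, baselines, sensitivity surfaces — and writes a
#' report bundle to `config$output_dir`: `features.csv`,
#' `classification.csv` (one row per group x variant),
#' `baseline_method1.csv`, `baseline_method2.json`, per-grid
#' `sensitivity_*.csv`, a `summary.json` (per-group best variant by ACC) and
#' a `run_log.txt`. Fully deterministic for a fixed config.
#'
#' @param config an [experiment_config()].
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log <- character(0)
  summary <- list(seed = config$seed)
  stage <- "simulate"
  result <- tryCatch({
    log <- log_stage(log, stage, "resolving cohort")
    cohort <- resolve_cohort(config$cohort, config$seed)
    log <- log_stage(log, stage, length(cohort), " subjects")

    stage <- "features"
    feats <- extract_cohort_features(cohort)
    write.csv(format_features(feats), out("features.csv"),
              row.names = FALSE, quote = FALSE)
    log <- log_stage(log, stage, nrow(feats), " views -> features.csv")

    if (isTRUE(config$classification)) {
      stage <- "classify"
      tab <- run_grouped_evaluation(feats,
                                    seed = stage_seed(config$seed, stage),
                                    groups = config$groups,
                                    variants = config$variants)
      write.csv(tab, out("classification.csv"), row.names = FALSE)
      best <- lapply(split(tab, tab$group), function(g)
        list(variant = g$variant[which.max(g$ACC)], ACC = max(g$ACC)))
      summary$classification <- list(
        n_rows = nrow(tab),
        acc = setNames(tab$ACC, paste(tab$group, tab$variant, sep = ".")),
        best_by_group = best)
      log <- log_stage(log, stage, nrow(tab),
                       " group x variant rows -> classification.csv")
    }

    if (isTRUE(config$baselines)) {
      stage <- "baseline"
      sweep <- method1_threshold_sweep(cohort)
      write.csv(sweep, out("baseline_method1.csv"), row.names = FALSE)
      parts <- split_cohort(feats, stage_seed(config$seed, "classify"))
      tree <- method2_fit(parts$train, parts$validation,
                          seed = stage_seed(config$seed, stage))
      m2 <- confusion_metrics(parts$test$label,
                              method2_predict(tree, parts$test))
      write_tree_json(tree, out("baseline_method2.json"))
      summary$baselines <- list(
        method1_best_ACC = max(sweep$ACC),
        method1_best_threshold = sweep$threshold[which.max(sweep$ACC)],
        method2_prune_level = tree$prune_level, method2_ACC = m2$ACC)
      log <- log_stage(log, stage, "method1 sweep (", nrow(sweep),
                       " thresholds), method2 prune level ",
                       tree$prune_level)
    }

    if (!is.null(config$sensitivity)) {
      stage <- "sensitivity"
      for (nm in names(config$sensitivity)) {
        surf <- classification_sensitivity_surface(
          cohort, config$sensitivity[[nm]],
          variant = config$sensitivity_variant,
          seed = stage_seed(config$seed, "classify"))
        write_surface_csv(surf, out(sprintf("sensitivity_%s.csv", nm)))
        zero <- surf[surf$dm == 0 & surf$dn == 0 & surf$dM == 0 &
                       surf$dN == 0 & surf$phi == 0, ]
        summary$sensitivity[[nm]] <- list(cells = nrow(surf),
                                          baseline_ACC = zero$ACC)
        log <- log_stage(log, stage, nm, ": ", nrow(surf),
                         " cells -> sensitivity_", nm, ".csv")
      }
    }
    summary
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(result, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  writeLines(log, out("run_log.txt"))
  invisible(result)
}

# stable text formatting so byte-identical reruns are achievable
format_features <- function(feats) {
  feats$w1 <- sprintf("%.10g", feats$w1)  # >= 6 significant digits
  feats$w3 <- sprintf("%.10g", feats$w3)
  feats
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `features`, `classify`, `baseline`,
#' `sensitivity`, `run-all`. Common flags: `--seed` (mandatory),
#' `--output-dir`, `--cohort-dir` (use a serialized cohort instead of
#' simulating), `--n-healthy`, `--n-patient`, `--group`, `--variant`,
#' `--config` (JSON file overriding cohort counts and lists). Exits with
#' status 0 on success and 1 with a stage-tagged message otherwise.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
thyrotex_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: thyrotex <simulate|features|classify|baseline|sensitivity|",
    "run-all> --seed INT --output-dir DIR [--cohort-dir DIR]",
    "[--n-healthy INT] [--n-patient INT] [--group G ...] [--variant V ...]",
    "[--config FILE.json]")
  status <- tryCatch({
    if (length(args) < 1L) stop(usage)
    cmd <- args[1L]
    opts <- parse_cli_options(args[-1L])
    if (is.null(opts$seed)) stop("--seed is mandatory\n", usage)
    seed <- as.integer(opts$seed)
    outdir <- opts[["output-dir"]]
    if (is.null(outdir)) stop("--output-dir is mandatory\n", usage)
    cfg_file <- if (!is.null(opts$config))
      jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
    n_healthy <- as.integer(opts[["n-healthy"]] %||%
                              cfg_file$n_healthy %||% 30L)
    n_patient <- as.integer(opts[["n-patient"]] %||%
                              cfg_file$n_patient %||% 30L)
    groups <- opts$group %||% cfg_file$groups %||%
      c("LO", "RO", "LRO", "LD", "RD", "RLD", "RLOD")
    variants <- opts$variant %||% cfg_file$variants %||%
      discriminant_variants
    cohort <- if (!is.null(opts[["cohort-dir"]])) opts[["cohort-dir"]]
              else cohort_config(n_healthy, n_patient, seed = seed)
    switch(cmd,
      simulate = {
        write_cohort(resolve_cohort(cohort, seed), outdir)
        message("cohort written to ", outdir)
      },
      features = {
        feats <- extract_cohort_features(resolve_cohort(cohort, seed))
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        write.csv(format_features(feats),
                  file.path(outdir, "features.csv"),
                  row.names = FALSE, quote = FALSE)
      },
      classify = run_experiment(experiment_config(
        cohort, groups = groups, variants = variants, baselines = FALSE,
        sensitivity = NULL, seed = seed, output_dir = outdir)),
      baseline = run_experiment(experiment_config(
        cohort, classification = FALSE, sensitivity = NULL, seed = seed,
        output_dir = outdir)),
      sensitivity = run_experiment(experiment_config(
        cohort, classification = FALSE, baselines = FALSE, seed = seed,
        output_dir = outdir)),
      `run-all` = run_experiment(experiment_config(
        cohort, groups = groups, variants = variants, seed = seed,
        output_dir = outdir)),
      stop("unknown subcommand '", cmd, "'\n", usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value")
    val <- args[i + 1L]
    opts[[key]] <- c(opts[[key]], val)
    i <- i + 2L
  }
  opts
}
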