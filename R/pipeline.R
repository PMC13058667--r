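# End-to-end orchestration: simulate or ingest, prep, correlate, fit the
# model ladder, adjudicate, and validate against external correlates, all
# from one config, with a reproducibility manifest.

#' Ladder of competing structural models for the preset roster
#'
#' Named model texts of increasing elaboration for the 39-diagnosis preset:
#' a single general factor, a 4-factor model with a combined
#' internalizing/externalizing layout, a 5-factor model separating Substance
#' Use, the 6-factor correlated model, the 6-factor model with the preset
#' correlated residuals (the preferred refinement), and the bifactor
#' counterpart of the 6-factor model.
#'
#' @param config A [generator_config()] with the preset factor structure
#'   (default [six_factor_preset()] labels).
#' @return Named character vector of model texts, parseable by
#'   [parse_model()].
#' @export
model_ladder <- function(config = six_factor_preset(n_persons = 100)) {
  L <- config$loadings
  members <- lapply(colnames(L), function(f) rownames(L)[L[, f] != 0])
  names(members) <- colnames(L)
  line <- function(f, inds) paste0(f, " =~ ", paste(inds, collapse = " + "))
  ladder <- c(
    m1_general = line("General", unlist(members, use.names = FALSE)),
    m2_int_ext_thought_neuro = paste(
      line("Internalizing", c(members$Fear, members$Distress)),
      line("Externalizing", c(members$Externalizing, members$SubstanceUse)),
      line("ThoughtProblems", members$ThoughtProblems),
      line("Neurodevelopmental", members$Neurodevelopmental), sep = "\n"),
    m3_five_factor = paste(
      line("Internalizing", c(members$Fear, members$Distress)),
      line("Externalizing", members$Externalizing),
      line("SubstanceUse", members$SubstanceUse),
      line("ThoughtProblems", members$ThoughtProblems),
      line("Neurodevelopmental", members$Neurodevelopmental), sep = "\n"),
    m4_six_factor = paste(
      vapply(names(members), function(f) line(f, members[[f]]), character(1)),
      collapse = "\n"),
    m5_six_factor_residuals = config_model_text(config),
    m6_bifactor = paste(
      paste(vapply(names(members), function(f) line(f, members[[f]]),
                   character(1)), collapse = "\n"),
      "general: on", sep = "\n"))
  ladder
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, cohort prep, tetrachoric estimation, the model
#' ladder, model comparison, adjudication (split-half, permutation null,
#' optional leave-one-out), and external-correlate validation, writing every
#' artifact plus a reproducibility manifest to `out_dir`. Re-running with the
#' same config and seed reproduces all numeric outputs exactly.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   * `mode`: `"synthetic"` (default) or `"matrix"`;
#'   * `generator`: for synthetic mode, a [generator_config()] or the string
#'     `"six_factor_preset"`; `n_persons` optionally overrides the preset size;
#'   * `matrix_file`: for matrix mode, a TSV with `person_id` + 0/1 columns;
#'   * `ladder`: named character vector of model texts or file paths
#'     (default [model_ladder()]); the last entry is treated as preferred;
#'   * `adjudication`: list with `K` (permutations, default 100), `split_seed`,
#'     `bootstrap_B` (0 disables bootstrap SEs), `loo` (logical);
#'   * `external`: logical, regress correlates (synthetic mode only);
#'   * `out_dir`, `seed`.
#' @return The manifest (list, also written as YAML), invisibly the full
#'   results environment in attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("psychspectra_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  adj <- utils::modifyList(
    list(K = 100L, split_seed = seed + 1L, bootstrap_B = 0L, loo = FALSE),
    config$adjudication %||% list())
  manifest <- list(seed = seed, out_dir = out_dir, stages = list(),
                   package_version = as.character(utils::packageVersion("psychspectra")))
  stage <- function(name, expr) {
    res <- tryCatch(list(value = force(expr), status = "ok"),
                    error = function(e) list(value = NULL,
                                             status = paste("error:", conditionMessage(e))))
    manifest$stages[[name]] <<- res$status
    if (res$status != "ok")
      stop("pipeline stage '", name, "' failed: ", res$status, call. = FALSE)
    res$value
  }

  # --- input stage -----------------------------------------------------
  mode <- config$mode %||% "synthetic"
  truth <- NULL
  correlates <- NULL
  if (mode == "synthetic") {
    gen <- config$generator %||% "six_factor_preset"
    if (is.character(gen) && gen == "six_factor_preset")
      gen <- six_factor_preset(n_persons = config$n_persons %||% 20000,
                               seed = seed)
    sim <- stage("simulate", simulate_dataset(gen, events = TRUE))
    dx <- stage("prep", {
      collapsed <- collapse_codes(sim$events, sim$cluster_map)
      filter_cohort(collapsed)
    })
    truth <- sim$truth
    correlates <- sim$correlates
    readr_write <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    readr_write(sim$cluster_map, "cluster_map.tsv")
    readr_write(utils::head(sim$events, 1000), "events_head.tsv")
    if (!is.null(correlates)) readr_write(correlates, "correlates.tsv")
  } else if (mode == "matrix") {
    dx <- stage("ingest", {
      tab <- utils::read.delim(config$matrix_file, check.names = FALSE)
      filter_cohort(tibble::as_tibble(tab))
    })
  } else stop("unknown mode: ", mode, call. = FALSE)
  utils::write.table(dx, file.path(out_dir, "diagnosis_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- correlation stage ----------------------------------------------
  tet <- stage("tetrachoric", suppressMessages(tetrachoric(dx)))
  utils::write.table(round(tet$rho, 6), file.path(out_dir, "tetrachoric.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(diagnosis = names(tet$tau), tau = round(tet$tau, 6),
               prevalence = round(tet$prevalence, 6)),
    file.path(out_dir, "thresholds.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- model ladder ----------------------------------------------------
  ladder <- config$ladder %||% (if (mode == "synthetic" &&
                                      inherits(gen, "generator_config"))
    model_ladder(gen) else stop("config$ladder required for matrix mode",
                                call. = FALSE))
  ladder <- vapply(ladder, function(x) {
    if (file.exists(x)) paste(readLines(x), collapse = "\n") else x
  }, character(1))
  if (!length(ladder)) stop("model ladder is empty", call. = FALSE)
  fits <- stage("fit_ladder",
                lapply(ladder, function(tx) fit_cfa(tet, model = tx)))
  comparison <- stage("compare", compare_models(fits))
  utils::write.table(comparison, file.path(out_dir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  preferred_name <- names(fits)[length(fits)]
  preferred <- fits[[preferred_name]]
  if (adj$bootstrap_B > 0) {
    boot <- stage("bootstrap",
                  bootstrap_se(dx, preferred$model, B = adj$bootstrap_B,
                               seed = seed + 7L))
    preferred <- with_se(preferred, boot)
  }
  utils::write.table(tidy.cfa_fit(preferred),
                     file.path(out_dir, "preferred_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(alt_indices(preferred),
                     file.path(out_dir, "alt_indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- adjudication ----------------------------------------------------
  nulls <- NULL
  if (adj$K > 0) {
    nulls <- stage("permutation_null",
                   random_assignment_null(tet, preferred$model, K = adj$K,
                                          seed = seed + 2L,
                                          observed_fit = preferred))
    utils::write.table(nulls$draws, file.path(out_dir, "null_draws.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sh <- stage("split_half",
              suppressMessages(split_half(dx, lapply(ladder, parse_model),
                                          seed = adj$split_seed)))
  utils::write.table(sh$per_model, file.path(out_dir, "split_half.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loo <- NULL
  if (isTRUE(adj$loo)) {
    loo <- stage("loo", loo_scan(tet, preferred$model))
    utils::write.table(round(loo$delta, 6), file.path(out_dir, "loo_delta.tsv"),
                       sep = "\t", quote = FALSE)
  }

  # --- external correlates ---------------------------------------------
  ext <- NULL
  if (!is.null(correlates) && isTRUE(config$external %||% TRUE)) {
    ext <- stage("external", {
      sc <- factor_scores(preferred, dx, tet$tau)
      reg <- regress_correlates(sc, correlates,
                                B = max(adj$bootstrap_B, 100L),
                                seed = seed + 3L)
      list(scores = sc, reg = reg, tests = profile_difference_test(reg))
    })
    utils::write.table(ext$reg$coefficients,
                       file.path(out_dir, "correlate_coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ext$tests, file.path(out_dir, "profile_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest$n_persons <- nrow(dx)
  manifest$n_diagnoses <- ncol(dx) - 1L
  manifest$ladder_models <- names(ladder)
  manifest$preferred <- preferred_name
  manifest$indices_preferred <- lapply(
    preferred$indices[c("cfi", "tli", "rmsea", "srmr")],
    function(v) round(v, 10))
  if (requireNamespace("digest", quietly = TRUE)) {
    manifest$digests <- list(
      diagnosis_matrix = digest::digest(dx),
      tetrachoric = digest::digest(round(tet$rho, 10)),
      comparison = digest::digest(round(comparison$f_value, 10)))
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results <- list(data = dx, tetra = tet, fits = fits,
                  comparison = comparison, preferred = preferred,
                  nulls = nulls, split_half = sh, loo = loo,
                  external = ext, truth = truth)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Write a small deterministic fixture family
#'
#' Generates the fixtures used by the test suite: a 2,000-person preset
#' dataset (events, cluster map, binary matrix, correlates, truth config), a
#' set of toy 2x2 tables (including the balanced independence table), and
#' toy model files. Byte-identical under the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the list of written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- six_factor_preset(n_persons = 2000, seed = seed)
  sim <- simulate_dataset(cfg, events = TRUE)
  w <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(out_dir, f)
  }
  paths <- c(
    w(sim$diagnoses, "preset_diagnoses.tsv"),
    w(sim$events, "preset_events.tsv"),
    w(sim$cluster_map, "preset_cluster_map.tsv"),
    w(sim$correlates, "preset_correlates.tsv"),
    w(tibble::tibble(
      table = c("independence", "positive", "perfect"),
      n00 = c(25, 40, 50), n01 = c(25, 10, 0),
      n10 = c(25, 10, 0), n11 = c(25, 40, 50)), "toy_tables.tsv"))
  truth_doc <- list(
    seed = seed, n_persons = cfg$n_persons,
    loadings = apply(cfg$loadings, 1, function(r) as.list(r), simplify = FALSE),
    factor_corr = apply(cfg$factor_corr, 1, as.list, simplify = FALSE),
    prevalences = as.list(cfg$prevalences),
    residual_corr = if (!is.null(cfg$residual_corr))
      apply(cfg$residual_corr, 1, as.list, simplify = FALSE))
  yaml::write_yaml(truth_doc, file.path(out_dir, "preset_truth.yaml"))
  model_file <- file.path(out_dir, "toy_models.txt")
  writeLines(c("F1 =~ a + b + c", "F2 =~ d + e + f", "a ~~ d"), model_file)
  invisible(c(paths, file.path(out_dir, "preset_truth.yaml"), model_file))
}
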