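# Model adjudication beyond conventional fit indices: alternative indices
# (loading magnitude / consistency / precision), side-by-side model
# comparison, random diagnosis-to-factor assignment nulls, split-half
# replication with intraclass correlations, leave-one-out loading
# sensitivity, and a refit-based candidate-parameter scan.

#' Alternative adjudication indices
#'
#' Per-factor summaries of the standardized loadings: *magnitude* (median
#' absolute loading), *consistency* (sample SD of the loadings), and
#' *precision* (mean bootstrap SE, when SEs are attached via [with_se()]).
#' Cross-loadings are attributed to every factor they load on. Pooled
#' versions (median / SD / mean SE over all loadings) are appended as factor
#' `".pooled"`.
#'
#' @param fit A `cfa_fit` (optionally with bootstrap SEs attached).
#' @return A tibble with `factor`, `n_loadings`, `magnitude`, `consistency`
#'   (`NA` with a flag for factors with < 2 loadings), `precision` (`NA` if
#'   SEs are unavailable), `flag`.
#' @export
alt_indices <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  td <- tidy.cfa_fit(fit)
  if (!"se" %in% names(td)) td$se <- NA_real_
  per_factor <- td |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      n_loadings = dplyr::n(),
      magnitude = stats::median(abs(.data$loading)),
      consistency = if (dplyr::n() >= 2) stats::sd(.data$loading) else NA_real_,
      precision = if (all(is.na(.data$se))) NA_real_
                  else mean(.data$se, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n_loadings < 2 ~ "SD undefined (< 2 loadings)",
      is.na(.data$precision) ~ "no SEs attached",
      TRUE ~ NA_character_))
  pooled <- tibble::tibble(
    factor = ".pooled", n_loadings = nrow(td),
    magnitude = stats::median(abs(td$loading)),
    consistency = stats::sd(td$loading),
    precision = if (all(is.na(td$se))) NA_real_ else mean(td$se, na.rm = TRUE),
    flag = if (all(is.na(td$se))) "no SEs attached" else NA_character_)
  dplyr::bind_rows(per_factor, pooled)
}

#' Compare fitted models side by side
#'
#' One row per model: conventional fit indices, pooled alternative indices,
#' and per-index ranks. No single winner is declared; adjudication is
#' multi-criterion by design.
#'
#' @param fits Named list of `cfa_fit` objects fitted to the same correlation
#'   matrix and sample size (checked).
#' @return A tibble with one row per model and rank columns
#'   (`rank_cfi`, ... — rank 1 is best: highest CFI/TLI/FL, lowest
#'   RMSEA/SRMR).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, logical(1), "cfa_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model_", seq_along(fits))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1)
    stop("fits use different sample sizes", call. = FALSE)
  common <- sort(Reduce(intersect, lapply(fits, function(f) colnames(f$R))))
  for (f in fits) {
    Rf <- f$R[common, common]
    R1 <- fits[[1]]$R[common, common]
    if (max(abs(Rf - R1)) > 1e-12)
      stop("fits are based on different correlation matrices", call. = FALSE)
  }
  rows <- purrr::imap(fits, function(f, nm) {
    pooled <- alt_indices(f) |> dplyr::filter(.data$factor == ".pooled")
    tibble::tibble(model = nm, cfi = f$indices$cfi, tli = f$indices$tli,
                   rmsea = f$indices$rmsea, srmr = f$indices$srmr,
                   fl = pooled$magnitude, sd = pooled$consistency,
                   se = pooled$precision,
                   df = f$df, f_value = f$F_value, converged = f$converged)
  })
  out <- dplyr::bind_rows(rows)
  out$rank_cfi <- rank(-out$cfi, ties.method = "min")
  out$rank_tli <- rank(-out$tli, ties.method = "min")
  out$rank_rmsea <- rank(out$rmsea, ties.method = "min")
  out$rank_srmr <- rank(out$srmr, ties.method = "min")
  out$rank_fl <- rank(-out$fl, ties.method = "min")
  out
}

#' Random diagnosis-to-factor assignment null distributions
#'
#' Generates `K` variants of the model in which diagnoses are randomly
#' reassigned to factors while preserving the factor-size multiset
#' (optionally unconstrained), drops cross-loadings and residual pairs, fits
#' each variant to the same correlation matrix, and reports null
#' distributions of every index together with the observed model's
#' percentile.
#'
#' @param R A `tetra_result` or correlation matrix.
#' @param model The observed `cfa_model` (or text).
#' @param K Number of random assignments (>= 0).
#' @param seed Integer seed (reproducible end to end).
#' @param n Sample size (defaults to the `tetra_result`'s).
#' @param preserve_sizes Keep the factor-size multiset (default `TRUE`).
#' @param observed_fit Optional precomputed `cfa_fit` of `model` (avoids a
#'   refit).
#' @return An object of class `null_result`: `draws` (tibble of per-null
#'   indices and pooled alternative indices, non-converged fits flagged),
#'   `observed` (one-row tibble), `percentiles` (named vector, percent of
#'   converged nulls at or below the observed value per index; `NA` when
#'   `K = 0`), `n_nonconverged`, `K`.
#' @export
random_assignment_null <- function(R, model, K, seed = 1L, n = NULL,
                                   preserve_sizes = TRUE,
                                   observed_fit = NULL) {
  if (is.character(model)) model <- parse_model(model)
  if (inherits(R, "tetra_result")) {
    if (is.null(n)) n <- R$n
    R <- R$rho
  }
  if (is.null(observed_fit))
    observed_fit <- fit_cfa(R, n = n, model = model)
  obs_pooled <- alt_indices(observed_fit) |>
    dplyr::filter(.data$factor == ".pooled")
  observed <- tibble::tibble(
    cfi = observed_fit$indices$cfi, tli = observed_fit$indices$tli,
    rmsea = observed_fit$indices$rmsea, srmr = observed_fit$indices$srmr,
    fl = obs_pooled$magnitude, sd = obs_pooled$consistency)

  sizes <- lengths(model$factors)
  fac_names <- names(model$factors)
  indicators <- model$indicators[!duplicated(model$indicators)]
  # nulls use each indicator once (primary assignments only)
  inds <- names(model$primary)
  set.seed(seed)
  draws <- vector("list", K)
  n_fail <- 0L
  for (k in seq_len(K)) {
    if (preserve_sizes) {
      perm <- sample(inds)
      assign_f <- rep(fac_names, times = sizes[fac_names])
    } else {
      assign_f <- sample(fac_names, length(inds), replace = TRUE)
      perm <- inds
      # every factor needs >= 1 indicator for identification
      while (length(unique(assign_f)) < length(fac_names))
        assign_f <- sample(fac_names, length(inds), replace = TRUE)
    }
    null_factors <- split(perm, factor(assign_f, levels = fac_names))
    text <- paste(vapply(fac_names, function(f)
      paste0(f, " =~ ", paste(null_factors[[f]], collapse = " + ")),
      character(1)), collapse = "\n")
    if (model$bifactor) text <- paste(text, "general: on", sep = "\n")
    fit_k <- tryCatch(fit_cfa(R, n = n, model = parse_model(text)),
                      error = function(e) NULL)
    if (is.null(fit_k)) {
      n_fail <- n_fail + 1L
      draws[[k]] <- tibble::tibble(draw = k, converged = FALSE,
                                   cfi = NA_real_, tli = NA_real_,
                                   rmsea = NA_real_, srmr = NA_real_,
                                   fl = NA_real_, sd = NA_real_,
                                   heywood = NA_integer_)
      next
    }
    pooled_k <- alt_indices(fit_k) |> dplyr::filter(.data$factor == ".pooled")
    if (!fit_k$converged) n_fail <- n_fail + 1L
    draws[[k]] <- tibble::tibble(
      draw = k, converged = fit_k$converged,
      cfi = fit_k$indices$cfi, tli = fit_k$indices$tli,
      rmsea = fit_k$indices$rmsea, srmr = fit_k$indices$srmr,
      fl = pooled_k$magnitude, sd = pooled_k$consistency,
      heywood = nrow(fit_k$heywood))
  }
  draws <- if (K > 0) dplyr::bind_rows(draws) else
    tibble::tibble(draw = integer(0), converged = logical(0),
                   cfi = numeric(0), tli = numeric(0), rmsea = numeric(0),
                   srmr = numeric(0), fl = numeric(0), sd = numeric(0),
                   heywood = integer(0))
  ok <- draws[draws$converged %in% TRUE, , drop = FALSE]
  pct <- function(obs, null_vals) {
    if (!length(null_vals)) return(NA_real_)
    100 * mean(null_vals <= obs)
  }
  percentiles <- c(
    cfi = pct(observed$cfi, ok$cfi), tli = pct(observed$tli, ok$tli),
    rmsea = pct(observed$rmsea, ok$rmsea),
    srmr = pct(observed$srmr, ok$srmr),
    fl = pct(observed$fl, ok$fl), sd = pct(observed$sd, ok$sd))
  structure(list(draws = draws, observed = observed,
                 percentiles = percentiles,
                 n_nonconverged = n_fail, K = K,
                 preserve_sizes = preserve_sizes),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat("<null_result> K = ", x$K, " random assignments (",
      x$n_nonconverged, " non-converged)\n", sep = "")
  print(round(x$percentiles, 1))
  invisible(x)
}

#' Two-way absolute-agreement single-measure intraclass correlation
#'
#' ICC(A,1) from the two-way mean-squares decomposition: both measurement
#' vectors are treated as raters of the same targets, and disagreement in
#' level is penalised (absolute agreement).
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return A single ICC value; `NA` (with a warning) when both vectors are
#'   constant.
#' @export
icc_absolute <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  k <- 2
  dat <- cbind(x, y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("both vectors are constant; ICC undefined", call. = FALSE)
    return(NA_real_)
  }
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  mse <- (sum((dat - outer(row_means, rep(1, k)) -
                 outer(rep(1, n), col_means) + grand)^2)) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Split-half replication of model fits
#'
#' Randomly partitions persons into two disjoint halves (sizes differing by
#' at most 1), runs the full pipeline (tetrachoric estimation, smoothing,
#' fitting) in each half for every model, and reports per model the absolute
#' fit-index differences between halves and the intraclass correlation
#' (ICC(A,1), [icc_absolute()]) of the loading vectors. With two or more
#' models, per-index ICCs across models are also computed. Diagnoses
#' degenerate in either half are dropped from both halves (and the models)
#' with a report.
#'
#' @param data Binary diagnosis tibble or matrix (n >= 4).
#' @param models Named list of `cfa_model` objects or model texts.
#' @param seed Integer seed for the partition.
#' @return An object of class `split_half_result`: `per_model` (tibble:
#'   model, loading ICC, per-index values in each half and |difference|),
#'   `index_icc` (tibble, when >= 2 models), `dropped` (diagnoses removed),
#'   `n_half` (sizes).
#' @export
split_half <- function(data, models, seed = 1L) {
  m <- dx_matrix(data)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 persons", call. = FALSE)
  if (!is.list(models)) models <- list(model = models)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- paste0("model_", seq_along(models))
  models <- lapply(models, function(x) if (is.character(x)) parse_model(x) else x)
  set.seed(seed)
  perm <- sample.int(n)
  half1 <- sort(perm[seq_len(floor(n / 2))])
  half2 <- sort(perm[seq(floor(n / 2) + 1, n)])
  m1 <- m[half1, , drop = FALSE]
  m2 <- m[half2, , drop = FALSE]

  prev1 <- colMeans(m1); prev2 <- colMeans(m2)
  degen <- prev1 <= 0 | prev1 >= 1 | prev2 <= 0 | prev2 >= 1
  dropped <- colnames(m)[degen]
  if (length(dropped)) {
    rlang::inform(paste0("dropping diagnoses degenerate in a half: ",
                         paste(dropped, collapse = ", ")))
    m1 <- m1[, !degen, drop = FALSE]
    m2 <- m2[, !degen, drop = FALSE]
    models <- lapply(models, drop_indicators, dropped)
  }
  t1 <- suppressMessages(tetrachoric(m1))
  t2 <- suppressMessages(tetrachoric(m2))

  per_model <- purrr::imap(models, function(mod, nm) {
    f1 <- fit_cfa(t1, model = mod)
    f2 <- fit_cfa(t2, model = mod)
    l1 <- f1$lambda[f1$layout$P]
    l2 <- f2$lambda[f2$layout$P]
    tibble::tibble(
      model = nm,
      loading_icc = icc_absolute(l1, l2),
      cfi_1 = f1$indices$cfi, cfi_2 = f2$indices$cfi,
      tli_1 = f1$indices$tli, tli_2 = f2$indices$tli,
      rmsea_1 = f1$indices$rmsea, rmsea_2 = f2$indices$rmsea,
      srmr_1 = f1$indices$srmr, srmr_2 = f2$indices$srmr,
      cfi_diff = abs(f1$indices$cfi - f2$indices$cfi),
      tli_diff = abs(f1$indices$tli - f2$indices$tli),
      rmsea_diff = abs(f1$indices$rmsea - f2$indices$rmsea),
      srmr_diff = abs(f1$indices$srmr - f2$indices$srmr),
      converged = f1$converged && f2$converged)
  }) |> dplyr::bind_rows()

  index_icc <- NULL
  if (nrow(per_model) >= 2) {
    index_icc <- tibble::tibble(
      index = c("cfi", "tli", "rmsea", "srmr"),
      icc = c(icc_absolute(per_model$cfi_1, per_model$cfi_2),
              icc_absolute(per_model$tli_1, per_model$tli_2),
              icc_absolute(per_model$rmsea_1, per_model$rmsea_2),
              icc_absolute(per_model$srmr_1, per_model$srmr_2)))
  }
  structure(list(per_model = per_model, index_icc = index_icc,
                 dropped = dropped,
                 n_half = c(length(half1), length(half2)),
                 half_ids = list(half1 = half1, half2 = half2)),
            class = "split_half_result")
}

# remove indicators from a model (used when a half has degenerate margins or
# for leave-one-out refits)
drop_indicators <- function(model, drop) {
  factors <- lapply(model$factors, setdiff, y = drop)
  factors <- factors[lengths(factors) > 0]
  rp <- model$residual_pairs
  rp <- rp[!(rp$a %in% drop | rp$b %in% drop), , drop = FALSE]
  text <- paste(c(
    vapply(names(factors), function(f)
      paste0(f, " =~ ", paste(factors[[f]], collapse = " + ")), character(1)),
    if (nrow(rp)) paste0(rp$a, " ~~ ", rp$b),
    if (model$bifactor) "general: on"), collapse = "\n")
  parse_model(text)
}

#' Leave-one-out loading sensitivity
#'
#' Refits the model with each diagnosis removed in turn and records the
#' signed change in every remaining diagnosis's primary loading. Because the
#' tetrachoric matrix is estimated pairwise, removal only subsets the
#' correlation matrix; no re-estimation of correlations is needed. Removals
#' that would leave any factor with fewer than 2 indicators are skipped with
#' a flag.
#'
#' @param R A `tetra_result` or correlation matrix.
#' @param model `cfa_model` or text.
#' @param n Sample size (defaults to the `tetra_result`'s).
#' @return An object of class `loo_result`: `delta` (d x d matrix, cell
#'   `(j, k)` = change in j's primary loading when k is removed, diagonal and
#'   skipped columns `NA`), `skipped` (named reasons), `summary` (signed
#'   mean, median, SD, min, max over defined cells).
#' @export
loo_scan <- function(R, model, n = NULL) {
  if (is.character(model)) model <- parse_model(model)
  if (inherits(R, "tetra_result")) {
    if (is.null(n)) n <- R$n
    R <- R$rho
  }
  base <- fit_cfa(R, n = n, model = model)
  inds <- model$indicators
  d <- length(inds)
  primary_loading <- function(fit) {
    vapply(fit$model$indicators, function(j)
      fit$lambda[j, fit$model$primary[j]], numeric(1))
  }
  base_load <- primary_loading(base)
  delta <- matrix(NA_real_, d, d, dimnames = list(inds, inds))
  skipped <- character(0)
  for (k in inds) {
    sizes_after <- lengths(lapply(model$factors, setdiff, y = k))
    if (any(sizes_after < 2)) {
      skipped[k] <- "a factor would retain < 2 indicators"
      next
    }
    red_model <- drop_indicators(model, k)
    fit_k <- tryCatch(
      fit_cfa(R[red_model$indicators, red_model$indicators],
              n = n, model = red_model),
      error = function(e) NULL)
    if (is.null(fit_k) || !fit_k$converged) {
      skipped[k] <- "reduced fit did not converge"
      next
    }
    lk <- primary_loading(fit_k)
    keep <- intersect(names(lk), names(base_load))
    delta[keep, k] <- lk[keep] - base_load[keep]
  }
  vals <- delta[!is.na(delta)]
  structure(list(
    delta = delta, skipped = skipped,
    summary = tibble::tibble(mean = mean(vals), median = stats::median(vals),
                             sd = stats::sd(vals), min = min(vals),
                             max = max(vals), n_cells = length(vals))),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> ", nrow(x$delta), " diagnoses, ",
      length(x$skipped), " removal(s) skipped\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Refit-based candidate-parameter scan
#'
#' For each candidate cross-loading or residual pair, refits the model with
#' that single parameter freed (warm-started at the base solution, so the
#' discrepancy can only improve) and reports the discrepancy drop, index
#' changes, and the freed parameter's estimate, ranked by discrepancy drop.
#' No candidate is accepted automatically.
#'
#' @param R A `tetra_result` or correlation matrix.
#' @param model Base `cfa_model` or text.
#' @param candidates Tibble with columns `type` (`"cross"` or `"residual"`),
#'   `a` (indicator), `b` (factor name for `"cross"`, second indicator for
#'   `"residual"`).
#' @param n Sample size (defaults to the `tetra_result`'s).
#' @return A tibble ranked by `delta_f` (>= 0 by construction) with columns
#'   `type`, `a`, `b`, `delta_f`, `delta_cfi`, `delta_rmsea`, `delta_srmr`,
#'   `estimate`, `flag` (`"redundant"` for already-free parameters,
#'   `"skipped"` when freeing would exhaust df).
#' @export
candidate_scan <- function(R, model, candidates, n = NULL) {
  if (is.character(model)) model <- parse_model(model)
  if (inherits(R, "tetra_result")) {
    if (is.null(n)) n <- R$n
    R <- R$rho
  }
  candidates <- tibble::as_tibble(candidates)
  stopifnot(all(c("type", "a", "b") %in% names(candidates)))
  base <- fit_cfa(R, n = n, model = model)
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    type <- candidates$type[i]; a <- candidates$a[i]; b <- candidates$b[i]
    redundant <- switch(type,
      cross = b %in% names(model$factors) && a %in% model$factors[[b]],
      residual = any((model$residual_pairs$a == min(a, b) &
                        model$residual_pairs$b == max(a, b))),
      stop("unknown candidate type: ", type, call. = FALSE))
    if (redundant) {
      rows[[i]] <- tibble::tibble(type = type, a = a, b = b, delta_f = 0,
                                  delta_cfi = 0, delta_rmsea = 0,
                                  delta_srmr = 0, estimate = NA_real_,
                                  flag = "redundant")
      next
    }
    if (model$df - 1 <= 0) {
      rows[[i]] <- tibble::tibble(type = type, a = a, b = b,
                                  delta_f = NA_real_, delta_cfi = NA_real_,
                                  delta_rmsea = NA_real_, delta_srmr = NA_real_,
                                  estimate = NA_real_, flag = "skipped (df)")
      next
    }
    new_text <- if (type == "cross") {
      add_cross_to_text(model$text, indicator = a, factor = b)
    } else {
      paste(model$text, paste0(a, " ~~ ", b), sep = "\n")
    }
    fit_i <- tryCatch(
      fit_cfa(R, n = n, model = parse_model(new_text),
              extra_starts = list(augment_theta(base, type, a, b))),
      error = function(e) NULL)
    if (is.null(fit_i)) {
      rows[[i]] <- tibble::tibble(type = type, a = a, b = b,
                                  delta_f = NA_real_, delta_cfi = NA_real_,
                                  delta_rmsea = NA_real_, delta_srmr = NA_real_,
                                  estimate = NA_real_, flag = "skipped (fit error)")
      next
    }
    est <- if (type == "cross") fit_i$lambda[a, b] else {
      rp <- fit_i$residuals
      rp$estimate[rp$a == min(a, b) & rp$b == max(a, b)]
    }
    rows[[i]] <- tibble::tibble(
      type = type, a = a, b = b,
      delta_f = max(base$F_value - fit_i$F_value, 0),
      delta_cfi = fit_i$indices$cfi - base$indices$cfi,
      delta_rmsea = fit_i$indices$rmsea - base$indices$rmsea,
      delta_srmr = fit_i$indices$srmr - base$indices$srmr,
      estimate = est, flag = NA_character_)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$delta_f))
}

# append an indicator to a factor's "=~" line in model text
add_cross_to_text <- function(text, indicator, factor) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- paste0("^\\s*", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", factor),
                "\\s*=~")
  hit <- grepl(pat, lines)
  if (!any(hit)) stop("no factor named '", factor, "' in model", call. = FALSE)
  lines[hit] <- paste0(lines[hit], " + ", indicator)
  paste(lines, collapse = "\n")
}

# warm start for a one-parameter extension: base solution + 0 for the new
# parameter, mapped into the augmented model's layout by name
augment_theta <- function(base, type, a, b) {
  layout <- base$layout
  if (type == "residual") {
    # the appended pair parses into residual_pairs in line order, i.e. last
    c(base$lambda[layout$lam_idx],
      if (layout$n_phi) base$phi[layout$phi_idx] else numeric(0),
      base$residuals$estimate, 0)
  } else {
    model2 <- parse_model(add_cross_to_text(base$model$text, a, b))
    layout2 <- model_layout(model2)
    # base$lambda already has 0 in the new pattern cell
    c(base$lambda[layout2$lam_idx],
      if (layout2$n_phi) base$phi[layout2$phi_idx] else numeric(0),
      base$residuals$estimate)
  }
}
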