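# Confirmatory factor analysis on a tetrachoric correlation matrix.
#
# Models are written in a small SEM-style text language:
#   Fear =~ agoraphobia + panic disorder + OCD
#   Distress =~ MDD + dysthymia
#   MDD ~~ dysthymia          (correlated residual)
#   general: on               (bifactor: adds an orthogonal general factor)
#
# Fitting minimises the (weighted) least-squares discrepancy
#   F(theta) = sum_{i<j} w_ij (r_ij - sigma_ij(theta))^2
# over standardized loadings, factor correlations, and residual correlations,
# with uniquenesses solved so the implied diagonal is exactly 1. ULS (w = 1)
# is the default; DWLS uses reciprocal estimated sampling variances.

#' Parse a factor model specification
#'
#' @param text Model text: one `Factor =~ a + b + c` line per factor,
#'   `a ~~ b` lines for correlated residuals, and an optional `general: on`
#'   directive that adds a general factor loading on every indicator (all
#'   factors then mutually orthogonal — the bifactor convention). An
#'   indicator appearing on more than one factor line is a cross-loading; its
#'   primary factor is the first line on which it appears.
#' @param check_df Error when the model has negative degrees of freedom
#'   (default `TRUE`). Disable for under-identified toy specifications used
#'   only with [implied_matrix()] or [factor_scores()], which do not require
#'   an identified model; [fit_cfa()] always re-checks.
#' @return An object of class `cfa_model` with elements `factors` (named list
#'   of indicator vectors), `indicators` (order of first appearance),
#'   `primary` (named map indicator -> primary factor), `cross` (tibble of
#'   cross-loadings), `residual_pairs` (tibble `a`, `b`), `bifactor`, `npar`,
#'   `df`.
#' @export
parse_model <- function(text, check_df = TRUE) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", lines)
  factors <- list()
  pairs <- list()
  bifactor <- FALSE
  for (li in seq_along(lines)) {
    line <- trimws(lines[li])
    if (!nzchar(line)) next
    if (grepl("^general\\s*:", line)) {
      val <- trimws(sub("^general\\s*:", "", line))
      if (!val %in% c("on", "off"))
        stop(sprintf("line %d: 'general:' must be 'on' or 'off'", li),
             call. = FALSE)
      bifactor <- val == "on"
    } else if (grepl("=~", line, fixed = TRUE)) {
      parts <- strsplit(line, "=~", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        stop(sprintf("line %d: malformed factor definition", li), call. = FALSE)
      fname <- trimws(parts[1])
      inds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      inds <- inds[nzchar(inds)]
      if (!nzchar(fname) || !length(inds))
        stop(sprintf("line %d: malformed factor definition", li), call. = FALSE)
      if (fname %in% names(factors))
        stop(sprintf("line %d: duplicate factor name '%s'", li, fname),
             call. = FALSE)
      if (anyDuplicated(inds))
        stop(sprintf("line %d: duplicate indicator on factor '%s'", li, fname),
             call. = FALSE)
      factors[[fname]] <- inds
    } else if (grepl("~~", line, fixed = TRUE)) {
      parts <- trimws(strsplit(line, "~~", fixed = TRUE)[[1]])
      if (length(parts) != 2 || !all(nzchar(parts)))
        stop(sprintf("line %d: malformed residual correlation", li),
             call. = FALSE)
      pairs[[length(pairs) + 1L]] <- sort(parts)
    } else {
      stop(sprintf("line %d: cannot parse '%s'", li, line), call. = FALSE)
    }
  }
  if (!length(factors)) stop("model defines no factors", call. = FALSE)
  if (bifactor && "general" %in% names(factors))
    stop("'general' is reserved for the bifactor general factor", call. = FALSE)

  indicators <- unique(unlist(factors, use.names = FALSE))
  primary <- stats::setNames(rep(NA_character_, length(indicators)), indicators)
  cross <- list()
  for (f in names(factors)) {
    for (ind in factors[[f]]) {
      if (is.na(primary[ind])) {
        primary[ind] <- f
      } else {
        cross[[length(cross) + 1L]] <- tibble::tibble(indicator = ind,
                                                     factor = f)
      }
    }
  }
  cross <- if (length(cross)) dplyr::bind_rows(cross)
           else tibble::tibble(indicator = character(0), factor = character(0))

  if (length(pairs)) {
    keys <- vapply(pairs, paste, character(1), collapse = " ~~ ")
    if (anyDuplicated(keys))
      stop("duplicate residual correlation: ",
           keys[duplicated(keys)][1], call. = FALSE)
    rp <- tibble::tibble(a = vapply(pairs, `[`, character(1), 1),
                         b = vapply(pairs, `[`, character(1), 2))
    if (any(rp$a == rp$b))
      stop("residual correlation of an indicator with itself", call. = FALSE)
  } else {
    rp <- tibble::tibble(a = character(0), b = character(0))
  }

  d <- length(indicators)
  q <- length(factors)
  n_loadings <- sum(lengths(factors)) + if (bifactor) d else 0L
  n_phi <- if (bifactor) 0L else (q * (q - 1L)) %/% 2L
  npar <- n_loadings + n_phi + nrow(rp)
  df <- (d * (d - 1L)) %/% 2L - npar
  if (check_df && df < 0)
    stop(sprintf("model is not identified: df = %d (npar = %d, moments = %d)",
                 df, npar, (d * (d - 1L)) %/% 2L), call. = FALSE)

  structure(list(factors = factors, indicators = indicators, primary = primary,
                 cross = cross, residual_pairs = rp, bifactor = bifactor,
                 npar = npar, df = df,
                 text = paste(lines, collapse = "\n")),
            class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat("<cfa_model> ", length(x$factors), " factor(s)",
      if (x$bifactor) " + general (bifactor)", ", ",
      length(x$indicators), " indicators, ",
      nrow(x$residual_pairs), " residual pair(s); npar = ", x$npar,
      ", df = ", x$df, "\n", sep = "")
  invisible(x)
}

# Parameter layout: loadings over the pattern (column-major, specific factors
# in declaration order then the general factor), free factor correlations
# (lower triangle, column-major; none for bifactor), residual correlations in
# pair order.
model_layout <- function(model) {
  d <- length(model$indicators)
  fac_names <- names(model$factors)
  if (model$bifactor) fac_names <- c(fac_names, "general")
  q <- length(fac_names)
  P <- matrix(FALSE, d, q, dimnames = list(model$indicators, fac_names))
  for (f in names(model$factors)) P[model$factors[[f]], f] <- TRUE
  if (model$bifactor) P[, "general"] <- TRUE
  lam_idx <- which(P)
  phi_idx <- if (model$bifactor || q == 1) {
    matrix(integer(0), 0, 2)
  } else {
    which(lower.tri(matrix(0, q, q)), arr.ind = TRUE)
  }
  res_idx <- cbind(match(model$residual_pairs$a, model$indicators),
                   match(model$residual_pairs$b, model$indicators))
  list(d = d, q = q, P = P, lam_idx = lam_idx, phi_idx = phi_idx,
       res_idx = res_idx,
       n_lam = length(lam_idx), n_phi = nrow(phi_idx), n_res = nrow(res_idx))
}

unpack_params <- function(theta, layout) {
  L <- matrix(0, layout$d, layout$q,
              dimnames = dimnames(layout$P))
  L[layout$lam_idx] <- theta[seq_len(layout$n_lam)]
  Phi <- diag(1, layout$q)
  dimnames(Phi) <- list(colnames(layout$P), colnames(layout$P))
  if (layout$n_phi) {
    v <- theta[layout$n_lam + seq_len(layout$n_phi)]
    Phi[layout$phi_idx] <- v
    Phi[layout$phi_idx[, c(2, 1), drop = FALSE]] <- v
  }
  res <- if (layout$n_res)
    theta[layout$n_lam + layout$n_phi + seq_len(layout$n_res)] else numeric(0)
  list(L = L, Phi = Phi, res = res)
}

#' Model-implied correlation matrix
#'
#' Computes `Sigma = Lambda Phi Lambda' + Theta` with uniquenesses set so the
#' diagonal is exactly 1 and residual correlations placed on their
#' off-diagonal cells.
#'
#' @param model A `cfa_model`.
#' @param params A list with `lambda` (full `d x q` loading matrix, entries
#'   outside the model's pattern ignored), optional `phi` (factor correlation
#'   matrix; identity if omitted or bifactor), and optional `residuals`
#'   (vector in the order of `model$residual_pairs`).
#' @return The implied correlation matrix with attribute `uniqueness`.
#' @export
implied_matrix <- function(model, params) {
  layout <- model_layout(model)
  L <- matrix(0, layout$d, layout$q, dimnames = dimnames(layout$P))
  lam_in <- params$lambda
  if (is.null(lam_in)) stop("params$lambda is required", call. = FALSE)
  lam_in <- as.matrix(lam_in)
  if (!is.null(rownames(lam_in)))
    lam_in <- lam_in[model$indicators, , drop = FALSE]
  stopifnot(nrow(lam_in) == layout$d, ncol(lam_in) == layout$q)
  L[layout$P] <- lam_in[layout$P]
  Phi <- if (is.null(params$phi)) diag(1, layout$q) else as.matrix(params$phi)
  S <- L %*% Phi %*% t(L)
  uniq <- 1 - diag(S)
  if (layout$n_res) {
    res <- params$residuals %||% rep(0, layout$n_res)
    S[layout$res_idx] <- S[layout$res_idx] + res
    S[layout$res_idx[, c(2, 1), drop = FALSE]] <- S[layout$res_idx]
  }
  diag(S) <- 1
  dimnames(S) <- list(model$indicators, model$indicators)
  attr(S, "uniqueness") <- stats::setNames(uniq, model$indicators)
  S
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: sigma and discrepancy machinery shared by fit and scans
make_objective <- function(R, W, layout, penalty = 1e3) {
  d <- layout$d
  force(R); force(W)
  obj <- function(theta) {
    p <- unpack_params(theta, layout)
    LP <- p$L %*% p$Phi
    S <- LP %*% t(p$L)
    h <- diag(S)
    if (layout$n_res) {
      S[layout$res_idx] <- S[layout$res_idx] + p$res
      S[layout$res_idx[, c(2, 1), drop = FALSE]] <- S[layout$res_idx]
    }
    diag(S) <- 1
    Dm <- S - R
    diag(Dm) <- 0
    f <- 0.5 * sum(W * Dm * Dm)
    # soft admissibility bounds: communality <= 1, |phi| <= 0.999
    pen <- penalty * sum(pmax(h - 1, 0)^2)
    if (layout$n_phi) {
      ph <- p$Phi[layout$phi_idx]
      pen <- pen + penalty * sum(pmax(abs(ph) - 0.999, 0)^2)
    }
    f + pen
  }
  grad <- function(theta) {
    p <- unpack_params(theta, layout)
    LP <- p$L %*% p$Phi
    S <- LP %*% t(p$L)
    h <- diag(S)
    if (layout$n_res) {
      S[layout$res_idx] <- S[layout$res_idx] + p$res
      S[layout$res_idx[, c(2, 1), drop = FALSE]] <- S[layout$res_idx]
    }
    diag(S) <- 1
    Dm <- W * (S - R)
    diag(Dm) <- 0
    gL <- 2 * Dm %*% LP
    hb <- pmax(h - 1, 0)
    if (any(hb > 0)) gL <- gL + penalty * 4 * hb * LP
    g <- gL[layout$lam_idx]
    if (layout$n_phi) {
      Gphi <- 2 * t(p$L) %*% Dm %*% p$L
      gphi <- Gphi[layout$phi_idx]
      if (any(hb > 0)) {
        Lh <- p$L * (penalty * 4 * hb)
        extra <- t(Lh) %*% p$L
        gphi <- gphi + extra[layout$phi_idx]
      }
      ph <- p$Phi[layout$phi_idx]
      pb <- pmax(abs(ph) - 0.999, 0)
      gphi <- gphi + penalty * 2 * pb * sign(ph)
      g <- c(g, gphi)
    }
    if (layout$n_res) {
      g <- c(g, 2 * Dm[layout$res_idx])
    }
    g
  }
  discrepancy <- function(theta) {
    p <- unpack_params(theta, layout)
    S <- p$L %*% p$Phi %*% t(p$L)
    if (layout$n_res) {
      S[layout$res_idx] <- S[layout$res_idx] + p$res
      S[layout$res_idx[, c(2, 1), drop = FALSE]] <- S[layout$res_idx]
    }
    diag(S) <- 1
    Dm <- S - R
    diag(Dm) <- 0
    list(F = 0.5 * sum(W * Dm * Dm), sigma = S, resid = R - S)
  }
  list(obj = obj, grad = grad, discrepancy = discrepancy)
}

#' Fit a factor model to a tetrachoric correlation matrix
#'
#' Minimises the weighted least-squares discrepancy between the observed and
#' model-implied correlations, from several deterministic starting points,
#' and reports the standardized solution (unit-variance factors), a
#' pseudo-chi-square `T = (n - 1) * F` (comparative, not calibrated), and the
#' fit indices CFI, TLI, RMSEA, SRMR against the zero-correlation null model.
#'
#' @param R A `tetra_result` or a correlation matrix with diagnosis labels.
#' @param n Sample size used for index scaling; defaults to the `tetra_result`
#'   sample size.
#' @param model A `cfa_model` (or model text, parsed on the fly).
#' @param estimator `"uls"` (unit weights, default) or `"dwls"` (weights are
#'   reciprocal `weights` variances, e.g. from [pair_variances()]).
#' @param weights For `"dwls"`: a `d x d` matrix of estimated sampling
#'   variances of the correlations.
#' @param n_starts Number of deterministic starting points (loadings on a
#'   0.3-0.7 grid, factor correlations at 0.3, residuals at 0).
#' @param extra_starts Optional list of full parameter vectors prepended to
#'   the start list (used for warm starts in nested refits).
#' @param control Passed to [stats::nlminb()] (iteration cap 2000 by default).
#' @return An object of class `cfa_fit`.
#' @export
fit_cfa <- function(R, n = NULL, model, estimator = c("uls", "dwls"),
                    weights = NULL, n_starts = 5, extra_starts = NULL,
                    control = list()) {
  estimator <- match.arg(estimator)
  if (is.character(model)) model <- parse_model(model)
  if (inherits(R, "tetra_result")) {
    if (is.null(n)) n <- R$n
    R <- R$rho
  }
  if (is.null(n) || n <= 1) stop("`n` (> 1) is required", call. = FALSE)
  missing_ind <- setdiff(model$indicators, colnames(R))
  if (length(missing_ind))
    stop("indicators absent from the correlation matrix: ",
         paste(missing_ind, collapse = ", "), call. = FALSE)
  R <- R[model$indicators, model$indicators]
  layout <- model_layout(model)
  if (model$df < 0)
    stop("model has negative degrees of freedom (df = ", model$df, ")",
         call. = FALSE)

  W <- matrix(1, layout$d, layout$d)
  if (estimator == "dwls") {
    if (is.null(weights))
      stop("estimator 'dwls' needs a `weights` variance matrix", call. = FALSE)
    weights <- weights[model$indicators, model$indicators]
    W <- 1 / pmax(weights, 1e-10)
  }
  diag(W) <- 0

  machinery <- make_objective(R, W, layout)
  start_grid <- seq(0.3, 0.7, length.out = max(n_starts, 1))
  starts <- lapply(start_grid, function(s)
    c(rep(s, layout$n_lam), rep(0.3, layout$n_phi), rep(0, layout$n_res)))
  starts <- c(extra_starts, starts)

  ctrl <- utils::modifyList(list(iter.max = 2000, eval.max = 5000,
                                 rel.tol = 1e-14), control)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, machinery$obj, gradient = machinery$grad,
                    control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  theta <- best$par
  gnorm <- max(abs(machinery$grad(theta)))
  # nlminb's own code is conservative (relative-convergence stops report
  # non-zero); accept a solution whose scaled gradient is numerically flat
  converged <- best$convergence == 0 ||
    gnorm < 1e-5 * (1 + abs(best$objective))

  p <- unpack_params(theta, layout)
  # resolve sign indeterminacy: each factor's loading sum non-negative
  for (k in seq_len(layout$q)) {
    if (sum(p$L[, k]) < 0) {
      p$L[, k] <- -p$L[, k]
      p$Phi[k, ] <- -p$Phi[k, ]
      p$Phi[, k] <- -p$Phi[, k]
      diag(p$Phi) <- 1
    }
  }
  theta <- pack_params(p, layout)

  disc <- machinery$discrepancy(theta)
  Fhat <- disc$F
  h <- rowSums((p$L %*% p$Phi) * p$L)
  uniqueness <- 1 - h
  heywood <- tibble::tibble(
    indicator = model$indicators[h >= 1 - 1e-8 | apply(abs(p$L), 1, max) > 1],
  )
  F_null <- {
    Dm <- R; diag(Dm) <- 0
    0.5 * sum(W * Dm * Dm)
  }
  d <- layout$d
  df_null <- (d * (d - 1L)) %/% 2L
  T_stat <- (n - 1) * Fhat
  T_null <- (n - 1) * F_null
  resid_off <- disc$resid[upper.tri(disc$resid)]
  idx <- if (model$df > 0) {
    fit_indices(T_stat, model$df, T_null, df_null, n, resid_off)
  } else {
    # just-identified model: incremental indices are trivially perfect
    list(cfi = 1, tli = NA_real_, rmsea = 0,
         srmr = sqrt(mean(resid_off^2)), degenerate_null = T_null <= df_null)
  }

  structure(
    list(model = model, lambda = p$L, phi = p$Phi,
         residuals = dplyr::mutate(model$residual_pairs, estimate = p$res),
         uniqueness = stats::setNames(uniqueness, model$indicators),
         F_value = Fhat, T_stat = T_stat, df = model$df,
         T_null = T_null, df_null = df_null,
         indices = idx, n = n, estimator = estimator,
         converged = converged, grad_norm = gnorm,
         heywood = heywood, R = R, sigma = disc$sigma,
         resid_matrix = disc$resid, theta = theta, layout = layout,
         se = NULL),
    class = "cfa_fit")
}

pack_params <- function(p, layout) {
  c(p$L[layout$lam_idx],
    if (layout$n_phi) p$Phi[layout$phi_idx] else numeric(0),
    p$res)
}

#' Conventional fit indices for a correlation-structure model
#'
#' Implements CFI, TLI (truncated to `[0, 1]`), RMSEA and SRMR from the
#' pseudo-chi-square of the fitted model and of the zero-correlation null
#' model. The pseudo-chi-square `T = (n - 1) F` is comparative, not
#' calibrated; indices are intended for model comparison.
#'
#' @param T_stat,df Fitted model pseudo-chi-square and degrees of freedom.
#' @param T_null,df_null Null (zero off-diagonal correlations) counterparts.
#' @param n Sample size.
#' @param residuals Vector (or matrix) of `r_ij - sigma_hat_ij` over the
#'   unique off-diagonal cells, for SRMR.
#' @return A list with `cfi`, `tli`, `rmsea`, `srmr`, `degenerate_null`.
#' @export
fit_indices <- function(T_stat, df, T_null, df_null, n, residuals) {
  stopifnot(df > 0, df_null > 0, n > 1)
  if (is.matrix(residuals)) residuals <- residuals[upper.tri(residuals)]
  degenerate <- T_null <= df_null
  cfi <- 1 - max(T_stat - df, 0) / max(T_null - df_null, T_stat - df, 0)
  if (!is.finite(cfi)) cfi <- 1  # both excesses zero: saturated-vs-null tie
  tli <- ((T_null / df_null) - (T_stat / df)) / ((T_null / df_null) - 1)
  tli <- min(max(tli, 0), 1)
  if (degenerate) tli <- NA_real_
  rmsea <- sqrt(max(T_stat - df, 0) / (df * (n - 1)))
  srmr <- sqrt(mean(residuals^2))
  list(cfi = min(max(cfi, 0), 1), tli = tli, rmsea = rmsea, srmr = srmr,
       degenerate_null = degenerate)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("<cfa_fit> ", length(x$model$factors), " factor(s)",
      if (x$model$bifactor) " + general", ", d = ", nrow(x$lambda),
      ", n = ", x$n, ", estimator = ", x$estimator, "\n", sep = "")
  cat(sprintf("  F = %.6g, T = %.4g (df = %d), CFI = %.4f, TLI = %.4f, RMSEA = %.4f, SRMR = %.4f\n",
              x$F_value, x$T_stat, x$df, x$indices$cfi,
              if (is.na(x$indices$tli)) NA else x$indices$tli,
              x$indices$rmsea, x$indices$srmr))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (nrow(x$heywood)) cat("  Heywood flags:",
                           paste(x$heywood$indicator, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy loadings of a fitted model
#'
#' @param x A `cfa_fit`.
#' @param ... Unused.
#' @return A tibble with `indicator`, `factor`, `loading`, `primary` (is this
#'   the indicator's primary factor), and `se` when bootstrap standard errors
#'   have been attached.
#' @export
tidy.cfa_fit <- function(x, ...) {
  layout <- x$layout
  pos <- which(layout$P, arr.ind = TRUE)
  out <- tibble::tibble(
    indicator = rownames(layout$P)[pos[, 1]],
    factor = colnames(layout$P)[pos[, 2]],
    loading = x$lambda[pos],
    primary = x$model$primary[rownames(layout$P)[pos[, 1]]] ==
      colnames(layout$P)[pos[, 2]])
  out$primary[is.na(out$primary)] <- FALSE
  if (!is.null(x$se)) {
    key <- paste(out$indicator, out$factor)
    sekey <- paste(x$se$loading_se$indicator, x$se$loading_se$factor)
    out$se <- x$se$loading_se$se[match(key, sekey)]
  }
  out
}

#' One-row fit summary
#'
#' @param x A `cfa_fit`.
#' @param ... Unused.
#' @return A tibble with the fit indices, discrepancy, pseudo-chi-square,
#'   degrees of freedom, convergence and Heywood flags.
#' @export
glance.cfa_fit <- function(x, ...) {
  tibble::tibble(cfi = x$indices$cfi, tli = x$indices$tli,
                 rmsea = x$indices$rmsea, srmr = x$indices$srmr,
                 f_value = x$F_value, t_stat = x$T_stat, df = x$df,
                 npar = x$model$npar, n = x$n,
                 converged = x$converged, n_heywood = nrow(x$heywood))
}

#' Jackknife-of-batches sampling variances of tetrachoric correlations
#'
#' Splits persons into `n_batches` deterministic batches, re-estimates the
#' tetrachoric matrix leaving one batch out at a time, and returns the
#' delete-one-group jackknife variance for every pair — the weight source for
#' the DWLS estimator.
#'
#' @param data Binary diagnosis tibble or matrix.
#' @param n_batches Number of batches (default 20).
#' @return A `d x d` symmetric matrix of variance estimates (diagonal 0).
#' @export
pair_variances <- function(data, n_batches = 20) {
  m <- dx_matrix(data)
  n <- nrow(m)
  G <- min(n_batches, n)
  batch <- rep(seq_len(G), length.out = n)
  reps <- lapply(seq_len(G), function(g)
    suppressMessages(tetrachoric(m[batch != g, , drop = FALSE],
                                 smooth = FALSE))$rho)
  Rbar <- Reduce(`+`, reps) / G
  V <- Reduce(`+`, lapply(reps, function(Rg) (Rg - Rbar)^2)) * (G - 1) / G
  diag(V) <- 0
  V
}

#' Bootstrap standard errors for a fitted model
#'
#' Person-level nonparametric bootstrap: each of `B` resamples with
#' replacement is pushed through the full pipeline (tetrachoric estimation,
#' PSD smoothing, model fit), factor signs are aligned to the point estimate,
#' and the SE is the SD across converged resamples. More than 20%
#' non-convergence raises an error unless `allow_nonconverged = TRUE`.
#'
#' @param data Binary diagnosis tibble or matrix (cohort-filtered).
#' @param model A `cfa_model` or model text.
#' @param B Number of bootstrap resamples (>= 2; default 100).
#' @param seed Integer seed.
#' @param estimator,weights Passed to [fit_cfa()].
#' @param allow_nonconverged Keep going past 20% non-convergence.
#' @return An object of class `cfa_boot`: `loading_se` (tibble), `phi_se`,
#'   `residual_se`, `index_se`, `replicates` (B x npar matrix of aligned
#'   parameter vectors, `NA` rows for failures), `n_converged`, `B`.
#' @export
bootstrap_se <- function(data, model, B = 100, seed = 1L,
                         estimator = "uls", weights = NULL,
                         allow_nonconverged = FALSE) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (is.character(model)) model <- parse_model(model)
  m <- dx_matrix(data)
  point <- fit_cfa(suppressMessages(tetrachoric(m)), n = nrow(m), model,
                   estimator = estimator, weights = weights)
  layout <- point$layout
  set.seed(seed)
  idx_mat <- matrix(sample.int(nrow(m), nrow(m) * B, replace = TRUE),
                    nrow(m), B)
  reps <- matrix(NA_real_, B, length(point$theta))
  idx_reps <- matrix(NA_real_, B, 4,
                     dimnames = list(NULL, c("cfi", "tli", "rmsea", "srmr")))
  for (b in seq_len(B)) {
    mb <- m[idx_mat[, b], , drop = FALSE]
    fitb <- tryCatch({
      prev <- colMeans(mb)
      if (any(prev <= 0 | prev >= 1)) stop("degenerate resample margin")
      fit_cfa(suppressMessages(tetrachoric(mb)), n = nrow(mb), model,
              estimator = estimator, weights = weights,
              extra_starts = list(point$theta), n_starts = 1)
    }, error = function(e) NULL)
    if (is.null(fitb) || !fitb$converged) next
    pb <- unpack_params(fitb$theta, layout)
    # align factor signs to the point estimate
    for (k in seq_len(layout$q)) {
      if (sum(pb$L[, k] * point$lambda[, k]) < 0) {
        pb$L[, k] <- -pb$L[, k]
        pb$Phi[k, ] <- -pb$Phi[k, ]
        pb$Phi[, k] <- -pb$Phi[, k]
        diag(pb$Phi) <- 1
      }
    }
    reps[b, ] <- pack_params(pb, layout)
    idx_reps[b, ] <- c(fitb$indices$cfi, fitb$indices$tli,
                       fitb$indices$rmsea, fitb$indices$srmr)
  }
  ok <- !is.na(reps[, 1])
  if (mean(!ok) > 0.2 && !allow_nonconverged)
    stop(sprintf("%.0f%% of bootstrap resamples failed to converge",
                 100 * mean(!ok)), call. = FALSE)
  se_vec <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  pos <- which(layout$P, arr.ind = TRUE)
  loading_se <- tibble::tibble(
    indicator = rownames(layout$P)[pos[, 1]],
    factor = colnames(layout$P)[pos[, 2]],
    se = se_vec[seq_len(layout$n_lam)])
  phi_se <- if (layout$n_phi) {
    tibble::tibble(
      factor_a = colnames(layout$P)[layout$phi_idx[, 2]],
      factor_b = colnames(layout$P)[layout$phi_idx[, 1]],
      se = se_vec[layout$n_lam + seq_len(layout$n_phi)])
  } else tibble::tibble(factor_a = character(0), factor_b = character(0),
                        se = numeric(0))
  residual_se <- dplyr::mutate(
    model$residual_pairs,
    se = if (layout$n_res)
      se_vec[layout$n_lam + layout$n_phi + seq_len(layout$n_res)]
    else numeric(0))
  structure(
    list(loading_se = loading_se, phi_se = phi_se, residual_se = residual_se,
         index_se = apply(idx_reps[ok, , drop = FALSE], 2, stats::sd),
         replicates = reps, n_converged = sum(ok), B = B,
         point = point),
    class = "cfa_boot")
}

#' Attach bootstrap standard errors to a fit
#'
#' @param fit A `cfa_fit`.
#' @param boot A `cfa_boot` computed for the same model.
#' @return The fit with `se` populated (used by [tidy.cfa_fit()] and
#'   [alt_indices()]).
#' @export
with_se <- function(fit, boot) {
  stopifnot(inherits(fit, "cfa_fit"), inherits(boot, "cfa_boot"))
  fit$se <- boot
  fit
}
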