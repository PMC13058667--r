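# External validation: maximum-a-posteriori factor scores under the probit
# measurement model implied by the fitted loadings and thresholds, simple
# regressions of external correlates on the standardized scores, and a
# Wald-type test that association profiles differ across dimensions.

#' Maximum-a-posteriori factor scores
#'
#' For each person, maximises the posterior
#' `N(eta; 0, Phi) * prod_j P(y_j | eta)` under the probit measurement model
#' `P(y_j = 1 | eta) = pnorm((Lambda_j eta - tau_j) / sqrt(uniqueness_j))`
#' by damped Newton iterations (the probit log-likelihood is concave, so the
#' optimum is unique). Persons sharing a response pattern share a score, so
#' the optimisation runs once per distinct pattern.
#'
#' @param fit A converged `cfa_fit`.
#' @param data Binary diagnosis tibble or matrix covering the model's
#'   indicators.
#' @param tau Named threshold vector (`qnorm(1 - prevalence)`), e.g. from a
#'   `tetra_result`.
#' @param max_iter,tol Newton iteration cap (50) and step-norm tolerance
#'   (1e-8).
#' @return A tibble with `person_id`, one column per factor (liability
#'   scale), and `converged` (per person).
#' @export
factor_scores <- function(fit, data, tau, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(fit, "cfa_fit"))
  m <- dx_matrix(data)
  inds <- fit$model$indicators
  missing_ind <- setdiff(inds, colnames(m))
  if (length(missing_ind))
    stop("data lacks indicators: ", paste(missing_ind, collapse = ", "),
         call. = FALSE)
  Y <- m[, inds, drop = FALSE]
  tau <- tau[inds]
  if (anyNA(tau)) stop("tau must be named for every indicator", call. = FALSE)
  u <- pmax(fit$uniqueness[inds], 1e-4)
  A <- fit$lambda / sqrt(u)          # d x q, rows scaled
  bvec <- tau / sqrt(u)
  q <- ncol(A)
  Phi_inv <- solve(fit$phi + diag(1e-10, q))

  pat_key <- apply(Y, 1, paste, collapse = "")
  first <- !duplicated(pat_key)
  Yu <- Y[first, , drop = FALSE]
  nu <- nrow(Yu)
  S <- 2 * Yu - 1                    # signs
  eta <- matrix(0, nu, q)
  conv <- rep(FALSE, nu)

  log_post <- function(E) {
    Z <- E %*% t(A) - matrix(bvec, nrow(E), length(bvec), byrow = TRUE)
    ll <- rowSums(stats::pnorm(S * Z, log.p = TRUE))
    ll - 0.5 * rowSums((E %*% Phi_inv) * E)
  }
  lp <- log_post(eta)
  for (it in seq_len(max_iter)) {
    Z <- eta %*% t(A) - matrix(bvec, nu, length(bvec), byrow = TRUE)
    ZS <- S * Z
    mills <- exp(stats::dnorm(ZS, log = TRUE) -
                   stats::pnorm(ZS, log.p = TRUE))
    G <- (S * mills) %*% A - eta %*% Phi_inv
    Wt <- mills * (mills + ZS)       # -d2 loglik / dz2, >= 0
    step <- matrix(0, nu, q)
    active <- which(!conv)
    if (!length(active)) break
    for (i in active) {
      H <- Phi_inv + crossprod(A * sqrt(pmax(Wt[i, ], 0)))
      step[i, ] <- tryCatch(solve(H, G[i, ]), error = function(e) G[i, ] * 0.1)
    }
    # damped update with step halving on posterior decrease
    alpha <- rep(1, nu)
    for (half in 1:20) {
      cand <- eta + alpha * step
      lp_new <- log_post(cand)
      bad <- which(lp_new < lp - 1e-12 & !conv)
      if (!length(bad)) break
      alpha[bad] <- alpha[bad] / 2
    }
    cand <- eta + alpha * step
    lp <- log_post(cand)
    moved <- sqrt(rowSums((cand - eta)^2))
    eta <- cand
    conv <- conv | moved < tol
    if (all(conv)) break
  }
  if (!all(conv))
    rlang::inform(paste0(sum(!conv), " pattern(s) hit the iteration cap; ",
                         "best iterate used"))
  scores_u <- eta
  idx <- match(pat_key, pat_key[first])
  scores <- scores_u[idx, , drop = FALSE]
  colnames(scores) <- colnames(fit$lambda)
  pid <- if (!is.null(rownames(m))) rownames(m) else
    sprintf("P%06d", seq_len(nrow(m)))
  out <- tibble::tibble(person_id = pid)
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  out$converged <- conv[idx]
  out
}

# fast probit regression coefficient (value ~ score) via glm.fit
probit_coef <- function(y, x) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(link = "probit"),
                   control = list(maxit = 50)))
  fit$coefficients[2]
}

#' Regress external correlates on factor scores
#'
#' For each (correlate, factor) pair, a simple regression of the correlate on
#' that factor's standardized score: ordinary least squares for continuous
#' and ordinal (treated as numeric) correlates, probit regression for binary
#' ones. Standard errors and the across-factor coefficient covariance come
#' from a person-level bootstrap.
#'
#' @param scores Factor-score tibble from [factor_scores()].
#' @param correlates Long tibble with `person_id`, `correlate`, `value`,
#'   `type`.
#' @param B Bootstrap replicates for SEs/covariance (default 200).
#' @param seed Integer seed.
#' @return An object of class `correlate_reg`: `coefficients` (tibble:
#'   `correlate`, `factor`, `estimate`, `se`, `type`, `n`), `replicates`
#'   (named list of B x q coefficient matrices per correlate), `skipped`
#'   (zero-variance correlates).
#' @export
regress_correlates <- function(scores, correlates, B = 200, seed = 1L) {
  correlates <- tibble::as_tibble(correlates)
  stopifnot(all(c("person_id", "correlate", "value", "type") %in%
                  names(correlates)))
  fac_cols <- setdiff(names(scores), c("person_id", "converged"))
  X <- as.matrix(scores[fac_cols])
  # population-SD standardization: invariant under person duplication
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(X^2) - mu^2)
  Z <- sweep(sweep(X, 2, mu), 2, sd_pop, "/")
  rownames(Z) <- scores$person_id

  cor_names <- unique(correlates$correlate)
  skipped <- character(0)
  coef_rows <- list()
  replicates <- list()
  for (cn in cor_names) {
    sub <- correlates[correlates$correlate == cn, ]
    if (anyDuplicated(sub$person_id))
      stop("multiple values per person for correlate '", cn, "'",
           call. = FALSE)
    keep <- sub$person_id %in% rownames(Z)
    sub <- sub[keep, ]
    if (nrow(sub) < 30)
      stop("fewer than 30 overlapping persons for correlate '", cn, "'",
           call. = FALSE)
    y <- sub$value
    type <- sub$type[1]
    if (stats::var(y) == 0) {
      skipped <- c(skipped, cn)
      rlang::inform(paste0("correlate '", cn, "' has zero variance; skipped"))
      next
    }
    Xz <- Z[sub$person_id, , drop = FALSE]
    one_pass <- function(idx) {
      yy <- y[idx]
      XX <- Xz[idx, , drop = FALSE]
      if (type == "binary") {
        vapply(seq_along(fac_cols), function(k)
          probit_coef(yy, XX[, k]), numeric(1))
      } else {
        # OLS slope of y on each standardized score
        vapply(seq_along(fac_cols), function(k) {
          xk <- XX[, k]
          stats::cov(yy, xk) / stats::var(xk)
        }, numeric(1))
      }
    }
    est <- one_pass(seq_len(nrow(sub)))
    set.seed(stream_seed(seed, match(cn, cor_names)))
    reps <- matrix(NA_real_, B, length(fac_cols),
                   dimnames = list(NULL, fac_cols))
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(sub), replace = TRUE)
      reps[b, ] <- tryCatch(one_pass(idx), error = function(e)
        rep(NA_real_, length(fac_cols)))
    }
    ok <- stats::complete.cases(reps)
    replicates[[cn]] <- reps[ok, , drop = FALSE]
    coef_rows[[cn]] <- tibble::tibble(
      correlate = cn, factor = fac_cols, estimate = est,
      se = apply(reps[ok, , drop = FALSE], 2, stats::sd),
      type = type, n = nrow(sub))
  }
  structure(list(coefficients = dplyr::bind_rows(coef_rows),
                 replicates = replicates, skipped = skipped,
                 factors = fac_cols, B = B),
            class = "correlate_reg")
}

#' @export
print.correlate_reg <- function(x, ...) {
  cat("<correlate_reg> ", length(x$replicates), " correlate(s) x ",
      length(x$factors), " factor(s), B = ", x$B, "\n", sep = "")
  print(x$coefficients, n = 24)
  invisible(x)
}

#' Tidy correlate-regression coefficients
#'
#' @param x A `correlate_reg`.
#' @param ... Unused.
#' @return The coefficient tibble.
#' @export
tidy.correlate_reg <- function(x, ...) x$coefficients

#' Profile-difference test across dimensions
#'
#' For each correlate, a Wald-type chi-square test that the coefficients on
#' all factors are equal, using the bootstrap covariance of the coefficient
#' vector with successive-difference contrasts (the statistic is invariant to
#' factor ordering). A singular bootstrap covariance is handled by a
#' generalized inverse (flagged, degrees of freedom reduced to the rank).
#'
#' @param reg A `correlate_reg` from [regress_correlates()].
#' @return A tibble with `correlate`, `statistic`, `df`, `p_value`, `flag`,
#'   plus per-pair contrast tables in attribute `contrasts`.
#' @export
profile_difference_test <- function(reg) {
  stopifnot(inherits(reg, "correlate_reg"))
  q <- length(reg$factors)
  if (q < 2) stop("need at least two factors", call. = FALSE)
  C <- diff(diag(q))                     # successive differences, (q-1) x q
  rows <- list()
  contrasts <- list()
  for (cn in names(reg$replicates)) {
    theta <- reg$coefficients$estimate[reg$coefficients$correlate == cn]
    V <- stats::cov(reg$replicates[[cn]])
    d <- C %*% theta
    M <- C %*% V %*% t(C)
    qr_M <- qr(M)
    flag <- NA_character_
    if (qr_M$rank < nrow(M)) {
      flag <- "singular bootstrap covariance; generalized inverse"
      sv <- svd(M)
      pos <- sv$d > max(sv$d) * 1e-10
      Minv <- sv$v[, pos, drop = FALSE] %*%
        (1 / sv$d[pos] * t(sv$u[, pos, drop = FALSE]))
      df <- sum(pos)
    } else {
      Minv <- solve(M)
      df <- nrow(M)
    }
    stat <- drop(t(d) %*% Minv %*% d)
    rows[[cn]] <- tibble::tibble(
      correlate = cn, statistic = stat, df = df,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE), flag = flag)
    pair_idx <- utils::combn(q, 2)
    contrasts[[cn]] <- tibble::tibble(
      factor_a = reg$factors[pair_idx[1, ]],
      factor_b = reg$factors[pair_idx[2, ]],
      difference = theta[pair_idx[1, ]] - theta[pair_idx[2, ]],
      se = sqrt(pmax(V[cbind(pair_idx[1, ], pair_idx[1, ])] +
                       V[cbind(pair_idx[2, ], pair_idx[2, ])] -
                       2 * V[cbind(pair_idx[1, ], pair_idx[2, ])], 0)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "contrasts") <- contrasts
  out
}
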