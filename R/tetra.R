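# Tetrachoric correlation estimation: two-step ML (probit thresholds from the
# margins, then a 1-D likelihood maximisation over rho), pairwise over a
# binary diagnosis matrix, with PSD smoothing by alternating projections.

#' Tetrachoric correlation for a single 2x2 table
#'
#' Two-step maximum-likelihood estimate of the latent bivariate-normal
#' correlation underlying a 2x2 table of dichotomised outcomes. Thresholds are
#' fixed at the univariate probit estimates of the margins; `rho` maximises
#' the bivariate-normal likelihood of the four cell counts. Tables containing
#' a zero cell receive a continuity correction (`zero_cell_add` added to every
#' cell, margins recomputed) before estimation.
#'
#' The estimate is computed on a canonical orientation (non-negative sample
#' association) and sign-restored afterwards, so recoding either variable
#' (0 <-> 1) flips the sign of `rho` exactly.
#'
#' @param n00,n01,n10,n11 Cell counts: `nxy` is the number of observations
#'   with first variable `x` and second variable `y`.
#' @param zero_cell_add Continuity correction added to all cells when any cell
#'   is zero (default 0.5). Set to 0 to disable.
#' @param bound Estimates are clipped to `[-bound, bound]` (default 0.999).
#' @return A tibble with one row: `rho`, `tau_row`, `tau_col`, `converged`,
#'   `corrected` (logical: continuity correction applied), `message`.
#' @examples
#' tetrachoric_pair(25, 25, 25, 25) # independence, rho = 0
#' @export
tetrachoric_pair <- function(n00, n01, n10, n11, zero_cell_add = 0.5,
                             bound = 0.999) {
  cells <- c(n00, n01, n10, n11)
  if (any(cells < 0) || sum(cells) <= 0)
    stop("cell counts must be non-negative with a positive total", call. = FALSE)

  # Canonicalise before estimating so table symmetries are exact in floating
  # point: recoding a variable (0 <-> 1) flips the sign of rho bit-exactly,
  # and transposing the table (swapping the variables) leaves rho unchanged.
  if (n00 * n11 - n01 * n10 < 0) {
    # negative association: flip the column variable's coding and negate
    out <- tetrachoric_pair(n01, n00, n11, n10,
                            zero_cell_add = zero_cell_add, bound = bound)
    out$rho <- -out$rho
    out$tau_col <- -out$tau_col
    return(out)
  }
  if (n10 + n11 > n01 + n11) {
    # transpose orientation: row margin no larger than column margin
    out <- tetrachoric_pair(n00, n10, n01, n11,
                            zero_cell_add = zero_cell_add, bound = bound)
    tmp <- out$tau_row
    out$tau_row <- out$tau_col
    out$tau_col <- tmp
    return(out)
  }

  corrected <- FALSE
  if (any(cells == 0) && zero_cell_add > 0) {
    cells <- cells + zero_cell_add
    corrected <- TRUE
  }
  n00 <- cells[1]; n01 <- cells[2]; n10 <- cells[3]; n11 <- cells[4]
  ntot <- sum(cells)
  p_row <- (n10 + n11) / ntot  # P(first variable = 1)
  p_col <- (n01 + n11) / ntot  # P(second variable = 1)
  if (p_row <= 0 || p_row >= 1 || p_col <= 0 || p_col >= 1) {
    return(tibble::tibble(
      rho = NA_real_, tau_row = NA_real_, tau_col = NA_real_,
      converged = FALSE, corrected = corrected,
      message = "degenerate margin"))
  }
  tau_row <- stats::qnorm(1 - p_row)
  tau_col <- stats::qnorm(1 - p_col)
  pr <- stats::pnorm(-tau_row)
  pc <- stats::pnorm(-tau_col)

  if (n00 * n11 == n01 * n10) {
    # zero sample association: the MLE is exactly zero
    return(tibble::tibble(rho = 0, tau_row = tau_row, tau_col = tau_col,
                          converged = TRUE, corrected = corrected,
                          message = NA_character_))
  }

  negll <- function(rho) {
    p11 <- .bvn_upper(tau_row, tau_col, rho)
    p10 <- max(pr - p11, 0)
    p01 <- max(pc - p11, 0)
    p00 <- max(1 - p11 - p10 - p01, 0)
    -(n00 * log(max(p00, 1e-320)) + n01 * log(max(p01, 1e-320)) +
        n10 * log(max(p10, 1e-320)) + n11 * log(max(p11, 1e-320)))
  }

  opt <- tryCatch(
    stats::optimize(negll, interval = c(0, bound), tol = 1e-8),
    error = function(e) NULL)
  converged <- !is.null(opt)
  if (!converged) {
    # grid-search fallback over the admissible range
    grid <- seq(0, bound, by = 1e-3)
    vals <- vapply(grid, negll, numeric(1))
    rho_hat <- grid[which.min(vals)]
    msg <- "optimizer failed; grid-search fallback"
  } else {
    rho_hat <- opt$minimum
    # optimize() never samples the endpoints; check rho = 0 explicitly so the
    # independence case is exact
    if (negll(0) <= opt$objective) rho_hat <- 0
    msg <- NA_character_
  }
  rho_hat <- min(max(rho_hat, 0), bound)
  tibble::tibble(rho = rho_hat, tau_row = tau_row, tau_col = tau_col,
                 converged = converged, corrected = corrected,
                 message = msg)
}

# extract numeric person x diagnosis matrix from a tibble (person_id column
# optional) or a matrix
dx_matrix <- function(data) {
  if (is.matrix(data)) {
    m <- data
  } else {
    data <- tibble::as_tibble(data)
    cols <- setdiff(names(data), "person_id")
    m <- as.matrix(data[cols])
    if (!is.null(data[["person_id"]])) rownames(m) <- as.character(data$person_id)
  }
  storage.mode(m) <- "double"
  bad <- !(m %in% c(0, 1))
  if (any(bad)) stop("diagnosis matrix entries must be 0/1", call. = FALSE)
  m
}

#' Pairwise tetrachoric correlation matrix
#'
#' Estimates all pairwise tetrachoric correlations of a person-by-diagnosis
#' binary matrix, assembles them into a correlation matrix, and (by default)
#' smooths an indefinite result to the nearest positive-semidefinite
#' correlation matrix by alternating projections.
#'
#' Diagnoses with degenerate margins (prevalence 0 or 1) are excluded with a
#' report; the tetrachoric correlation is undefined for them.
#'
#' @param data A tibble with a `person_id` column plus one 0/1 column per
#'   diagnosis, or a plain 0/1 matrix with diagnosis column names.
#' @param smooth Smooth an indefinite matrix to PSD (default `TRUE`).
#' @param zero_cell_add Continuity correction for tables with empty cells.
#' @return An object of class `tetra_result`: a list with elements `rho`
#'   (correlation matrix), `tau` (named threshold vector,
#'   `qnorm(1 - prevalence)`), `prevalence`, `n` (persons), `pairs` (tibble of
#'   per-pair estimates and flags), `excluded` (character vector of degenerate
#'   diagnoses), `smoothed`, `min_eigen_before`, `min_eigen_after`.
#' @export
tetrachoric <- function(data, smooth = TRUE, zero_cell_add = 0.5) {
  m <- dx_matrix(data)
  if (ncol(m) < 2) stop("need at least two diagnoses", call. = FALSE)
  prev <- colMeans(m)
  degenerate <- prev <= 0 | prev >= 1
  excluded <- colnames(m)[degenerate]
  if (length(excluded))
    rlang::inform(paste0("excluding ", length(excluded),
                         " diagnosis(es) with degenerate margins: ",
                         paste(excluded, collapse = ", ")))
  m <- m[, !degenerate, drop = FALSE]
  if (ncol(m) < 2)
    stop("fewer than two diagnoses with non-degenerate margins", call. = FALSE)
  d <- ncol(m)
  n <- nrow(m)
  labels <- colnames(m)
  prev <- colMeans(m)
  tau <- stats::qnorm(1 - prev)

  # sufficient statistics: all pairwise 2x2 tables from cross-products
  x11 <- crossprod(m)                 # joint 1/1 counts
  ones <- colSums(m)
  R <- diag(1, d)
  dimnames(R) <- list(labels, labels)
  pair_rows <- vector("list", d * (d - 1) / 2)
  idx <- 0L
  for (i in seq_len(d - 1)) {
    for (j in seq(i + 1, d)) {
      n11 <- x11[i, j]
      n10 <- ones[i] - n11
      n01 <- ones[j] - n11
      n00 <- n - n11 - n10 - n01
      est <- tetrachoric_pair(n00, n01, n10, n11,
                              zero_cell_add = zero_cell_add)
      R[i, j] <- R[j, i] <- est$rho
      idx <- idx + 1L
      pair_rows[[idx]] <- tibble::tibble(
        row = labels[i], col = labels[j], rho = est$rho,
        n00 = n00, n01 = n01, n10 = n10, n11 = n11,
        converged = est$converged, corrected = est$corrected)
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  if (anyNA(R)) stop("tetrachoric estimation failed for some pair", call. = FALSE)

  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min_before <- min(ev)
  smoothed <- FALSE
  min_after <- min_before
  if (smooth && min_before < -1e-10) {
    R <- nearest_pd(R)
    smoothed <- TRUE
    min_after <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  }
  structure(
    list(rho = R, tau = stats::setNames(tau, labels),
         prevalence = stats::setNames(prev, labels), n = n, pairs = pairs,
         excluded = excluded, smoothed = smoothed,
         min_eigen_before = min_before, min_eigen_after = min_after),
    class = "tetra_result")
}

#' @export
print.tetra_result <- function(x, ...) {
  cat("<tetra_result> ", ncol(x$rho), " diagnoses, n = ", x$n,
      if (x$smoothed) " (smoothed)" else "", "\n", sep = "")
  cat("  min eigenvalue: ", format(x$min_eigen_before, digits = 4),
      " -> ", format(x$min_eigen_after, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a tetrachoric result into a long pair table
#'
#' @param x A `tetra_result`.
#' @param ... Unused.
#' @return A tibble with one row per unordered diagnosis pair: `row`, `col`,
#'   `rho` (smoothed value if smoothing was applied), `rho_raw`, convergence
#'   and correction flags.
#' @export
tidy.tetra_result <- function(x, ...) {
  out <- x$pairs
  out$rho_raw <- out$rho
  out$rho <- x$rho[cbind(match(out$row, rownames(x$rho)),
                         match(out$col, colnames(x$rho)))]
  out[c("row", "col", "rho", "rho_raw", "converged", "corrected")]
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Alternating projections onto the PSD cone and the unit-diagonal affine set,
#' stopping when the maximum elementwise change drops below `tol` or after
#' `max_iter` sweeps.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Convergence tolerance on the max elementwise change (1e-8).
#' @param max_iter Maximum sweeps (200).
#' @return The smoothed correlation matrix (unit diagonal, min eigenvalue
#'   >= -1e-8).
#' @export
nearest_pd <- function(R, tol = 1e-8, max_iter = 200) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("input must be symmetric", call. = FALSE)
  Y <- (R + t(R)) / 2
  for (it in seq_len(max_iter)) {
    e <- eigen(Y, symmetric = TRUE)
    X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    X <- (X + t(X)) / 2
    diag(X) <- 1
    delta <- max(abs(X - Y))
    Y <- X
    if (delta < tol) break
  }
  Y[Y > 1] <- 1
  Y[Y < -1] <- -1
  dimnames(Y) <- dimnames(R)
  Y
}

#' Heatmap ordering by factor block
#'
#' Orders diagnoses for heatmap display: by primary factor block (in the
#' model's factor order), then by descending mean within-block correlation.
#'
#' @param R Correlation matrix (or `tetra_result`).
#' @param model A `cfa_model` assigning each diagnosis a primary factor.
#' @return A list with `order` (integer permutation of columns of `R`),
#'   `labels` (reordered), and `blocks` (tibble of factor, start, end for
#'   drawing block boundaries).
#' @export
heatmap_order <- function(R, model) {
  if (inherits(R, "tetra_result")) R <- R$rho
  labels <- colnames(R)
  primary <- model$primary[labels]
  if (anyNA(primary))
    stop("diagnoses absent from model: ",
         paste(labels[is.na(primary)], collapse = ", "), call. = FALSE)
  fac_order <- names(model$factors)
  ord <- integer(0)
  blocks <- list()
  pos <- 0L
  for (f in fac_order) {
    members <- which(primary == f)
    if (!length(members)) next
    within_mean <- vapply(members, function(i) {
      others <- setdiff(members, i)
      if (!length(others)) return(1)
      mean(R[i, others])
    }, numeric(1))
    members <- members[order(-within_mean)]
    ord <- c(ord, members)
    blocks[[f]] <- tibble::tibble(factor = f, start = pos + 1L,
                                  end = pos + length(members))
    pos <- pos + length(members)
  }
  list(order = ord, labels = labels[ord], blocks = dplyr::bind_rows(blocks))
}
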