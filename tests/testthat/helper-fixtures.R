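# Shared fixtures, built in code.

# bank of 2x2 tables exercising balanced, skewed, near-degenerate and
# zero-cell margins (used against the grid-search likelihood oracle)
toy_table_bank <- function() {
  tibble::tribble(
    ~n00, ~n01, ~n10, ~n11,
    25,   25,   25,   25,
    40,   10,   10,   40,
    10,   40,   40,   10,
    50,    0,    0,   50,
    0,    50,   50,    0,
    70,   10,   15,    5,
    5,    15,   10,   70,
    90,    5,    3,    2,
    2,     3,    5,   90,
    60,   20,   15,    5,
    33,   17,   25,   25,
    80,    5,   10,    5,
    45,    5,   45,    5,
    5,    45,    5,   45,
    100,  20,   20,   60,
    60,   20,   20,  100,
    12,    8,    7,   13,
    200,  50,   60,   90,
    90,   60,   50,  200,
    30,   30,   20,   20,
    15,    5,   60,   20,
    20,   60,    5,   15,
    500, 100,  120,  280,
    7,     3,    2,    8,
    55,   45,   35,   65)
}

# grid-search likelihood oracle for the tetrachoric MLE (thresholds fixed at
# probit margins, rho over [-0.999, 0.999] with step `step`); independent of
# the optimizer path, shares only the BVN CDF
grid_oracle_rho <- function(n00, n01, n10, n11, zero_cell_add = 0.5,
                            step = 1e-4) {
  cells <- c(n00, n01, n10, n11)
  if (any(cells == 0)) cells <- cells + zero_cell_add
  n00 <- cells[1]; n01 <- cells[2]; n10 <- cells[3]; n11 <- cells[4]
  ntot <- sum(cells)
  t1 <- stats::qnorm(1 - (n10 + n11) / ntot)
  t2 <- stats::qnorm(1 - (n01 + n11) / ntot)
  p1 <- stats::pnorm(-t1); p2 <- stats::pnorm(-t2)
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r) {
    p11 <- 1 - stats::pnorm(t1) - stats::pnorm(t2) + pbvnorm(t1, t2, r)
    p10 <- max(p1 - p11, 1e-320)
    p01 <- max(p2 - p11, 1e-320)
    p00 <- max(1 - p11 - p10 - p01, 1e-320)
    n00 * log(p00) + n01 * log(p01) + n10 * log(p10) +
      n11 * log(max(p11, 1e-320))
  }, numeric(1))
  grid[which.max(ll)]
}

# dichotomised bivariate-normal sample reduced to a 2x2 count table
simulate_pair_table <- function(n, rho, tau1 = 0, tau2 = 0) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  a <- x > tau1
  b <- y > tau2
  c(n00 = sum(!a & !b), n01 = sum(!a & b), n10 = sum(a & !b),
    n11 = sum(a & b))
}

# small 1-factor generator config
one_factor_config <- function(n_persons, loadings, prevalences = NULL,
                              seed = 1L) {
  d <- length(loadings)
  labels <- paste0("dx", seq_len(d))
  L <- matrix(loadings, d, 1, dimnames = list(labels, "F1"))
  prev <- prevalences %||% stats::setNames(rep(0.3, d), labels)
  names(prev) <- labels
  generator_config(n_persons = n_persons, loadings = L,
                   factor_corr = matrix(1, 1, 1), prevalences = prev,
                   seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
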