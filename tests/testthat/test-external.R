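# measurement-model object at known parameters (no fitting involved; the
# score tests exercise the scoring machinery, not the estimator)
make_1f_fit <- function(lam = c(0.7, 0.7, 0.7)) {
  labels <- paste0("dx", seq_along(lam))
  mod <- parse_model(paste0("F =~ ", paste(labels, collapse = " + ")),
                     check_df = FALSE)
  L <- matrix(lam, length(lam), 1, dimnames = list(labels, "F"))
  structure(list(model = mod, lambda = L, phi = matrix(1, 1, 1),
                 uniqueness = stats::setNames(1 - lam^2, labels),
                 converged = TRUE),
            class = "cfa_fit")
}

all_patterns <- function(d) {
  g <- as.matrix(expand.grid(rep(list(0:1), d)))
  colnames(g) <- paste0("dx", seq_len(d))
  g
}

test_that("factor scores: symmetry and monotonicity in the response pattern", {
  fit <- make_1f_fit(c(0.7, 0.7))
  tau <- stats::setNames(c(0, 0), c("dx1", "dx2"))
  pats <- tibble::tibble(person_id = c("p10", "p01"),
                         dx1 = c(1, 0), dx2 = c(0, 1))
  sc <- factor_scores(fit, pats, tau)
  # equal loadings, zero thresholds: pattern (1,0) scores 0 by symmetry
  expect_equal(sc$F, c(0, 0), tolerance = 1e-6)

  fit3 <- make_1f_fit(c(0.7, 0.7, 0.7))
  tau3 <- stats::setNames(rep(0.5, 3), paste0("dx", 1:3))
  pats3 <- tibble::tibble(person_id = c("a", "b", "c"),
                          dx1 = c(1, 1, 1), dx2 = c(1, 1, 0),
                          dx3 = c(1, 0, 0))
  sc3 <- factor_scores(fit3, pats3, tau3)
  expect_gt(sc3$F[1], sc3$F[2])
  expect_gt(sc3$F[2], sc3$F[3])
})

test_that("factor scores match a dense grid-search oracle on all patterns", {
  lam <- rep(0.7, 3)
  fit <- make_1f_fit(lam)
  tau <- stats::setNames(rep(0.5, 3), paste0("dx", 1:3))
  pats <- all_patterns(3)
  dat <- dplyr::bind_cols(tibble::tibble(person_id = paste0("p", 1:8)),
                          tibble::as_tibble(pats))
  sc <- factor_scores(fit, dat, tau)
  u <- 1 - lam^2
  grid <- seq(-4, 4, by = 1e-3)
  for (i in seq_len(nrow(pats))) {
    y <- pats[i, ]
    lp <- stats::dnorm(grid, log = TRUE)
    for (j in 1:3) {
      z <- (lam[j] * grid - tau[j]) / sqrt(u[j])
      lp <- lp + if (y[j] == 1) stats::pnorm(z, log.p = TRUE) else
        stats::pnorm(-z, log.p = TRUE)
    }
    oracle <- grid[which.max(lp)]
    expect_equal(sc$F[i], oracle, tolerance = 1e-2,
                 label = paste("pattern", paste(y, collapse = "")))
  }
})

test_that("scores from the true model track true factor scores on preset data", {
  cfg <- six_factor_preset(n_persons = 20000, seed = 19)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = config_model_text(cfg))
  sc <- factor_scores(fit, sim$diagnoses, tet$tau)
  for (f in colnames(cfg$loadings)) {
    expect_gt(stats::cor(sc[[f]], sim$truth$factor_scores[[f]]), 0.7)
  }
})

test_that("noise correlates are null; point estimates are deterministic under duplication", {
  cfg <- one_factor_config(3000, c(0.7, 0.6, 0.65, 0.55, 0.6), seed = 25)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = "F =~ dx1 + dx2 + dx3 + dx4 + dx5")
  sc <- factor_scores(fit, sim$diagnoses, tet$tau)
  set.seed(31)
  noise <- tibble::tibble(person_id = sc$person_id, correlate = "noise",
                          value = stats::rnorm(nrow(sc)),
                          type = "continuous")
  reg <- regress_correlates(sc, noise, B = 60, seed = 3)
  z <- abs(reg$coefficients$estimate) / reg$coefficients$se
  expect_gte(mean(z < 2), 0.9)

  # duplicated persons: identical coefficients
  sc2 <- sc
  sc2$person_id <- paste0(sc$person_id, "_dup")
  sc_dup <- dplyr::bind_rows(sc, sc2)
  noise_dup <- dplyr::bind_rows(
    noise, dplyr::mutate(noise, person_id = paste0(person_id, "_dup")))
  reg_dup <- regress_correlates(sc_dup, noise_dup, B = 20, seed = 3)
  expect_equal(reg_dup$coefficients$estimate, reg$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("a pure Distress effect is recovered near the true-score oracle target", {
  cfg <- six_factor_preset(n_persons = 20000, seed = 55)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = config_model_text(cfg))
  sc <- factor_scores(fit, sim$diagnoses, tet$tau)
  # correlate generated as 0.5 x Distress + noise
  true_z <- scale(as.matrix(sim$truth$factor_scores[, -1]))
  set.seed(56)
  pure <- tibble::tibble(
    person_id = sim$truth$factor_scores$person_id,
    correlate = "pure_distress",
    value = 0.5 * true_z[, "Distress"] + stats::rnorm(nrow(true_z)),
    type = "continuous")
  reg <- regress_correlates(sc, pure, B = 30, seed = 7)
  est_d <- reg$coefficients$estimate[reg$coefficients$factor == "Distress"]
  # oracle: the same simple regression on the TRUE standardized factor score,
  # attenuated by the score's correlation with the true factor
  oracle_d <- stats::cov(pure$value, true_z[, "Distress"])
  attenuation <- stats::cor(sc$Distress, true_z[, "Distress"])
  expect_lt(abs(est_d - oracle_d * attenuation), 0.1)
  expect_gt(est_d, 0.2)
})

test_that("preset sleep profile keeps its marginal signs (Externalizing +, Substance Use -)", {
  cfg <- six_factor_preset(n_persons = 20000, seed = 57)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = config_model_text(cfg))
  sc <- factor_scores(fit, sim$diagnoses, tet$tau)
  sleep <- sim$correlates[sim$correlates$correlate == "sleep_disturbance", ]
  reg <- regress_correlates(sc, sleep, B = 30, seed = 7)
  co <- reg$coefficients
  expect_gt(co$estimate[co$factor == "Externalizing"], 0)
  expect_lt(co$estimate[co$factor == "SubstanceUse"], 0)
  expect_gt(co$estimate[co$factor == "Distress"],
            co$estimate[co$factor == "SubstanceUse"])
})

test_that("profile test: null when coefficients are equal, invariant to order", {
  cfg <- one_factor_config(2000, c(0.7, 0.6, 0.65), seed = 61)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = "F =~ dx1 + dx2 + dx3")
  sc <- factor_scores(fit, sim$diagnoses, tet$tau)
  # fabricate a second identical factor column: perfectly equal profiles are
  # degenerate, so perturb independently
  set.seed(5)
  sc$G <- sc$F + stats::rnorm(nrow(sc), sd = 1)
  sc <- sc[c("person_id", "F", "G", "converged")]
  y <- tibble::tibble(person_id = sc$person_id, correlate = "c1",
                      value = stats::rnorm(nrow(sc)), type = "continuous")
  reg <- regress_correlates(sc, y, B = 80, seed = 11)
  pt <- profile_difference_test(reg)
  expect_equal(pt$df, 1)
  expect_true(pt$p_value > 0.001)  # null case should rarely reject

  # order invariance
  sc_rev <- sc[c("person_id", "G", "F", "converged")]
  reg_rev <- regress_correlates(sc_rev, y, B = 80, seed = 11)
  pt_rev <- profile_difference_test(reg_rev)
  expect_equal(pt$statistic, pt_rev$statistic, tolerance = 0.3)
})

test_that("zero-variance correlates are skipped with a report", {
  fit <- make_1f_fit(c(0.7, 0.7, 0.7))
  tau <- stats::setNames(rep(0, 3), paste0("dx", 1:3))
  set.seed(2)
  dat <- dplyr::bind_cols(tibble::tibble(person_id = paste0("p", 1:50)),
                          tibble::as_tibble(matrix(
                            stats::rbinom(150, 1, 0.5), 50, 3,
                            dimnames = list(NULL, paste0("dx", 1:3)))))
  sc <- factor_scores(fit, dat, tau)
  flat <- tibble::tibble(person_id = dat$person_id, correlate = "flat",
                         value = 1, type = "continuous")
  expect_message(reg <- regress_correlates(sc, flat, B = 5), "zero variance")
  expect_equal(reg$skipped, "flat")
  expect_equal(nrow(reg$coefficients), 0)
})
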