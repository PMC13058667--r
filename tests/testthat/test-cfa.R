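test_that("model parsing: factors, residuals, cross-loadings, parameter counts", {
  m1 <- parse_model("F1 =~ a + b + c")
  expect_equal(names(m1$factors), "F1")
  expect_equal(m1$indicators, c("a", "b", "c"))
  expect_equal(nrow(m1$residual_pairs), 0)
  expect_equal(m1$npar, 3)
  expect_equal(m1$df, 0)

  m2 <- parse_model("F1 =~ a + b\nF2 =~ c + d\na ~~ c")
  # 4 loadings + 1 factor correlation + 1 residual = 6 free parameters
  expect_equal(m2$npar, 6)
  expect_equal(m2$df, 0)

  mx <- parse_model("F1 =~ a + b + c\nF2 =~ d + e + a")
  expect_equal(nrow(mx$cross), 1)
  expect_equal(mx$cross$indicator, "a")
  expect_equal(unname(mx$primary["a"]), "F1")

  mb <- parse_model("F1 =~ a + b + c\nF2 =~ d + e + f\ngeneral: on")
  expect_true(mb$bifactor)
  expect_equal(mb$npar, 6 + 6)  # specific + general loadings, orthogonal
})

test_that("model parsing rejects malformed and duplicate input", {
  expect_error(parse_model("F1 =~ a + b\na ~~ c\na ~~ c"), "duplicate residual")
  expect_error(parse_model("F1 =~ a + b\nc ~~ a\na ~~ c"), "duplicate residual")
  expect_error(parse_model("F1 =~ a + b\njunk line"), "line 2")
  expect_error(parse_model("F1 =~ a + b\nF1 =~ c"), "duplicate factor")
  expect_error(parse_model("a ~~ a\nF =~ a + b"), "itself")
  # more free parameters than moments
  expect_error(parse_model("F1 =~ a + b\nF2 =~ a + b\nF3 =~ a + b"),
               "not identified")
})

test_that("implied matrix follows common-factor algebra", {
  m1 <- parse_model("F =~ x1 + x2 + x3")
  lam <- matrix(c(0.6, 0.7, 0.8), 3, 1,
                dimnames = list(c("x1", "x2", "x3"), "F"))
  S <- implied_matrix(m1, list(lambda = lam))
  expect_equal(S["x1", "x2"], 0.42)
  expect_equal(S["x1", "x3"], 0.48)
  expect_equal(S["x2", "x3"], 0.56)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(unname(attr(S, "uniqueness")),
               1 - c(0.36, 0.49, 0.64))

  m2 <- parse_model("F =~ x1 + x2 + x3\nx1 ~~ x2", check_df = FALSE)
  S2 <- implied_matrix(m2, list(lambda = lam, residuals = 0.1))
  expect_equal(S2["x1", "x2"], 0.52)
  expect_equal(S2["x1", "x3"], S["x1", "x3"])
  expect_equal(unname(diag(S2)), rep(1, 3))
})

test_that("random admissible parameters give an exact unit diagonal", {
  mod <- parse_model("A =~ a + b + c\nB =~ d + e + f\nb ~~ e")
  set.seed(8)
  for (i in 1:10) {
    lam <- matrix(0, 6, 2,
                  dimnames = list(c("a", "b", "c", "d", "e", "f"),
                                  c("A", "B")))
    lam[1:3, 1] <- stats::runif(3, 0.3, 0.8)
    lam[4:6, 2] <- stats::runif(3, 0.3, 0.8)
    phi <- matrix(c(1, 0.4, 0.4, 1), 2)
    S <- implied_matrix(mod, list(lambda = lam, phi = phi,
                                  residuals = stats::runif(1, -0.1, 0.1)))
    expect_identical(unname(diag(S)), rep(1, 6))
  }
})

test_that("ULS fit recovers generating parameters exactly from implied matrices", {
  # 1-factor
  m1 <- parse_model("F =~ x1 + x2 + x3")
  lam <- matrix(c(0.6, 0.7, 0.8), 3, 1,
                dimnames = list(c("x1", "x2", "x3"), "F"))
  S <- implied_matrix(m1, list(lambda = lam))
  fit <- fit_cfa(S, n = 500, model = m1)
  expect_lt(fit$F_value, 1e-10)
  expect_equal(unname(fit$lambda[, 1]), c(0.6, 0.7, 0.8), tolerance = 1e-6)

  # 2-factor with factor correlation
  m2 <- parse_model("F1 =~ a + b + c\nF2 =~ d + e + f")
  lam2 <- matrix(0, 6, 2, dimnames = list(c("a", "b", "c", "d", "e", "f"),
                                          c("F1", "F2")))
  lam2[1:3, 1] <- 0.7; lam2[4:6, 2] <- 0.7
  S2 <- implied_matrix(m2, list(lambda = lam2,
                                phi = matrix(c(1, 0.5, 0.5, 1), 2)))
  f2 <- fit_cfa(S2, n = 500, model = m2)
  expect_equal(f2$phi[1, 2], 0.5, tolerance = 1e-4)
  expect_lt(f2$F_value, 1e-10)

  # 2-factor + residual pair
  m3 <- parse_model("F1 =~ a + b + c\nF2 =~ d + e + f\na ~~ d")
  S3 <- implied_matrix(m3, list(lambda = lam2,
                                phi = matrix(c(1, 0.5, 0.5, 1), 2),
                                residuals = 0.12))
  f3 <- fit_cfa(S3, n = 500, model = m3)
  expect_equal(f3$residuals$estimate, 0.12, tolerance = 1e-5)
  expect_lt(f3$F_value, 1e-10)

  # bifactor (heterogeneous loadings keep the decomposition identified)
  mb <- parse_model("F1 =~ a + b + c + g1\nF2 =~ d + e + f + g2\ngeneral: on")
  lamb <- matrix(0, 8, 3,
                 dimnames = list(c("a", "b", "c", "g1", "d", "e", "f", "g2"),
                                 c("F1", "F2", "general")))
  lamb[c("a", "b", "c", "g1"), "F1"] <- c(0.55, 0.45, 0.60, 0.50)
  lamb[c("d", "e", "f", "g2"), "F2"] <- c(0.50, 0.62, 0.48, 0.55)
  lamb[, "general"] <- seq(0.35, 0.70, length.out = 8)
  Sb <- implied_matrix(mb, list(lambda = lamb))
  fb <- fit_cfa(Sb, n = 500, model = mb)
  expect_lt(fb$F_value, 1e-9)
  Pb <- psychspectra:::model_layout(mb)$P
  expect_lt(max(abs(fb$lambda[Pb] - lamb[lamb != 0])), 1e-6)
})

test_that("fit is invariant to indicator order and resolves sign indeterminacy", {
  cfg <- one_factor_config(3000, c(0.7, 0.6, 0.5, 0.6), seed = 3)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  f1 <- fit_cfa(tet, model = "F =~ dx1 + dx2 + dx3 + dx4")
  f2 <- fit_cfa(tet, model = "F =~ dx4 + dx2 + dx1 + dx3")
  expect_equal(f1$F_value, f2$F_value, tolerance = 1e-9)
  expect_equal(f1$lambda[c("dx4", "dx2", "dx1", "dx3"), 1],
               f2$lambda[, 1], tolerance = 1e-6)
  expect_gte(sum(f1$lambda[, 1]), 0)
  expect_gte(sum(f2$lambda[, 1]), 0)
})

test_that("six-factor preset parameters are recovered from simulated data", {
  cfg <- six_factor_preset(n_persons = 20000, seed = 42)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  mod <- parse_model(config_model_text(cfg))
  fit <- fit_cfa(tet, model = mod)
  expect_true(fit$converged)
  P <- fit$layout$P
  errs <- fit$lambda[P] - cfg$loadings[cfg$loadings != 0]
  expect_lt(max(abs(errs)), 0.1)
  expect_lt(sqrt(mean(errs^2)), 0.05)
  expect_lt(max(abs(fit$phi - cfg$factor_corr)), 0.1)
})

test_that("fit index formulas are exact in closed form", {
  # T = df forces CFI = 1, RMSEA = 0
  idx <- fit_indices(50, 50, 500, 60, 1001, rep(0.02, 10))
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  # stated arithmetic case
  idx2 <- fit_indices(100, 50, 1000, 60, 1001, rep(0.01, 10))
  expect_equal(idx2$rmsea, sqrt(50 / 50000), tolerance = 1e-12)
  expect_equal(idx2$cfi, 1 - 50 / 940, tolerance = 1e-12)
  expect_equal(idx2$tli, ((1000 / 60) - 2) / ((1000 / 60) - 1),
               tolerance = 1e-12)
  # zero residuals give SRMR = 0
  expect_equal(fit_indices(100, 50, 1000, 60, 1001, rep(0, 10))$srmr, 0)
  # degenerate null flagged
  expect_true(fit_indices(100, 50, 55, 60, 1001, rep(0, 10))$degenerate_null)
})

test_that("freeing a parameter never increases the discrepancy (nesting)", {
  cfg <- six_factor_preset(n_persons = 5000, seed = 13)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  mod_no_res <- parse_model(paste(
    vapply(colnames(cfg$loadings), function(f)
      paste0(f, " =~ ",
             paste(rownames(cfg$loadings)[cfg$loadings[, f] != 0],
                   collapse = " + ")), character(1)), collapse = "\n"))
  base <- fit_cfa(tet, model = mod_no_res)
  cands <- tibble::tibble(
    type = "residual",
    a = c("major depressive disorder", "schizophrenia", "agoraphobia"),
    b = c("dysthymia", "schizoaffective disorder", "tic disorder"))
  scan <- candidate_scan(tet, mod_no_res, cands)
  expect_true(all(scan$delta_f >= 0))
  # the generated residual pairs reduce F strictly
  true_pairs <- scan[paste(scan$a, scan$b) %in%
                       c("major depressive disorder dysthymia",
                         "schizophrenia schizoaffective disorder"), ]
  expect_true(all(true_pairs$delta_f > 0))
})

test_that("DWLS accepts jackknife-of-batches weights and still recovers", {
  cfg <- one_factor_config(4000, c(0.7, 0.6, 0.5, 0.65, 0.55), seed = 19)
  sim <- simulate_dataset(cfg, events = FALSE)
  V <- pair_variances(sim$diagnoses, n_batches = 10)
  expect_true(isSymmetric(V))
  expect_true(all(V[upper.tri(V)] > 0))
  tet <- tetrachoric(sim$diagnoses)
  fit <- fit_cfa(tet, model = "F =~ dx1 + dx2 + dx3 + dx4 + dx5",
                 estimator = "dwls", weights = V)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$lambda[, 1] - c(0.7, 0.6, 0.5, 0.65, 0.55))), 0.1)
  expect_error(fit_cfa(tet, model = "F =~ dx1 + dx2 + dx3",
                       estimator = "dwls"), "weights")
})

test_that("fit errors on indicators missing from the correlation matrix", {
  cfg <- one_factor_config(500, c(0.7, 0.6, 0.5), seed = 4)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  expect_error(fit_cfa(tet, model = "F =~ dx1 + dx2 + nope"), "nope")
})

test_that("bootstrap SEs track the Monte-Carlo sampling distribution", {
  lam_true <- c(0.7, 0.6, 0.65, 0.55, 0.6)
  model_txt <- "F =~ dx1 + dx2 + dx3 + dx4 + dx5"
  n <- 4000
  # Monte-Carlo oracle: SD of estimates over independent fresh datasets
  mc <- matrix(NA_real_, 60, 5)
  for (r in seq_len(60)) {
    simr <- simulate_dataset(one_factor_config(n, lam_true, seed = 1000 + r),
                             events = FALSE)
    fr <- fit_cfa(suppressMessages(tetrachoric(simr$diagnoses)), n = n,
                  model = model_txt)
    mc[r, ] <- fr$lambda[, 1]
  }
  mc_sd <- apply(mc, 2, stats::sd)
  sim <- simulate_dataset(one_factor_config(n, lam_true, seed = 77),
                          events = FALSE)
  boot <- bootstrap_se(sim$diagnoses, model_txt, B = 60, seed = 5)
  expect_gte(boot$n_converged, 48)
  ratio <- boot$loading_se$se / mc_sd
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("bootstrap SEs shrink with sample size", {
  lam_true <- c(0.7, 0.6, 0.65, 0.55)
  model_txt <- "F =~ dx1 + dx2 + dx3 + dx4"
  se_small <- bootstrap_se(
    simulate_dataset(one_factor_config(1000, lam_true, seed = 2),
                     events = FALSE)$diagnoses,
    model_txt, B = 40, seed = 9)$loading_se$se
  se_big <- bootstrap_se(
    simulate_dataset(one_factor_config(8000, lam_true, seed = 2),
                     events = FALSE)$diagnoses,
    model_txt, B = 40, seed = 9)$loading_se$se
  expect_true(all(se_big < se_small))
})
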