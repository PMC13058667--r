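# build a small converged fit for index tests
fit_toy <- function(lam = c(0.5, 0.6, 0.7), n = 1000) {
  labels <- paste0("x", seq_along(lam))
  mod <- parse_model(paste0("F =~ ", paste(labels, collapse = " + ")))
  S <- implied_matrix(mod, list(lambda = matrix(lam, length(lam), 1,
                                                dimnames = list(labels, "F"))))
  fit_cfa(S, n = n, model = mod)
}

test_that("alternative indices: magnitude, consistency, precision", {
  fit <- fit_toy(c(0.5, 0.6, 0.7))
  ai <- alt_indices(fit)
  f_row <- ai[ai$factor == "F", ]
  expect_equal(f_row$magnitude, 0.6, tolerance = 1e-6)
  expect_equal(f_row$consistency, 0.1, tolerance = 1e-6)  # sample SD
  expect_true(is.na(f_row$precision))

  # all loadings equal: SD = 0
  ai2 <- alt_indices(fit_toy(c(0.6, 0.6, 0.6)))
  expect_equal(ai2$consistency[ai2$factor == "F"], 0, tolerance = 1e-6)

  # four loadings with SEs: direct-formula oracle
  fit4 <- fit_toy(c(0.43, 0.52, 0.61, 0.70))
  se_vals <- c(0.01, 0.02, 0.02, 0.03)
  boot_stub <- structure(
    list(loading_se = tibble::tibble(indicator = paste0("x", 1:4),
                                     factor = "F", se = se_vals)),
    class = "cfa_boot")
  fit4$se <- boot_stub
  ai4 <- alt_indices(fit4)
  row4 <- ai4[ai4$factor == "F", ]
  expect_equal(row4$magnitude, stats::median(c(0.43, 0.52, 0.61, 0.70)),
               tolerance = 1e-4)
  expect_equal(row4$magnitude, 0.565, tolerance = 1e-3)
  expect_equal(row4$precision, 0.02, tolerance = 1e-12)
  expect_equal(row4$consistency, stats::sd(c(0.43, 0.52, 0.61, 0.70)),
               tolerance = 1e-3)
  pooled <- ai4[ai4$factor == ".pooled", ]
  expect_equal(pooled$n_loadings, 4)
})

test_that("model comparison: identical models give identical rows, order-invariant ranks", {
  cfg <- six_factor_preset(n_persons = 3000, seed = 6)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  mod6 <- parse_model(config_model_text(cfg))
  mod1 <- parse_model(paste0("General =~ ",
                             paste(rownames(cfg$loadings), collapse = " + ")))
  f6 <- fit_cfa(tet, model = mod6)
  f1 <- fit_cfa(tet, model = mod1)
  cmp_dup <- compare_models(list(a = f6, b = f6))
  expect_equal(cmp_dup$cfi[1], cmp_dup$cfi[2])
  expect_equal(cmp_dup$f_value[1], cmp_dup$f_value[2])

  cmp <- compare_models(list(six = f6, general = f1))
  cmp_rev <- compare_models(list(general = f1, six = f6))
  expect_equal(cmp$rank_cfi[cmp$model == "six"],
               cmp_rev$rank_cfi[cmp_rev$model == "six"])
  expect_gt(cmp$cfi[cmp$model == "six"], cmp$cfi[cmp$model == "general"])
  expect_lt(cmp$rmsea[cmp$model == "six"], cmp$rmsea[cmp$model == "general"])

  # different matrices are rejected
  sim2 <- simulate_dataset(six_factor_preset(n_persons = 3000, seed = 60),
                           events = FALSE)
  f_other <- fit_cfa(tetrachoric(sim2$diagnoses), model = mod6)
  expect_error(compare_models(list(f6, f_other)), "different")
})

test_that("random-assignment nulls preserve the factor-size multiset and reproduce", {
  cfg <- six_factor_preset(n_persons = 3000, seed = 10)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  mod6 <- parse_model(config_model_text(cfg))
  fit6 <- fit_cfa(tet, model = mod6)

  # K = 0: empty distributions, NA percentiles
  nul0 <- random_assignment_null(tet, mod6, K = 0, observed_fit = fit6)
  expect_equal(nrow(nul0$draws), 0)
  expect_true(all(is.na(nul0$percentiles)))

  nul <- random_assignment_null(tet, mod6, K = 5, seed = 3,
                                observed_fit = fit6)
  expect_equal(nrow(nul$draws), 5)
  nul_rep <- random_assignment_null(tet, mod6, K = 5, seed = 3,
                                    observed_fit = fit6)
  expect_equal(nul$draws, nul_rep$draws)
  expect_true(all(nul$percentiles >= 0 & nul$percentiles <= 100, na.rm = TRUE))
})

test_that("ICC(A,1) matches the mean-squares formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(icc_absolute(x, x), 1)
  y <- x + 10
  # direct two-way decomposition oracle
  n <- 4; k <- 2
  dat <- cbind(x, y)
  rm_ <- rowMeans(dat); cm <- colMeans(dat); g <- mean(dat)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  mse <- sum((dat - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g)^2) /
    ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc_absolute(x, y), oracle, tolerance = 1e-12)
  # absolute agreement penalises the offset
  expect_lt(icc_absolute(x, y), 1)

  set.seed(14)
  a <- stats::rnorm(1000); b <- stats::rnorm(1000)
  expect_lt(abs(icc_absolute(a, b)), 0.1)
  expect_warning(icc_absolute(rep(1, 5), rep(1, 5)), "constant")
})

test_that("split-half: disjoint partition, label symmetry, replicable indices", {
  cfg <- six_factor_preset(n_persons = 4000, seed = 12)
  sim <- simulate_dataset(cfg, events = FALSE)
  mod6 <- parse_model(config_model_text(cfg))
  sh <- split_half(sim$diagnoses, list(six = mod6), seed = 4)
  ids <- sh$half_ids
  expect_length(intersect(ids$half1, ids$half2), 0)
  expect_setequal(c(ids$half1, ids$half2), seq_len(4000))
  expect_lte(abs(length(ids$half1) - length(ids$half2)), 1)
  expect_true(all(c("loading_icc", "cfi_diff") %in% names(sh$per_model)))
  expect_gte(sh$per_model$loading_icc, -1)
})

test_that("leave-one-out: contract shape and separable orthogonal blocks", {
  # exactly separable blocks: Phi = 0, implied-matrix input
  mod <- parse_model("A =~ a1 + a2 + a3 + a4\nB =~ b1 + b2 + b3 + b4")
  labs <- c(paste0("a", 1:4), paste0("b", 1:4))
  lam <- matrix(0, 8, 2, dimnames = list(labs, c("A", "B")))
  lam[1:4, 1] <- c(0.7, 0.6, 0.65, 0.55)
  lam[5:8, 2] <- c(0.6, 0.7, 0.5, 0.65)
  S <- implied_matrix(mod, list(lambda = lam, phi = diag(2)))
  loo <- loo_scan(S, mod, n = 5000)
  expect_equal(dim(loo$delta), c(8, 8))
  expect_true(all(is.na(diag(loo$delta))))
  # removing a block-A indicator leaves block-B loadings untouched
  cross_ab <- loo$delta[paste0("b", 1:4), paste0("a", 1:4)]
  cross_ba <- loo$delta[paste0("a", 1:4), paste0("b", 1:4)]
  expect_lt(max(abs(cross_ab)), 1e-8)
  expect_lt(max(abs(cross_ba)), 1e-8)
  # within-block deltas are also ~0 here (input is exactly model-implied)
  expect_lt(max(abs(loo$delta), na.rm = TRUE), 1e-6)
})

test_that("leave-one-out skips removals that under-identify a factor", {
  mod <- parse_model("A =~ a1 + a2 + a3\nB =~ b1 + b2")
  labs <- c("a1", "a2", "a3", "b1", "b2")
  lam <- matrix(0, 5, 2, dimnames = list(labs, c("A", "B")))
  lam[1:3, 1] <- 0.7; lam[4:5, 2] <- 0.6
  S <- implied_matrix(mod, list(lambda = lam,
                                phi = matrix(c(1, 0.4, 0.4, 1), 2)))
  loo <- loo_scan(S, mod, n = 2000)
  expect_true(all(c("b1", "b2") %in% names(loo$skipped)))
  expect_true(all(is.na(loo$delta[, "b1"])))
})

test_that("candidate scan flags redundant candidates and ranks the true pair first", {
  cfg <- six_factor_preset(n_persons = 20000, seed = 77)
  sim <- simulate_dataset(cfg, events = FALSE)
  tet <- tetrachoric(sim$diagnoses)
  mod_full <- parse_model(config_model_text(cfg))
  # candidate already free in the model
  scan_red <- candidate_scan(tet, mod_full, tibble::tibble(
    type = "residual", a = "major depressive disorder", b = "dysthymia"))
  expect_equal(scan_red$flag, "redundant")
  expect_equal(scan_red$delta_f, 0)

  # true generated pair vs decoys
  mod_no_res <- parse_model(paste(
    vapply(colnames(cfg$loadings), function(f)
      paste0(f, " =~ ",
             paste(rownames(cfg$loadings)[cfg$loadings[, f] != 0],
                   collapse = " + ")), character(1)), collapse = "\n"))
  decoys <- tibble::tibble(
    type = "residual",
    a = c("major depressive disorder", "agoraphobia", "PTSD",
          "conduct disorder", "alcohol use disorder", "panic disorder",
          "eating disorder", "tic disorder", "delusional disorder",
          "specific phobia", "nicotine dependence"),
    b = c("dysthymia", "eating disorder", "tic disorder",
          "delusional disorder", "learning disorder", "PTSD",
          "schizotypal personality disorder", "intermittent explosive disorder",
          "separation anxiety disorder", "somatic symptom disorder",
          "Tourette syndrome"))
  scan <- candidate_scan(tet, mod_no_res, decoys)
  expect_equal(scan$a[1], "major depressive disorder")
  expect_equal(scan$b[1], "dysthymia")
  expect_true(all(scan$delta_f >= 0, na.rm = TRUE))
})

test_that("cross-loading candidates refit with the extra loading", {
  mod <- parse_model("A =~ a1 + a2 + a3 + a4\nB =~ b1 + b2 + b3 + b4")
  labs <- c(paste0("a", 1:4), paste0("b", 1:4))
  lam <- matrix(0, 8, 2, dimnames = list(labs, c("A", "B")))
  lam[1:4, 1] <- 0.7; lam[5:8, 2] <- 0.6
  lam[5, 1] <- 0.3  # b1 truly cross-loads on A
  mod_true <- parse_model("A =~ a1 + a2 + a3 + a4 + b1\nB =~ b1 + b2 + b3 + b4")
  S <- implied_matrix(mod_true, list(
    lambda = lam[, c("A", "B")],
    phi = matrix(c(1, 0.3, 0.3, 1), 2)))
  scan <- candidate_scan(S, mod, tibble::tibble(
    type = "cross", a = c("b1", "b2"), b = "A"), n = 3000)
  expect_equal(scan$a[1], "b1")
  expect_gt(scan$delta_f[1], scan$delta_f[2])
  expect_equal(scan$estimate[1], 0.3, tolerance = 0.02)
})
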