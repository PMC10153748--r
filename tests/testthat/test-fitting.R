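test_that("AICc follows the small-sample formula exactly", {
  expect_equal(aicc(0, 1, 3), 6)
  expect_equal(aicc(-10, 3, 50), 20 + 6 + 24 / 46)
  # monotone in -logL at fixed k
  lls <- seq(-5, -1, by = 0.5)
  expect_true(all(diff(aicc(lls, 2, 100)) < 0))
  expect_error(aicc(0, 5, 6), "n > k")
})

test_that("published-style (logL, k) pairs reproduce the Delta AICc", {
  # BM at logL = -19.1 (k = 2) vs the best four-regime multi-sigma OU at
  # logL = -3.43 (k = 9), n = 118 tips
  d <- aicc(-19.1, 2, 118) - aicc(-3.43, 9, 118)
  expect_equal(d, 15.78, tolerance = 0.005)
})

test_that("model enumeration yields 21 specs, 13 of them fit-able", {
  all21 <- enumerate_models()
  expect_length(all21, 21)
  fit13 <- enumerate_models(fit_able_only = TRUE)
  expect_length(fit13, 13)
  expect_true(all(vapply(fit13, `[[`, TRUE, "fit_able")))

  k9 <- model_spec("OUMV", "meta_abrupt_meta_gradual_paed_dd", 4)
  expect_equal(k9$k, 9L)
  expect_equal(model_spec("BM1", "random_evolution", 1)$k, 2L)
  expect_equal(model_spec("OUM", "metamorphosis_other", 2)$k, 4L)
  expect_equal(model_spec("BMS", "metamorphosis_other", 2)$k, 3L)
})

test_that("BM1 maximum likelihood matches its closed form", {
  tr <- simulate_yule_tree(40, seed = 61)
  p <- regime_painting(tr, rep("all", nrow(tr$edge)), "all")
  dec <- decompose_paths(tr, p)
  spec <- model_spec("BM1", "random_evolution", 1)
  x <- simulate_tips(model_params(spec, sigma = 0.8, x0 = 3), tr, p, seed = 6)

  fit <- fit_model(spec, tr, p, x)
  expect_true(fit$converged)

  C <- bm_covariance(dec, c(all = 1))
  Ci <- solve(C)
  one <- rep(1, nrow(C))
  x0_hat <- drop(t(one) %*% Ci %*% x[dec$tips]) / drop(t(one) %*% Ci %*% one)
  r <- x[dec$tips] - x0_hat
  s2_hat <- drop(t(r) %*% Ci %*% r) / length(r)
  expect_equal(unname(fit$params$x0), x0_hat, tolerance = 1e-8)
  expect_equal(unname(fit$params$sigma^2), s2_hat, tolerance = 1e-8)
})

test_that("BM1 rate is recovered from data simulated at a known rate", {
  tr <- simulate_yule_tree(200, seed = 71)
  p <- regime_painting(tr, rep("all", nrow(tr$edge)), "all")
  spec <- model_spec("BM1", "random_evolution", 1)
  x <- simulate_tips(model_params(spec, sigma = sqrt(0.5), x0 = 0), tr, p,
                     seed = 72)
  fit <- fit_model(spec, tr, p, x)
  expect_lt(abs(fit$params$sigma^2 - 0.5) / 0.5, 0.2)
})

test_that("GLS-profiled equilibria equal the directly optimized ones", {
  rp <- random_painted_tree(5, 2, seed = 81)
  spec <- model_spec("OUM", "h", 2)
  truth <- model_params(spec, alpha = 1.2, sigma = 0.6,
                        theta = c(r1 = 2, r2 = 4))
  x <- simulate_tips(truth, rp$tree, rp$painting, seed = 82)

  alpha <- 1.2; sigma <- 0.6
  # direct numerical optimization over theta at fixed (alpha, sigma)
  obj <- function(th) {
    -log_likelihood(model_params(spec, alpha = alpha, sigma = sigma,
                                 theta = setNames(th, c("r1", "r2"))),
                    rp$tree, rp$painting, x)
  }
  opt <- optim(c(3, 3), obj, method = "BFGS",
               control = list(reltol = 1e-14))

  # GLS formula at the same (alpha, sigma)
  W <- ou_weight_matrix(rp$dec, alpha)
  V <- ou_covariance(rp$dec, alpha, c(r1 = sigma^2, r2 = sigma^2))
  Vi <- solve(V)
  th_gls <- setNames(drop(solve(t(W) %*% Vi %*% W,
                                t(W) %*% Vi %*% x[rp$dec$tips])),
                     colnames(W))
  expect_equal(opt$par, unname(th_gls[c("r1", "r2")]), tolerance = 1e-6)
})

test_that("more complex nested models never fit worse", {
  fx <- study_mimic_fixture(seed = 17)
  h <- build_hypotheses()
  p4 <- coarsen(fx$painting, h$meta_abrupt_meta_gradual_paed_dd)
  p1 <- coarsen(fx$painting, h$random_evolution)

  f_bm1 <- fit_model(model_spec("BM1", "random_evolution", 1),
                     fx$tree, p1, fx$data)
  f_bms <- fit_model(model_spec("BMS", "meta_abrupt_meta_gradual_paed_dd", 4),
                     fx$tree, p4, fx$data)
  f_oum <- fit_model(model_spec("OUM", "meta_abrupt_meta_gradual_paed_dd", 4),
                     fx$tree, p4, fx$data)
  f_oumv <- fit_model(model_spec("OUMV", "meta_abrupt_meta_gradual_paed_dd", 4),
                      fx$tree, p4, fx$data)
  tol <- 1e-4
  expect_gte(f_bms$logL, f_bm1$logL - tol)
  expect_gte(f_oumv$logL, f_oum$logL - tol)
})

test_that("the model table ranks by AICc and is order-invariant", {
  fx <- study_mimic_fixture(seed = 23)
  h <- build_hypotheses()
  p1 <- coarsen(fx$painting, h$random_evolution)
  p2 <- coarsen(fx$painting, h$metamorphosis_other)
  fits <- list(
    fit_model(model_spec("BM1", "random_evolution", 1), fx$tree, p1, fx$data),
    fit_model(model_spec("BMS", "metamorphosis_other", 2), fx$tree, p2, fx$data),
    fit_model(model_spec("OUMV", "metamorphosis_other", 2), fx$tree, p2, fx$data))

  tab <- build_model_table(fits)
  expect_equal(tab$table$dAICc[1], 0)
  expect_true(!is.unsorted(tab$table$AICc))
  expect_true(all(tab$support$dAICc <= 4))

  tab2 <- build_model_table(rev(fits))
  expect_identical(tab$table, tab2$table)

  single <- build_model_table(fits[1])
  expect_equal(single$table$dAICc, 0)
  expect_equal(nrow(single$support), 1)
})

test_that("bootstrap intervals are reproducible and collapse without noise", {
  tr <- simulate_yule_tree(20, seed = 91)
  p <- regime_painting(tr, rep("all", nrow(tr$edge)), "all")
  spec <- model_spec("BM1", "random_evolution", 1)
  x <- simulate_tips(model_params(spec, sigma = 0.5, x0 = 1), tr, p, seed = 92)
  fit <- fit_model(spec, tr, p, x)

  ci1 <- bootstrap_ci(fit, tr, p, n_reps = 30, seed = 93)
  ci2 <- bootstrap_ci(fit, tr, p, n_reps = 30, seed = 93)
  expect_identical(ci1$ci, ci2$ci)
  expect_true(all(ci1$ci$lower <= ci1$ci$estimate + 1e-8))
  expect_true(all(ci1$ci$upper >= ci1$ci$estimate - 1e-8))

  # near-zero generating noise: every replicate refit lands on the MLE and
  # the interval width collapses
  tiny <- fit
  tiny$params <- model_params(spec, sigma = 1e-8, x0 = 1)
  ci0 <- bootstrap_ci(tiny, tr, p, n_reps = 20, seed = 94)
  x0_row <- ci0$ci[ci0$ci$parameter == "x0", ]
  expect_lt(x0_row$upper - x0_row$lower, 1e-6)
})

test_that("bootstrap intervals attain near-nominal coverage for the BM rate", {
  tr <- simulate_yule_tree(40, seed = 101)
  p <- regime_painting(tr, rep("all", nrow(tr$edge)), "all")
  spec <- model_spec("BM1", "random_evolution", 1)
  truth <- model_params(spec, sigma = sqrt(0.5), x0 = 0)

  hits <- 0L
  n_outer <- 100L
  for (i in seq_len(n_outer)) {
    x <- simulate_tips(truth, tr, p, seed = 1000 + i)
    fit <- fit_model(spec, tr, p, x)
    ci <- bootstrap_ci(fit, tr, p, n_reps = 199, level = 90,
                       seed = 2000 + i)
    row <- ci$ci[ci$ci$parameter == "sigma", ]
    if (row$lower^2 <= 0.5 && 0.5 <= row$upper^2) hits <- hits + 1L
  }
  expect_gte(hits / n_outer, 0.83)
  expect_lte(hits / n_outer, 0.97)
})
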