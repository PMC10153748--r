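test_that("OU weight rows sum to one for any alpha and painting", {
  set.seed(42)
  for (case in 1:8) {
    rp <- random_painted_tree(sample(3:8, 1), sample(1:3, 1), seed = 100 + case)
    alpha <- runif(1, 0.05, 10)
    W <- ou_weight_matrix(rp$dec, alpha)
    expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  }
})

test_that("single-branch OU moments match the closed forms", {
  tr <- read_newick("(A:1,B:1);")
  p <- regime_painting(tr, c("r1", "r1"), "r1")
  dec <- decompose_paths(tr, p)

  # tip variance sigma^2 (1 - e^{-2 alpha T}) / (2 alpha), T = 1
  V <- ou_covariance(dec, alpha = 1, sigma2 = c(r1 = 2))
  expect_equal(V[1, 1], 1 - exp(-2), tolerance = 1e-12)
  # tips diverging at the root share no path
  expect_equal(V[1, 2], 0)

  # large alpha pushes all weight onto the tipward regime
  W <- ou_weight_matrix(dec, alpha = 200)
  expect_equal(unname(W[, "r1"]), c(1, 1))
})

test_that("BM covariance equals shared path length times the rate", {
  tr <- read_newick("((A:0.4,B:0.4):0.6,C:1);")
  p <- regime_painting(tr, rep("r1", 4), "r1")
  dec <- decompose_paths(tr, p)
  V <- bm_covariance(dec, c(r1 = 1))
  expect_equal(V["A", "B"], 0.6)
  expect_equal(V["A", "A"], 1.0)
  # single regime: V = sigma2 x shared-path-length matrix
  expect_equal(bm_covariance(dec, c(r1 = 2.5)), 2.5 * V)
})

test_that("BM is the small-alpha limit of the OU covariance", {
  rp <- random_painted_tree(6, 2, seed = 9)
  s2 <- c(r1 = 0.7, r2 = 1.4)
  a <- 1e-8
  Vou <- ou_covariance(rp$dec, a, s2)
  Vbm <- bm_covariance(rp$dec, s2)
  # e^{-alpha(...)} corrections are O(alpha) on a height-1 tree
  expect_lt(max(abs(Vou - Vbm)), 1e-6)
})

test_that("likelihood matches the brute-force quadrature oracle", {
  set.seed(7)
  for (cls in c("BM1", "BMS", "OUM", "OUMV")) {
    k <- if (cls == "BM1") 1L else 2L
    rp <- random_painted_tree(5, k, seed = 400 + match(cls, c("BM1", "BMS", "OUM", "OUMV")))
    params <- random_params(cls, rp$labels)
    x <- simulate_tips(params, rp$tree, rp$painting, seed = 1)
    mom <- oracle_moments(params, rp$dec)
    ref <- oracle_mvn_logdens(x[rp$dec$tips], mom$mean, mom$cov)
    got <- log_likelihood(params, rp$tree, rp$painting, x)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("a standard-normal tip at its mode has the textbook density", {
  # two independent tips each with unit variance, observed at the mean:
  # logL = 2 * (-0.5 log(2 pi))
  tr <- read_newick("(A:1,B:1);")
  p <- regime_painting(tr, c("r1", "r1"), "r1")
  spec <- model_spec("BM1", "random_evolution", 1)
  params <- model_params(spec, sigma = 1, x0 = 3)
  ll <- log_likelihood(params, tr, p, c(A = 3, B = 3))
  expect_equal(ll, -log(2 * pi), tolerance = 1e-12)
})

test_that("OU at tiny alpha with theta at the root state matches BM1", {
  tr <- simulate_yule_tree(12, seed = 21)
  p <- regime_painting(tr, rep("r1", nrow(tr$edge)), "r1")
  x <- simulate_tips(model_params(model_spec("BM1", "h", 1), sigma = 0.6, x0 = 2),
                     tr, p, seed = 2)
  ll_bm <- log_likelihood(model_params(model_spec("BM1", "h", 1),
                                       sigma = 0.6, x0 = 2), tr, p, x)
  ll_ou <- log_likelihood(model_params(model_spec("OUM", "h", 1), alpha = 1e-8,
                                       sigma = 0.6, theta = c(r1 = 2)),
                          tr, p, x)
  expect_equal(ll_ou, ll_bm, tolerance = 1e-4)
})

test_that("simulation is seeded-reproducible and exact at sigma = 0", {
  fx <- study_mimic_fixture(seed = 8)
  a <- simulate_tips(fx$params, fx$tree, fx$painting, seed = 123)
  b <- simulate_tips(fx$params, fx$tree, fx$painting, seed = 123)
  expect_identical(a, b)

  # zero noise: every tip decays deterministically to its theta mix; with a
  # single regime every tip is exactly theta
  tr <- simulate_yule_tree(10, seed = 31)
  p <- regime_painting(tr, rep("r1", nrow(tr$edge)), "r1")
  spec <- model_spec("OUM", "h", 1)
  det <- simulate_tips(model_params(spec, alpha = 2, sigma = 0,
                                    theta = c(r1 = 5)), tr, p, seed = 1)
  expect_equal(unname(det), rep(5, 10))
})

test_that("simulated moments agree with the model mean and covariance", {
  # 4-tip two-regime tree, moderate replication (the full-scale version of
  # this check runs in the acceptance suite)
  tr <- read_newick("(((A:0.3,B:0.3):0.4,C:0.7):0.3,D:1);")
  p <- regime_painting(tr, c("r2", "r2", "r2", "r1", "r1", "r1"), "r1")
  dec <- decompose_paths(tr, p)
  spec <- model_spec("OUMV", "h", 2)
  params <- model_params(spec, alpha = 1.5,
                         sigma = c(r1 = 0.5, r2 = 0.9),
                         theta = c(r1 = 2, r2 = 4))
  nsim <- 20000
  X <- simulate_tips(params, tr, p, seed = 99, nsim = nsim)
  W <- ou_weight_matrix(dec, 1.5)
  m <- drop(W %*% c(r1 = 2, r2 = 4)[colnames(W)])
  V <- ou_covariance(dec, 1.5, c(r1 = 0.25, r2 = 0.81))
  se_m <- sqrt(diag(V) / nsim)
  expect_true(all(abs(rowMeans(X) - m) <= 3 * se_m))
  Vhat <- cov(t(X))
  se_v <- sqrt((outer(diag(V), diag(V)) + V^2) / nsim)
  expect_true(all(abs(Vhat - V) <= 3 * se_v))
})

test_that("degenerate inputs raise errors rather than NaN", {
  tr <- read_newick("(A:1,B:1);")
  p <- regime_painting(tr, c("r1", "r1"), "r1")
  dec <- decompose_paths(tr, p)
  expect_error(ou_weight_matrix(dec, 0), "alpha")
  expect_error(ou_covariance(dec, -1, c(r1 = 1)), "alpha")
  spec <- model_spec("BM1", "h", 1)
  expect_error(log_likelihood(model_params(spec, sigma = 1, x0 = 0),
                              tr, p, c(A = 1)), "every tip")
})
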