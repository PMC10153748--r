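# Independent oracles used across the suite: mean and covariance of the
# regime-painted processes assembled by numerical quadrature over each
# root-to-tip path, and a brute-force multivariate-normal density.  These
# deliberately avoid the package's closed forms (they only reuse the path
# segments, i.e. the integration limits).

# E[x_i] for the OU process: int_0^{T_i} alpha e^{-alpha (T_i - u)} theta(u) du
#                            + e^{-alpha T_i} theta_root
oracle_ou_mean <- function(dec, alpha, theta, root_regime = dec$root_regime) {
  vapply(seq_len(dec$n), function(i) {
    segs <- dec$segments[[i]]
    Ti <- dec$tipT[i]
    acc <- exp(-alpha * Ti) * theta[[root_regime]]
    for (s in seq_len(nrow(segs))) {
      th <- theta[[segs$regime[s]]]
      acc <- acc + stats::integrate(
        function(u) alpha * exp(-alpha * (Ti - u)) * th,
        segs$a[s], segs$b[s], rel.tol = 1e-12)$value
    }
    acc
  }, 0)
}

# Cov[x_i, x_j] for the OU process:
#   int_0^{t_s} sigma2(u) e^{-alpha (T_i - u)} e^{-alpha (T_j - u)} du
oracle_ou_cov <- function(dec, alpha, sigma2) {
  n <- dec$n
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ts <- dec$ts[i, j]
    segs <- dec$segments[[i]]   # shared path is a prefix of either path
    acc <- 0
    for (s in seq_len(nrow(segs))) {
      a <- segs$a[s]; b <- min(segs$b[s], ts)
      if (b <= a) next
      s2 <- sigma2[[segs$regime[s]]]
      acc <- acc + stats::integrate(
        function(u) s2 * exp(-alpha * (dec$tipT[i] - u)) *
          exp(-alpha * (dec$tipT[j] - u)),
        a, b, rel.tol = 1e-12)$value
    }
    V[i, j] <- V[j, i] <- acc
  }
  dimnames(V) <- list(dec$tips, dec$tips)
  V
}

# Cov under BM: int over the shared path of sigma2(u) du
oracle_bm_cov <- function(dec, sigma2) {
  n <- dec$n
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ts <- dec$ts[i, j]
    segs <- dec$segments[[i]]
    acc <- 0
    for (s in seq_len(nrow(segs))) {
      a <- segs$a[s]; b <- min(segs$b[s], ts)
      if (b <= a) next
      s2 <- sigma2[[segs$regime[s]]]
      acc <- acc + stats::integrate(function(u) rep(s2, length(u)),
                                    a, b, rel.tol = 1e-12)$value
    }
    V[i, j] <- V[j, i] <- acc
  }
  dimnames(V) <- list(dec$tips, dec$tips)
  V
}

# Brute-force MVN log density via explicit inverse and determinant.
oracle_mvn_logdens <- function(x, m, V) {
  n <- length(x)
  -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus) -
    0.5 * drop(t(x - m) %*% solve(V) %*% (x - m))
}

# A random small tree with a random valid painting of `k` regimes (every
# label used on at least one edge; root label taken from the labels).
random_painted_tree <- function(n_tips, k, seed) {
  tree <- simulate_yule_tree(n_tips, seed = seed)
  labels <- paste0("r", seq_len(k))
  ne <- nrow(tree$edge)
  lab <- sample(rep(labels, length.out = ne))
  painting <- regime_painting(tree, lab, sample(labels, 1L))
  list(tree = tree, painting = painting,
       dec = decompose_paths(tree, painting), labels = labels)
}

# Random parameters for one model class on the given regime labels.
random_params <- function(class, labels, hypothesis = "test") {
  r <- length(labels)
  spec <- model_spec(class, hypothesis, if (class == "BM1") 1L else r)
  th <- stats::setNames(stats::runif(r, 1, 5), labels)
  switch(class,
    BM1 = model_params(spec, sigma = stats::runif(1, 0.3, 1.2), x0 = stats::runif(1, 1, 5)),
    BMS = model_params(spec, sigma = stats::setNames(stats::runif(r, 0.3, 1.2), labels),
                       x0 = stats::runif(1, 1, 5)),
    OUM = model_params(spec, alpha = stats::runif(1, 0.5, 3),
                       sigma = stats::runif(1, 0.3, 1.2), theta = th),
    OUMV = model_params(spec, alpha = stats::runif(1, 0.5, 3),
                        sigma = stats::setNames(stats::runif(r, 0.3, 1.2), labels),
                        theta = th))
}

# Model mean/covariance via the quadrature oracles for any class in scope.
oracle_moments <- function(params, dec) {
  labels <- dec$labels
  s <- params$sigma
  s2 <- if (length(s) == 1L) stats::setNames(rep(s^2, length(labels)), labels) else (s^2)[labels]
  if (params$spec$class %in% c("OUM", "OUMV")) {
    th <- params$theta[labels]
    list(mean = oracle_ou_mean(dec, params$alpha, as.list(th)),
         cov = oracle_ou_cov(dec, params$alpha, as.list(s2)))
  } else {
    list(mean = rep(params$x0, dec$n),
         cov = oracle_bm_cov(dec, as.list(s2)))
  }
}
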