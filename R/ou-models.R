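#' Model specification for regime-painted trait models
#'
#' Four fit-able model classes are supported: `BM1` (single-rate Brownian
#' motion), `BMS` (per-regime rates), `OUM` (Ornstein--Uhlenbeck with shared
#' pull \eqn{\alpha} and noise \eqn{\sigma}, per-regime equilibria
#' \eqn{\theta_i}), and `OUMV` (per-regime \eqn{\sigma_i} and
#' \eqn{\theta_i}, shared \eqn{\alpha}).  The multi-\eqn{\alpha} classes
#' `OUMA` and `OUMVA` may be enumerated but are not fit-able here; in
#' practice they are prone to fitting pathologies.
#'
#' Parameter counts: `BM1` k = 2 (\eqn{\sigma}, root state); `BMS` k = r + 1;
#' `OUM` k = r + 2; `OUMV` k = 2r + 1.
#'
#' @param class One of `"BM1"`, `"BMS"`, `"OUM"`, `"OUMV"`, `"OUMA"`,
#'   `"OUMVA"`.
#' @param hypothesis Hypothesis name the painting is coarsened under.
#' @param r Number of regimes.
#' @return An object of class `"model_spec"` with a `k` field.
#' @export
model_spec <- function(class, hypothesis, r) {
  class <- match.arg(class, c("BM1", "BMS", "OUM", "OUMV", "OUMA", "OUMVA"))
  r <- as.integer(r)
  stopifnot(r >= 1L)
  if (class == "BM1" && r != 1L) {
    stop("BM1 is a single-regime model (r = 1)")
  }
  k <- switch(class,
    BM1 = 2L,
    BMS = r + 1L,
    OUM = r + 2L,
    OUMV = 2L * r + 1L,
    OUMA = 2L * r + 1L,
    OUMVA = 3L * r)
  fit_able <- class %in% c("BM1", "BMS", "OUM", "OUMV")
  structure(list(class = class, hypothesis = hypothesis, r = r, k = k,
                 fit_able = fit_able),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s model, hypothesis '%s', r = %d regimes, k = %d parameters%s\n",
              x$class, x$hypothesis, x$r, x$k,
              if (x$fit_able) "" else " (enumeration only)"))
  invisible(x)
}

#' Parameter vector for a model
#'
#' @param spec A [model_spec()].
#' @param alpha Deterministic pull per unit time (OU classes; > 0).
#' @param sigma Per-regime stochastic noise intensity \eqn{\sigma}
#'   (trait units per sqrt(time)); a single value for `BM1`/`OUM` or a named
#'   vector over regime labels.
#' @param theta Per-regime deterministic equilibrium (OU classes; named
#'   vector over regime labels).
#' @param x0 Root state (BM classes).
#' @return An object of class `"model_params"`.
#' @export
model_params <- function(spec, alpha = NULL, sigma, theta = NULL, x0 = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  is_ou <- spec$class %in% c("OUM", "OUMV")
  if (is_ou) {
    if (is.null(alpha) || alpha <= 0) stop("OU classes require alpha > 0")
    if (is.null(theta) || length(theta) != spec$r) {
      stop("OU classes require one theta per regime")
    }
  } else {
    if (is.null(x0)) stop("BM classes require a root state x0")
  }
  nsig <- if (spec$class %in% c("BMS", "OUMV")) spec$r else 1L
  if (length(sigma) != nsig) {
    stop(sprintf("%s requires %d sigma value(s)", spec$class, nsig))
  }
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(spec = spec, alpha = alpha, sigma = sigma, theta = theta,
                 x0 = x0),
            class = "model_params")
}

# sigma^2 per regime label, recycling the shared-sigma classes.
.sigma2_by_regime <- function(params, labels) {
  s <- params$sigma
  if (length(s) == 1L) {
    stats::setNames(rep(s^2, length(labels)), labels)
  } else {
    if (is.null(names(s))) names(s) <- labels
    miss <- setdiff(labels, names(s))
    if (length(miss) > 0L) stop(sprintf("sigma missing for regime(s): %s",
                                        paste(miss, collapse = ", ")))
    (s^2)[labels]
  }
}

.theta_by_regime <- function(params, labels) {
  th <- params$theta
  if (is.null(names(th))) names(th) <- labels
  miss <- setdiff(labels, names(th))
  if (length(miss) > 0L) stop(sprintf("theta missing for regime(s): %s",
                                      paste(miss, collapse = ", ")))
  th[labels]
}

#' OU weight matrix
#'
#' For a tip i whose root-to-tip path (time 0 at the root, `T_i` at the tip)
#' is cut into regime segments, the expected trait value under a shared-pull
#' OU process is a convex combination of the regime equilibria:
#' \deqn{E[x_i] = e^{-\alpha T_i}\theta_{root} +
#'   \sum_{seg [a,b], regime \rho} (e^{-\alpha(T_i-b)} - e^{-\alpha(T_i-a)})
#'   \theta_\rho,}
#' the root term reflecting a root trait fixed at the root regime's
#' equilibrium.  `W` collects the weights so that `E[x] = W %*% theta`;
#' every row sums to one.
#'
#' @param decomposition A [decompose_paths()] object.
#' @param alpha Pull strength, > 0.
#' @param root_regime Label receiving the root weight; defaults to the
#'   painting's root regime.
#' @return An `n x r` matrix with regime labels as columns.
#' @export
ou_weight_matrix <- function(decomposition, alpha,
                             root_regime = decomposition$root_regime) {
  dec <- decomposition
  if (alpha <= 0) stop("alpha must be > 0 (use the BM classes at alpha = 0)")
  labels <- dec$labels
  r <- length(labels)
  ne <- length(dec$edge_a)
  # e^{alpha b} - e^{alpha a}, written to keep precision for small alpha
  inc <- exp(alpha * dec$edge_a) * expm1(alpha * dec$edge_len)
  M <- matrix(0, ne, r)
  M[cbind(seq_len(ne), dec$edge_regime)] <- inc
  W <- crossprod(dec$D, M) * exp(-alpha * dec$tipT)
  ri <- match(root_regime, labels)
  if (is.na(ri)) stop(sprintf("root regime '%s' not among painting labels",
                              root_regime))
  W[, ri] <- W[, ri] + exp(-alpha * dec$tipT)
  dimnames(W) <- list(dec$tips, labels)
  W
}

#' OU trait covariance among tips
#'
#' With the root trait fixed, the covariance of tips i and j under a
#' shared-pull OU process with per-regime noise is
#' \deqn{V_{ij} = e^{-\alpha(T_i+T_j)} \sum_{seg [a,b] \subset [0,t_s],
#'   regime \rho} \sigma_\rho^2 \frac{e^{2\alpha b} - e^{2\alpha a}}{2\alpha},}
#' summing over the shared root-to-MRCA path (the full path on the
#' diagonal).
#'
#' @param decomposition A [decompose_paths()] object.
#' @param alpha Pull strength, > 0.
#' @param sigma2 Per-regime noise variances \eqn{\sigma^2} (named by regime
#'   label, or a single shared value).
#' @return Symmetric positive-definite `n x n` matrix.
#' @export
ou_covariance <- function(decomposition, alpha, sigma2) {
  dec <- decomposition
  if (alpha <= 0) stop("alpha must be > 0")
  labels <- dec$labels
  if (length(sigma2) == 1L) sigma2 <- stats::setNames(rep(sigma2, length(labels)), labels)
  s2 <- sigma2[labels]
  if (anyNA(s2)) stop("sigma2 must be named by regime label")
  ce <- s2[dec$edge_regime] * exp(2 * alpha * dec$edge_a) *
    expm1(2 * alpha * dec$edge_len) / (2 * alpha)
  V0 <- crossprod(dec$D * sqrt(ce))
  u <- exp(-alpha * dec$tipT)
  V <- V0 * tcrossprod(u)
  dimnames(V) <- list(dec$tips, dec$tips)
  V
}

#' BM trait covariance among tips
#'
#' \eqn{V_{ij}} is the noise-variance-weighted length of the shared
#' root-to-MRCA path: \eqn{\sum \sigma_\rho^2 (b - a)} over shared segments
#' (the tip's own path on the diagonal).
#'
#' @inheritParams ou_covariance
#' @return Symmetric positive-definite `n x n` matrix.
#' @export
bm_covariance <- function(decomposition, sigma2) {
  dec <- decomposition
  labels <- dec$labels
  if (length(sigma2) == 1L) sigma2 <- stats::setNames(rep(sigma2, length(labels)), labels)
  s2 <- sigma2[labels]
  if (anyNA(s2)) stop("sigma2 must be named by regime label")
  ce <- s2[dec$edge_regime] * dec$edge_len
  V <- crossprod(dec$D * sqrt(ce))
  dimnames(V) <- list(dec$tips, dec$tips)
  V
}

# Mean vector and covariance implied by a (spec, params) pair.
model_moments <- function(params, decomposition) {
  spec <- params$spec
  labels <- decomposition$labels
  if (spec$class %in% c("OUM", "OUMV")) {
    s2 <- .sigma2_by_regime(params, labels)
    th <- .theta_by_regime(params, labels)
    W <- ou_weight_matrix(decomposition, params$alpha)
    list(mean = drop(W %*% th[colnames(W)]),
         cov = ou_covariance(decomposition, params$alpha, s2))
  } else {
    s2 <- .sigma2_by_regime(params, labels)
    list(mean = stats::setNames(rep(params$x0, decomposition$n),
                                decomposition$tips),
         cov = bm_covariance(decomposition, s2))
  }
}

# log MVN density via Cholesky; stops (never NaN) on a non-PD covariance.
.mvn_loglik <- function(x, mean, V) {
  L <- tryCatch(t(chol(V)), error = function(e) {
    stop("covariance matrix is not positive definite (degenerate tree or parameters)")
  })
  z <- forwardsolve(L, x - mean)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Exact log-likelihood of tip data under a regime-painted model
#'
#' The tip trait vector under every model class in scope is multivariate
#' normal; the mean is `W %*% theta` for OU classes (root fixed at the root
#' regime's equilibrium) or the root state for BM classes, and the
#' covariance comes from [ou_covariance()] / [bm_covariance()].  The density
#' is evaluated through a Cholesky factorization.
#'
#' @param params A [model_params()].
#' @param tree A `"phylo"` object.
#' @param painting A [regime_painting()] coarsened to the model's regimes.
#' @param data Named numeric vector of tip trait values (ln pg).
#' @param decomposition Optional pre-computed [decompose_paths()]; passing it
#'   avoids recomputation in replicate-heavy procedures.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(params, tree, painting, data,
                           decomposition = NULL) {
  stopifnot(inherits(params, "model_params"))
  dec <- if (is.null(decomposition)) decompose_paths(tree, painting) else decomposition
  x <- data[dec$tips]
  if (anyNA(x)) stop("data must cover every tip of the tree")
  mom <- model_moments(params, dec)
  .mvn_loglik(x, mom$mean, mom$cov)
}

#' Simulate tip data under a regime-painted model
#'
#' Exact recursive simulation along the tree: the root value is the root
#' regime's equilibrium (OU) or the root state `x0` (BM); along an edge of
#' length `dt` in regime \eqn{\rho} a child value is drawn from
#' \deqn{N(\theta_\rho + (x_{par} - \theta_\rho) e^{-\alpha dt},\;
#'        \sigma_\rho^2 (1 - e^{-2\alpha dt}) / (2\alpha))}
#' for OU, or \eqn{N(x_{par}, \sigma_\rho^2 dt)} for BM.  `sigma = 0` is
#' allowed here (deterministic decay), though not in fitting.
#'
#' @inheritParams log_likelihood
#' @param seed Optional integer seed; if supplied, the draw is reproducible.
#' @param nsim Number of replicate tip vectors.
#' @return A named vector of tip values when `nsim = 1`, else an
#'   `n x nsim` matrix with tips as rows.
#' @export
simulate_tips <- function(params, tree, painting, seed = NULL, nsim = 1L,
                          decomposition = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  dec <- if (is.null(decomposition)) decompose_paths(tree, painting) else decomposition
  spec <- params$spec
  labels <- dec$labels
  is_ou <- spec$class %in% c("OUM", "OUMV")
  s2 <- .sigma2_by_regime(params, labels)
  n <- dec$n
  ntot <- n + tree$Nnode
  root <- n + 1L

  vals <- matrix(NA_real_, ntot, nsim)
  if (is_ou) {
    th <- .theta_by_regime(params, labels)
    vals[root, ] <- th[dec$root_regime]
  } else {
    vals[root, ] <- params$x0
  }

  clade <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(
    paste(clade$edge[, 1L], clade$edge[, 2L]),
    paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (idx in seq_along(ord)) {
    e <- ord[idx]
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    dt <- dec$edge_len[e]
    rho <- dec$edge_regime[e]
    parent_val <- vals[p, ]
    if (is_ou) {
      a <- params$alpha
      m <- th[rho] + (parent_val - th[rho]) * exp(-a * dt)
      v <- s2[rho] * (-expm1(-2 * a * dt)) / (2 * a)
    } else {
      m <- parent_val
      v <- s2[rho] * dt
    }
    vals[ch, ] <- m + sqrt(v) * stats::rnorm(nsim)
  }
  out <- vals[seq_len(n), , drop = FALSE]
  rownames(out) <- dec$tips
  if (nsim == 1L) drop(out)[dec$tips] else out
}
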