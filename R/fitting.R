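#' Optimizer configuration for model fitting
#'
#' The likelihood is maximized over `(log alpha, log sigma-ratios)` with the
#' regime equilibria (or BM root state) profiled out by generalized least
#' squares and the overall noise scale profiled analytically, so the
#' numerical search is low-dimensional.  `alpha` starts are laid out on a
#' grid of phylogenetic half-lives `log(2)/alpha` spanning roughly
#' `[T/50, 2T]` for tree height `T`; log-scale parameterization keeps the
#' scale parameters away from boundary pathologies.
#'
#' @param alpha_halflives Half-life grid (as fractions of tree height) from
#'   which `alpha` multi-starts are derived.
#' @param alpha_bounds Bounds on `alpha * T` (tree-height units).
#' @param delta_bound Bound on `|log(sigma_i^2 / sigma_1^2)|`.
#' @param factr `optim` L-BFGS-B `factr` (1e7 corresponds to ~1e-9 relative
#'   tolerance on the log-likelihood).
#' @param maxit Maximum optimizer iterations per start.
#' @param init_params Optional [model_params()] used as an additional start
#'   (replicate fits in bootstrap procedures start from the observed-data
#'   MLE).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(alpha_halflives = c(1 / 50, 1 / 10, 1 / 2, 2),
                       alpha_bounds = c(1e-3, 50),
                       delta_bound = 12,
                       factr = 1e7, maxit = 500L,
                       init_params = NULL) {
  structure(list(alpha_halflives = alpha_halflives,
                 alpha_bounds = alpha_bounds,
                 delta_bound = delta_bound,
                 factr = factr, maxit = maxit,
                 init_params = init_params),
            class = "fit_config")
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logL Log-likelihood at the maximum.
#' @param k Number of free parameters.
#' @param n Number of tips.
#' @return The AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc requires n > k + 1 (small-sample correction divides by n-k-1)")
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate candidate models over the regime hypotheses
#'
#' The single-regime hypothesis admits only BM1; each multi-regime
#' hypothesis is crossed with the five multi-regime classes
#' (BMS, OUM, OUMV, OUMA, OUMVA), giving 21 specifications over the five
#' built-in hypotheses.  Excluding the multi-`alpha` classes (which are
#' enumeration-only) leaves 13 fit-able specifications.
#'
#' @param hypotheses A list of [regime_hypothesis()] objects (default the
#'   five built-ins).
#' @param fit_able_only If `TRUE`, drop the multi-`alpha` classes.
#' @return A list of [model_spec()] objects.
#' @export
enumerate_models <- function(hypotheses = build_hypotheses(),
                             fit_able_only = FALSE) {
  specs <- list()
  for (h in hypotheses) {
    if (h$r == 1L) {
      specs <- c(specs, list(model_spec("BM1", h$name, 1L)))
    } else {
      for (cl in c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")) {
        specs <- c(specs, list(model_spec(cl, h$name, h$r)))
      }
    }
  }
  if (fit_able_only) specs <- Filter(function(s) s$fit_able, specs)
  specs
}

# Concentrated negative log-likelihood: mean coefficients by GLS, overall
# noise scale analytic.  Returns the pieces needed to reassemble the fit.
.concentrated_fit <- function(x, W, Vtilde) {
  n <- length(x)
  L <- t(chol(Vtilde))
  A <- forwardsolve(L, W)
  y <- forwardsolve(L, x)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) stop("design is rank deficient at these parameters")
  beta <- qr.coef(qrA, y)
  rss <- sum((y - A %*% beta)^2)
  s2 <- rss / n
  logL <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) -
    sum(log(diag(L))) - 0.5 * n
  list(beta = drop(beta), scale2 = s2, logL = logL)
}

# Relative sigma^2 per regime from the free ratio parameters (first regime
# is the reference with ratio 1).
.rel_sigma2 <- function(delta, labels) {
  stats::setNames(exp(c(0, delta)), labels)
}

# Evaluate the concentrated logL for one model class at free parameters.
.eval_model <- function(par, class, dec, x) {
  labels <- dec$labels
  r <- length(labels)
  if (class == "BM1") {
    W <- matrix(1, dec$n, 1)
    Vt <- bm_covariance(dec, stats::setNames(rep(1, r), labels))
    cf <- .concentrated_fit(x, W, Vt)
    return(list(logL = cf$logL, x0 = cf$beta, sigma2 = cf$scale2))
  }
  if (class == "BMS") {
    s2rel <- .rel_sigma2(par, labels)
    W <- matrix(1, dec$n, 1)
    Vt <- bm_covariance(dec, s2rel)
    cf <- .concentrated_fit(x, W, Vt)
    return(list(logL = cf$logL, x0 = cf$beta,
                sigma2 = cf$scale2 * s2rel))
  }
  alpha <- exp(par[1L])
  if (class == "OUM") {
    s2rel <- stats::setNames(rep(1, r), labels)
  } else { # OUMV
    s2rel <- .rel_sigma2(par[-1L], labels)
  }
  W <- ou_weight_matrix(dec, alpha)
  Vt <- ou_covariance(dec, alpha, s2rel)
  cf <- .concentrated_fit(x, W, Vt)
  list(logL = cf$logL, alpha = alpha,
       theta = stats::setNames(cf$beta, colnames(W)),
       sigma2 = cf$scale2 * s2rel)
}

# Free-parameter starting vectors for a class, from the config grid (and the
# optional warm start).
.start_vectors <- function(class, dec, config) {
  labels <- dec$labels
  r <- length(labels)
  H <- max(dec$tipT)
  starts <- list()
  nd <- if (class %in% c("BMS", "OUMV")) r - 1L else 0L
  if (class == "BM1") return(list(numeric(0)))
  if (class == "BMS") {
    starts <- list(rep(0, nd))
  } else if (class == "OUM") {
    starts <- lapply(config$alpha_halflives, function(h) log(log(2) / (h * H)))
  } else if (class == "OUMV") {
    starts <- lapply(config$alpha_halflives,
                     function(h) c(log(log(2) / (h * H)), rep(0, nd)))
  }
  ip <- config$init_params
  if (!is.null(ip) && ip$spec$class == class) {
    s2 <- .sigma2_by_regime(ip, labels)
    warm <- switch(class,
      BMS = log(s2[-1L] / s2[1L]),
      OUM = log(ip$alpha),
      OUMV = c(log(ip$alpha), log(s2[-1L] / s2[1L])))
    starts <- c(list(unname(warm)), starts)
  }
  starts
}

.param_bounds <- function(class, dec, config) {
  labels <- dec$labels
  r <- length(labels)
  H <- max(dec$tipT)
  la <- log(config$alpha_bounds / H)
  db <- config$delta_bound
  switch(class,
    BM1 = list(lower = numeric(0), upper = numeric(0)),
    BMS = list(lower = rep(-db, r - 1L), upper = rep(db, r - 1L)),
    OUM = list(lower = la[1L], upper = la[2L]),
    OUMV = list(lower = c(la[1L], rep(-db, r - 1L)),
                upper = c(la[2L], rep(db, r - 1L))))
}

#' Fit a regime-painted trait model by maximum likelihood
#'
#' Maximizes the exact multivariate-normal log-likelihood.  The regime
#' equilibria (OU) or root state (BM) are profiled out by generalized least
#' squares at every evaluation, the overall noise scale is profiled
#' analytically, and the remaining free parameters (`log alpha` and the log
#' noise-variance ratios) are optimized by bounded quasi-Newton search from
#' a multi-start grid.  BM1 has a closed-form maximum and needs no search.
#'
#' @param spec A [model_spec()]; must be fit-able.
#' @param tree A `"phylo"` object.
#' @param painting A [regime_painting()] already coarsened to the model's
#'   hypothesis (its regime count must equal `spec$r`).
#' @param data Named numeric vector of tip trait values.
#' @param config A [fit_config()].
#' @param decomposition Optional pre-computed [decompose_paths()].
#' @return An object of class `"ou_fit"`: `spec`, `params` (MLEs as
#'   [model_params()]), `logL`, `k`, `n`, `AICc`, `converged`, `n_starts`.
#'   When no start converges the result has `converged = FALSE` and `NA`
#'   likelihood.
#' @export
fit_model <- function(spec, tree, painting, data, config = fit_config(),
                      decomposition = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$fit_able) {
    stop(sprintf("%s is enumeration-only and cannot be fit", spec$class))
  }
  dec <- if (is.null(decomposition)) decompose_paths(tree, painting) else decomposition
  labels <- dec$labels
  if (length(labels) != spec$r) {
    stop(sprintf("painting has %d regimes but spec expects %d",
                 length(labels), spec$r))
  }
  x <- data[dec$tips]
  if (anyNA(x)) stop("data must cover every tip of the tree")
  n <- dec$n

  nll <- function(par) {
    out <- tryCatch(.eval_model(par, spec$class, dec, x)$logL,
                    error = function(e) -Inf)
    if (!is.finite(out)) 1e10 else -out
  }

  starts <- .start_vectors(spec$class, dec, config)
  bounds <- .param_bounds(spec$class, dec, config)

  best <- NULL; best_val <- Inf; n_conv <- 0L
  if (spec$class == "BM1") {
    val <- nll(numeric(0))
    if (val < 1e10) { best <- numeric(0); best_val <- val; n_conv <- 1L }
  } else {
    for (s in starts) {
      s <- pmin(pmax(s, bounds$lower), bounds$upper)
      opt <- tryCatch(
        stats::optim(s, nll, method = "L-BFGS-B",
                     lower = bounds$lower, upper = bounds$upper,
                     control = list(factr = config$factr,
                                    maxit = config$maxit)),
        error = function(e) NULL)
      if (is.null(opt) || opt$value >= 1e10) next
      if (opt$convergence == 0L) n_conv <- n_conv + 1L
      if (opt$value < best_val) { best <- opt$par; best_val <- opt$value }
    }
  }

  if (is.null(best) || n_conv == 0L) {
    return(structure(list(spec = spec, params = NULL, logL = NA_real_,
                          k = spec$k, n = n, AICc = NA_real_,
                          converged = FALSE, n_starts = length(starts)),
                     class = "ou_fit"))
  }

  ev <- .eval_model(best, spec$class, dec, x)
  params <- if (spec$class %in% c("OUM", "OUMV")) {
    sig <- sqrt(ev$sigma2)
    model_params(spec, alpha = ev$alpha,
                 sigma = if (spec$class == "OUM") unname(sig[1L]) else sig,
                 theta = ev$theta[labels])
  } else {
    sig <- sqrt(ev$sigma2)
    model_params(spec,
                 sigma = if (spec$class == "BM1") unname(sig[1L]) else sig,
                 x0 = unname(ev$x0))
  }
  structure(list(spec = spec, params = params, logL = ev$logL, k = spec$k,
                 n = n, AICc = aicc(ev$logL, spec$k, n), converged = TRUE,
                 n_starts = length(starts)),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("%s fit (hypothesis '%s'): DID NOT CONVERGE\n",
                x$spec$class, x$spec$hypothesis))
    return(invisible(x))
  }
  cat(sprintf("%s fit (hypothesis '%s'): logL = %.4f, k = %d, AICc = %.4f\n",
              x$spec$class, x$spec$hypothesis, x$logL, x$k, x$AICc))
  p <- x$params
  if (!is.null(p$alpha)) cat(sprintf("  alpha = %.4g\n", p$alpha))
  cat("  sigma =", paste(sprintf("%.4g", p$sigma), collapse = ", "), "\n")
  if (!is.null(p$theta)) {
    cat("  theta =", paste(sprintf("%s: %.4g", names(p$theta), p$theta),
                           collapse = ", "), "\n")
  }
  if (!is.null(p$x0)) cat(sprintf("  x0 = %.4g\n", p$x0))
  invisible(x)
}

#' Rank fitted models by AICc
#'
#' @param fits A list of [fit_model()] results.
#' @param support_cutoff `Delta AICc` below which a model belongs to the
#'   support set (default 4).
#' @return An object of class `"model_table"`: `table` (data frame sorted by
#'   AICc with `dAICc`), `best` (the top fit), `support` (rows with
#'   `dAICc <= support_cutoff`), `n_failed`.
#' @export
build_model_table <- function(fits, support_cutoff = 4) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0L) stop("no model fit converged; nothing to rank")
  df <- do.call(rbind, lapply(ok, function(f) {
    data.frame(hypothesis = f$spec$hypothesis, class = f$spec$class,
               k = f$k, logL = f$logL, AICc = f$AICc,
               stringsAsFactors = FALSE)
  }))
  df$dAICc <- df$AICc - min(df$AICc)
  ord <- order(df$AICc, df$k)  # AICc ties broken toward fewer parameters
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(table = df, best = ok[[ord[1L]]],
                 support = df[df$dAICc <= support_cutoff, , drop = FALSE],
                 n_failed = length(fits) - length(ok)),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  cat("Model comparison (AICc):\n")
  print(transform(x$table, logL = round(logL, 3), AICc = round(AICc, 2),
                  dAICc = round(dAICc, 2)))
  if (x$n_failed > 0L) cat(sprintf("(%d fit(s) failed to converge)\n", x$n_failed))
  invisible(x)
}

#' Flatten model parameters to a named numeric vector
#'
#' Order: `alpha` (OU), `sigma_<regime>`, `theta_<regime>` (OU) or `x0` (BM).
#'
#' @param params A [model_params()].
#' @return Named numeric vector.
#' @export
flatten_params <- function(params) {
  out <- c()
  if (!is.null(params$alpha)) out <- c(alpha = params$alpha)
  s <- params$sigma
  if (length(s) == 1L && is.null(names(s))) {
    out <- c(out, sigma = unname(s))
  } else {
    out <- c(out, stats::setNames(unname(s), paste0("sigma_", names(s))))
  }
  if (!is.null(params$theta)) {
    th <- params$theta
    out <- c(out, stats::setNames(unname(th), paste0("theta_", names(th))))
  }
  if (!is.null(params$x0)) out <- c(out, x0 = unname(params$x0))
  out
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `n_reps` datasets at the fitted MLEs, refits the same model to
#' each (warm-started from the observed-data MLE), and reports per-parameter
#' percentile intervals.  Replicate fits that fail to converge are dropped
#' and counted; if more than half fail the procedure errors out.
#'
#' @param fit A converged [fit_model()] result.
#' @param tree,painting The tree and (coarsened) painting the fit used.
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param level Interval level in percent (default 95: percentile bounds at
#'   2.5 and 97.5).
#' @param seed Integer seed; the procedure is reproducible given it.
#' @param config A [fit_config()] for the replicate fits.
#' @return An object of class `"bootstrap_ci"`: data frame `ci` with
#'   `parameter`, `estimate`, `lower`, `upper`; counts `n_ok`, `n_fail`;
#'   `level`; `seed`; matrix `replicates` of per-replicate estimates.
#' @export
bootstrap_ci <- function(fit, tree, painting, n_reps = 500L, level = 95,
                         seed = 1L, config = NULL) {
  stopifnot(inherits(fit, "ou_fit"), isTRUE(fit$converged),
            n_reps >= 2L, level > 0, level < 100)
  if (is.null(config)) config <- fit_config(init_params = fit$params)
  dec <- decompose_paths(tree, painting)
  est <- flatten_params(fit$params)

  set.seed(seed)
  sims <- simulate_tips(fit$params, tree, painting, nsim = n_reps,
                        decomposition = dec)
  reps <- matrix(NA_real_, n_reps, length(est),
                 dimnames = list(NULL, names(est)))
  n_fail <- 0L
  for (b in seq_len(n_reps)) {
    rf <- tryCatch(
      fit_model(fit$spec, tree, painting, sims[, b], config = config,
                decomposition = dec),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { n_fail <- n_fail + 1L; next }
    reps[b, ] <- flatten_params(rf$params)[names(est)]
  }
  if (n_fail > n_reps / 2) {
    stop(sprintf("bootstrap failed: %d of %d replicate fits did not converge",
                 n_fail, n_reps))
  }
  ok <- stats::complete.cases(reps)
  pr <- c((100 - level) / 200, 1 - (100 - level) / 200)
  qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile, probs = pr,
              names = FALSE)
  structure(list(
    ci = data.frame(parameter = names(est), estimate = unname(est),
                    lower = qs[1L, ], upper = qs[2L, ],
                    stringsAsFactors = FALSE),
    n_ok = sum(ok), n_fail = n_fail, level = level, seed = seed,
    replicates = reps[ok, , drop = FALSE]),
    class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Parametric bootstrap %g%% CIs (%d ok, %d failed replicates):\n",
              x$level, x$n_ok, x$n_fail))
  print(transform(x$ci, estimate = signif(estimate, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4)))
  invisible(x)
}
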