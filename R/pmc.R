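#' Observed likelihood-difference statistic
#'
#' `delta_obs = -2 (logL_0 - logL_1)` where model 0 is the simpler and model
#' 1 the more complex of a nested (or quasi-nested) pair fitted to the same
#' data.
#'
#' @param fit_simple,fit_complex Converged [fit_model()] results on the same
#'   data.
#' @return The statistic (a scalar).
#' @export
delta_obs <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "ou_fit"), inherits(fit_complex, "ou_fit"))
  -2 * (fit_simple$logL - fit_complex$logL)
}

# One arm of the Monte Carlo: simulate `n_sims` datasets under `gen_fit`'s
# MLEs, fit both models to each, collect the delta statistics.
.pmc_arm <- function(gen_fit, fit0, fit1, tree, painting0, painting1,
                     dec0, dec1, n_sims, seed, config0, config1) {
  set.seed(seed)
  gen_dec <- if (identical(gen_fit$spec, fit0$spec)) dec0 else dec1
  gen_paint <- if (identical(gen_fit$spec, fit0$spec)) painting0 else painting1
  sims <- simulate_tips(gen_fit$params, tree, gen_paint, nsim = n_sims,
                        decomposition = gen_dec)
  deltas <- rep(NA_real_, n_sims)
  n_fail <- 0L
  for (b in seq_len(n_sims)) {
    x <- sims[, b]
    f0 <- tryCatch(fit_model(fit0$spec, tree, painting0, x, config = config0,
                             decomposition = dec0), error = function(e) NULL)
    f1 <- tryCatch(fit_model(fit1$spec, tree, painting1, x, config = config1,
                             decomposition = dec1), error = function(e) NULL)
    if (is.null(f0) || is.null(f1) || !f0$converged || !f1$converged) {
      n_fail <- n_fail + 1L
      next
    }
    deltas[b] <- delta_obs(f0, f1)
  }
  if (n_fail > n_sims / 2) {
    stop(sprintf("phylogenetic Monte Carlo arm failed: %d of %d replicate fit pairs did not converge",
                 n_fail, n_sims))
  }
  list(delta = deltas[!is.na(deltas)], n_fail = n_fail)
}

#' Phylogenetic Monte Carlo model comparison
#'
#' Parametric-bootstrap comparison of a simpler against a more complex
#' model.  Both models are fitted to the observed data, giving
#' `delta_obs = -2 (logL_0 - logL_1)`.  Then `n_sims` datasets are
#' simulated under the simpler model at its MLEs and both models refitted to
#' each, yielding the null distribution of `delta`; the approximate p-value
#' is the fraction of null `delta` values at or above `delta_obs`.  The same
#' is done under the complex model's MLEs for the alternative distribution;
#' power is the fraction of alternative `delta` values above the 95th
#' percentile of the null distribution.  The two arms draw from independent
#' RNG streams derived from the master seed, so changing `n_sims` in one arm
#' does not perturb the other.  Replicate fits are warm-started at the
#' observed-data MLEs.
#'
#' @param spec_simple,spec_complex [model_spec()]s of the pair.
#' @param tree A `"phylo"` object.
#' @param painting_simple,painting_complex Paintings coarsened to each
#'   spec's hypothesis.
#' @param data Named numeric vector of tip traits.
#' @param n_sims Simulations per arm (default 500).
#' @param seed Master integer seed.
#' @param config A [fit_config()] for the observed-data fits.
#' @param arms Which arms to run: `"both"` (default), `"null"` (p-value
#'   only), or `"alt"`.
#' @return An object of class `"pmc_result"`: `delta_obs`, `null_delta`,
#'   `alt_delta`, `p_value`, `power`, `null_q95`, failure counts, `seed`,
#'   and both fits.
#' @export
pmc_compare <- function(spec_simple, spec_complex, tree,
                        painting_simple, painting_complex, data,
                        n_sims = 500L, seed = 1L, config = fit_config(),
                        arms = c("both", "null", "alt")) {
  arms <- match.arg(arms)
  stopifnot(n_sims >= 2L)
  dec0 <- decompose_paths(tree, painting_simple)
  dec1 <- decompose_paths(tree, painting_complex)
  fit0 <- fit_model(spec_simple, tree, painting_simple, data, config = config,
                    decomposition = dec0)
  fit1 <- fit_model(spec_complex, tree, painting_complex, data, config = config,
                    decomposition = dec1)
  if (!fit0$converged || !fit1$converged) {
    stop("observed-data fit did not converge; cannot run the comparison")
  }
  dobs <- delta_obs(fit0, fit1)
  cfg0 <- fit_config(init_params = fit0$params)
  cfg1 <- fit_config(init_params = fit1$params)

  # independent streams per arm, both reachable from the master seed
  seed_null <- (as.integer(seed) %% 1000000L) * 2L + 101L
  seed_alt <- (as.integer(seed) %% 1000000L) * 2L + 102L

  null_arm <- alt_arm <- list(delta = numeric(0), n_fail = NA_integer_)
  if (arms %in% c("both", "null")) {
    null_arm <- .pmc_arm(fit0, fit0, fit1, tree, painting_simple,
                         painting_complex, dec0, dec1, n_sims, seed_null,
                         cfg0, cfg1)
  }
  if (arms %in% c("both", "alt")) {
    alt_arm <- .pmc_arm(fit1, fit0, fit1, tree, painting_simple,
                        painting_complex, dec0, dec1, n_sims, seed_alt,
                        cfg0, cfg1)
  }

  p_value <- if (length(null_arm$delta) > 0L) {
    mean(null_arm$delta >= dobs)
  } else NA_real_
  null_q95 <- if (length(null_arm$delta) > 0L) {
    stats::quantile(null_arm$delta, 0.95, names = FALSE)
  } else NA_real_
  power <- if (length(alt_arm$delta) > 0L && !is.na(null_q95)) {
    mean(alt_arm$delta > null_q95)
  } else NA_real_

  structure(list(
    spec_simple = spec_simple, spec_complex = spec_complex,
    fit_simple = fit0, fit_complex = fit1,
    delta_obs = dobs, null_delta = null_arm$delta, alt_delta = alt_arm$delta,
    p_value = p_value, power = power, null_q95 = null_q95,
    n_fail_null = null_arm$n_fail, n_fail_alt = alt_arm$n_fail,
    n_sims = n_sims, seed = seed),
    class = "pmc_result")
}

#' @export
print.pmc_result <- function(x, ...) {
  cat(sprintf("Phylogenetic Monte Carlo: %s/%s (simple) vs %s/%s (complex)\n",
              x$spec_simple$class, x$spec_simple$hypothesis,
              x$spec_complex$class, x$spec_complex$hypothesis))
  cat(sprintf("  delta_obs = %.4f\n", x$delta_obs))
  if (!is.na(x$p_value)) {
    ptxt <- if (x$p_value == 0) sprintf("< %.4g", 1 / x$n_sims) else
      sprintf("%.4g", x$p_value)
    cat(sprintf("  p-value = %s  (null 95th percentile %.4f, %d sims)\n",
                ptxt, x$null_q95, length(x$null_delta)))
  }
  if (!is.na(x$power)) cat(sprintf("  power = %.4g\n", x$power))
  invisible(x)
}
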