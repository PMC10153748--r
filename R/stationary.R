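#' Stationary distribution of a fitted OU regime
#'
#' An OU process with pull `alpha`, equilibrium `theta` and noise `sigma`
#' forgets its starting value at rate `alpha` and settles into a normal
#' stationary law with mean `theta` and variance `sigma^2 / (2 alpha)`.
#'
#' @param params A [model_params()] from an OU-class model.
#' @param regime Regime label.
#' @return List with `mean`, `variance`, `sd`.
#' @export
stationary_distribution <- function(params, regime) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(params$alpha) || params$alpha <= 0) {
    stop("stationary distribution requires alpha > 0 (BM has none)")
  }
  th <- params$theta
  if (!(regime %in% names(th))) {
    stop(sprintf("unknown regime '%s'", regime))
  }
  s <- params$sigma
  sig <- if (length(s) == 1L) unname(s) else unname(s[regime])
  v <- sig^2 / (2 * params$alpha)
  list(mean = unname(th[regime]), variance = v, sd = sqrt(v))
}

#' Observed vs stationary trait distributions by regime
#'
#' For each regime, tabulates the observed tip traits (count, sample mean
#' and variance) next to the stationary distribution implied by the fitted
#' parameters, on the natural-log scale; this is the numerical content of a
#' histogram-with-density-overlay comparison.  Empty regimes are reported
#' with count 0 and no summary statistics.
#'
#' @param data Named numeric vector of tip trait values (ln pg).
#' @param tree A `"phylo"` object.
#' @param painting A [regime_painting()] matching the fitted regimes.
#' @param params OU-class [model_params()].
#' @return A data frame of class `"stationary_summary"` with one row per
#'   regime: `regime`, `n_tips`, `obs_mean`, `obs_var`, `pred_mean`,
#'   `pred_var`, `pred_sd`.
#' @export
regime_summary <- function(data, tree, painting, params) {
  regs <- tip_regimes(tree, painting)
  labels <- painting$labels
  rows <- lapply(labels, function(lab) {
    x <- data[names(regs)[regs == lab]]
    st <- stationary_distribution(params, lab)
    data.frame(
      regime = lab, n_tips = length(x),
      obs_mean = if (length(x) > 0L) mean(x) else NA_real_,
      obs_var = if (length(x) > 1L) stats::var(x) else NA_real_,
      pred_mean = st$mean, pred_var = st$variance, pred_sd = st$sd,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stationary_summary", class(out))
  out
}

#' Freedman--Diaconis histogram breaks for a regime overlay export
#'
#' @param x Numeric trait values of one regime.
#' @return Break points suitable for `hist(..., breaks = )`.
#' @export
fd_breaks <- function(x) {
  stopifnot(length(x) >= 2L)
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) h <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  if (h <= 0) h <- 1
  seq(floor(min(x) / h) * h, max(x) + h, by = h)
}
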