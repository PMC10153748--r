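#' Configuration of a full analysis run
#'
#' Collects everything a complete run needs: the inputs (tree, tip
#' life-history states, trait values), the regime hypotheses to fit under,
#' optional internal-node state overrides (e.g. the two assignments of a
#' contested ancestral node), replicate counts, and the master seed from
#' which every random draw in the run derives.
#'
#' @param tree A `"phylo"` object.
#' @param tip_states Named character vector of life-history codes per tip.
#' @param data Named numeric vector of tip trait values (ln pg).
#' @param hypotheses List of [regime_hypothesis()] (default the five
#'   built-ins).
#' @param internal_overrides,alt_overrides Optional named vectors for
#'   [paint_from_tip_states()]; when `alt_overrides` is given, model fitting
#'   is repeated under the alternative painting and both tables reported.
#' @param n_reps Bootstrap-CI replicates (default 500; 199 is a practical
#'   reduced setting).
#' @param n_sims Monte Carlo simulations per comparison arm (default 500).
#' @param level CI level in percent.
#' @param seed Master integer seed.
#' @param out_dir Output directory for [run_report()].
#' @param fit Config passed to the fitters ([fit_config()]).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tree, tip_states, data,
                       hypotheses = build_hypotheses(),
                       internal_overrides = NULL, alt_overrides = NULL,
                       n_reps = 500L, n_sims = 500L, level = 95,
                       seed = 1L, out_dir = tempfile("ouregimes_run_"),
                       fit = fit_config()) {
  structure(list(tree = tree, tip_states = tip_states, data = data,
                 hypotheses = hypotheses,
                 internal_overrides = internal_overrides,
                 alt_overrides = alt_overrides,
                 n_reps = as.integer(n_reps), n_sims = as.integer(n_sims),
                 level = level, seed = as.integer(seed), out_dir = out_dir,
                 fit = fit),
            class = "run_config")
}

# Fit every fit-able spec under one base painting; returns fits + paintings.
.fit_all_once <- function(config, overrides) {
  base <- paint_from_tip_states(config$tree, config$tip_states, overrides)
  specs <- enumerate_models(config$hypotheses, fit_able_only = TRUE)
  paintings <- lapply(config$hypotheses, function(h) coarsen(base, h))
  decs <- lapply(paintings, function(p) decompose_paths(config$tree, p))
  fits <- lapply(specs, function(s) {
    fit_model(s, config$tree, paintings[[s$hypothesis]], config$data,
              config = config$fit,
              decomposition = decs[[s$hypothesis]])
  })
  list(fits = fits, paintings = paintings, base = base)
}

#' Fit all candidate models and build the AICc table
#'
#' Paints regimes from the tip states (applying any internal-node
#' overrides), coarsens the painting under each hypothesis, fits the 13
#' fit-able models, and ranks them by AICc.  When `alt_overrides` is set in
#' the config, the whole procedure is repeated under the alternative
#' painting so the two tables can be compared side by side.
#'
#' @param config A [run_config()].
#' @return A list of class `"fit_all_result"`: `table` ([build_model_table()]
#'   result), `fits`, `paintings` (per hypothesis), and optionally
#'   `alt_table`/`alt_fits` under the alternative overrides.
#' @export
run_fit_all <- function(config) {
  main <- .fit_all_once(config, config$internal_overrides)
  out <- list(table = build_model_table(main$fits), fits = main$fits,
              paintings = main$paintings)
  if (!is.null(config$alt_overrides)) {
    alt <- .fit_all_once(config, config$alt_overrides)
    out$alt_table <- build_model_table(alt$fits)
    out$alt_fits <- alt$fits
  }
  class(out) <- "fit_all_result"
  out
}

#' @export
print.fit_all_result <- function(x, ...) {
  print(x$table)
  if (!is.null(x$alt_table)) {
    cat("\nUnder the alternative internal-node assignment:\n")
    print(x$alt_table)
  }
  invisible(x)
}

# The six standard pairwise comparisons, as (class, hypothesis) pairs.
.pmc_pairs <- function() {
  list(
    bm_vs_meta_other = list(
      simple = c("BM1", "random_evolution"),
      complex = c("OUMV", "metamorphosis_other")),
    meta_other_vs_meta_paed_dd = list(
      simple = c("OUMV", "metamorphosis_other"),
      complex = c("OUMV", "meta_paed_dd")),
    meta_other_vs_abrupt_gradual_other = list(
      simple = c("OUMV", "metamorphosis_other"),
      complex = c("OUMV", "meta_abrupt_meta_gradual_other")),
    meta_paed_dd_vs_four_regime = list(
      simple = c("OUMV", "meta_paed_dd"),
      complex = c("OUMV", "meta_abrupt_meta_gradual_paed_dd")),
    abrupt_gradual_other_vs_four_regime = list(
      simple = c("OUMV", "meta_abrupt_meta_gradual_other"),
      complex = c("OUMV", "meta_abrupt_meta_gradual_paed_dd")),
    single_vs_multi_sigma_four_regime = list(
      simple = c("OUM", "meta_abrupt_meta_gradual_paed_dd"),
      complex = c("OUMV", "meta_abrupt_meta_gradual_paed_dd")))
}

#' Run the six pairwise Monte Carlo comparisons
#'
#' Runs [pmc_compare()] for the standard ladder of comparisons: BM vs
#' metamorphosis-other; metamorphosis-other vs each three-regime refinement;
#' each three-regime hypothesis vs the four-regime model; and, within the
#' four-regime model, single vs multiple noise intensities.  Each comparison
#' gets a sub-seed derived from the master seed.
#'
#' @param config A [run_config()].
#' @param fit_all Optional [run_fit_all()] result (for its paintings).
#' @return Named list of six [pmc_compare()] results.
#' @export
run_pmc_suite <- function(config, fit_all = NULL) {
  if (is.null(fit_all)) fit_all <- run_fit_all(config)
  paintings <- fit_all$paintings
  pairs <- .pmc_pairs()
  out <- vector("list", length(pairs))
  names(out) <- names(pairs)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    h0 <- config$hypotheses[[pr$simple[2L]]]
    h1 <- config$hypotheses[[pr$complex[2L]]]
    out[[i]] <- pmc_compare(
      model_spec(pr$simple[1L], h0$name, h0$r),
      model_spec(pr$complex[1L], h1$name, h1$r),
      config$tree, paintings[[h0$name]], paintings[[h1$name]],
      config$data, n_sims = config$n_sims,
      seed = (config$seed + 1000L * i) %% .Machine$integer.max,
      config = config$fit)
  }
  out
}

#' Write a plain-text report plus machine-readable tables
#'
#' Emits, under `config$out_dir`: `model_table.tsv` (and
#' `model_table_alt.tsv` when an alternative painting was fitted),
#' `bootstrap_ci.tsv`, `pmc_summary.tsv`, `pmc_delta_<comparison>.tsv`
#' (the raw Monte Carlo samples), `stationary.tsv`, and `report.md`, a
#' narrative summary stamped with the package version and master seed.
#' Model support is reported with the conventional `Delta AICc <= 4` rule.
#'
#' @param config A [run_config()].
#' @param fit_all A [run_fit_all()] result.
#' @param ci Optional [bootstrap_ci()] result for the best model.
#' @param pmc Optional [run_pmc_suite()] result.
#' @return The output directory, invisibly.
#' @export
run_report <- function(config, fit_all, ci = NULL, pmc = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <<- c(outs, name)
    p
  }
  wtsv(fit_all$table$table, "model_table.tsv")
  if (!is.null(fit_all$alt_table)) {
    wtsv(fit_all$alt_table$table, "model_table_alt.tsv")
  }
  best <- fit_all$table$best
  if (!is.null(ci)) wtsv(ci$ci, "bootstrap_ci.tsv")
  if (!is.null(pmc)) {
    summ <- do.call(rbind, lapply(names(pmc), function(nm) {
      r <- pmc[[nm]]
      data.frame(comparison = nm, delta_obs = r$delta_obs,
                 p_value = r$p_value, power = r$power,
                 null_q95 = r$null_q95, n_sims = r$n_sims)
    }))
    wtsv(summ, "pmc_summary.tsv")
    for (nm in names(pmc)) {
      r <- pmc[[nm]]
      wtsv(data.frame(arm = c(rep("null", length(r$null_delta)),
                              rep("alt", length(r$alt_delta))),
                      delta = c(r$null_delta, r$alt_delta)),
           sprintf("pmc_delta_%s.tsv", nm))
    }
  }
  if (best$spec$class %in% c("OUM", "OUMV")) {
    wtsv(regime_summary(config$data, config$tree,
                        fit_all$paintings[[best$spec$hypothesis]],
                        best$params),
         "stationary.tsv")
  }

  lines <- c(
    "# Regime-painted trait model analysis",
    "",
    sprintf("- package: ouregimes %s",
            as.character(utils::packageVersion("ouregimes"))),
    sprintf("- master seed: %d", config$seed),
    sprintf("- tips: %d", ape::Ntip(config$tree)),
    sprintf("- bootstrap replicates: %d; Monte Carlo sims per arm: %d",
            config$n_reps, config$n_sims),
    "",
    "## Model table",
    "",
    sprintf("Best model: %s under '%s' (logL = %.3f, k = %d, AICc = %.2f).",
            best$spec$class, best$spec$hypothesis, best$logL, best$k,
            best$AICc),
    sprintf("Support set (Delta AICc <= 4): %s.",
            paste(sprintf("%s/%s", fit_all$table$support$class,
                          fit_all$table$support$hypothesis),
                  collapse = "; ")),
    "",
    "## Output files", "",
    sprintf("- %s", outs))
  writeLines(lines, file.path(config$out_dir, "report.md"))
  invisible(config$out_dir)
}
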