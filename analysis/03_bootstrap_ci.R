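#!/usr/bin/env Rscript
# Stage 3 — parametric-bootstrap confidence intervals for the best-fitting
# model.  199 replicates keep this stage to about two minutes; raise
# n_reps to 500 for a full-scale run.
#
# Inputs:  results/fixture/           (from 01_simulate.R)
# Outputs: results/bootstrap_ci.tsv

library(ouregimes)

tree <- read_newick("results/fixture/tree.nwk")
regs <- read_trait_table("results/fixture/regimes.tsv")
traits <- read_trait_table("results/fixture/traits.tsv")
tip_states <- setNames(regs$life_history, regs$species)
x <- setNames(traits$ln_pg, traits$species)

base <- paint_from_tip_states(tree, tip_states)
h4 <- build_hypotheses()$meta_abrupt_meta_gradual_paed_dd
p4 <- coarsen(base, h4)

fit <- fit_model(model_spec("OUMV", h4$name, 4L), tree, p4, x)
print(fit)

ci <- bootstrap_ci(fit, tree, p4, n_reps = 199L, level = 95, seed = 2L)
print(ci)

write.table(ci$ci, "results/bootstrap_ci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d of %d replicate fits converged", ci$n_ok,
                ci$n_ok + ci$n_fail))
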