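#' Simulate a pure-birth (Yule) tree
#'
#' Draws a birth-only tree conditioned on the number of tips and rescales it
#' to the requested height, so the result is exactly ultrametric with unit
#' height by default.  On a unit-height tree the OU pull `alpha` reads as
#' pull per tree depth (half-life `log(2)/alpha` tree depths).
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; the tree is reproducible given it.
#' @param height Tree height after rescaling (default 1).
#' @return A `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, height = 1) {
  stopifnot(n_tips >= 2L, height > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  H <- max(node_times(tree))
  tree$edge.length <- tree$edge.length * (height / H)
  tree
}

# Tip ids below each internal node (list over all node ids).
.clade_tips <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Paint clade-structured regimes at random
#'
#' Emulates life-history regimes that occupy whole clades: for every label
#' after the first, a clade of at least `min_clade_tips` tips is chosen at
#' random (disjoint from clades already taken, optionally steered toward a
#' per-label target tip count) and all its edges, including the stem edge,
#' receive the label.  All remaining edges and the root carry the first
#' (background) label.
#'
#' @param tree A `"phylo"` object.
#' @param regime_labels Character vector; first entry is the background.
#' @param min_clade_tips Minimum clade size per non-background label.
#' @param seed Optional integer seed.
#' @param target_tips Optional numeric vector of desired tip counts for the
#'   non-background labels; clades with sizes near the target are preferred.
#' @return A [regime_painting()].
#' @export
random_clade_painting <- function(tree, regime_labels, min_clade_tips = 2L,
                                  seed = NULL, target_tips = NULL) {
  stopifnot(length(regime_labels) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  painting_edge <- rep(regime_labels[1L], nrow(tree$edge))
  if (length(regime_labels) == 1L) {
    return(regime_painting(tree, painting_edge, regime_labels[1L]))
  }
  clades <- .clade_tips(tree)
  sizes <- lengths(clades)
  root <- n + 1L
  taken <- rep(FALSE, n)  # tips already claimed by a painted clade

  fg <- regime_labels[-1L]
  if (is.null(target_tips)) target_tips <- rep(NA_real_, length(fg))
  for (j in seq_along(fg)) {
    # leave room for the labels still to be placed plus >=1 background tip
    cap <- n - sum(taken) - (length(fg) - j) * min_clade_tips - 1L
    cand <- which(seq_along(clades) > n &               # internal nodes
                  seq_along(clades) != root &
                  sizes >= min_clade_tips & sizes <= cap &
                  !vapply(clades, function(s) any(taken[s]), TRUE))
    if (length(cand) == 0L) {
      stop(sprintf("cannot place regime '%s': no free clade with >= %d tips; try a smaller min_clade_tips",
                   fg[j], min_clade_tips))
    }
    if (is.na(target_tips[j])) {
      node <- cand[sample.int(length(cand), 1L)]
    } else {
      dist <- abs(sizes[cand] - target_tips[j])
      near <- cand[dist <= min(dist) + 2]
      node <- near[sample.int(length(near), 1L)]
    }
    in_clade <- tree$edge[, 2L] %in% .descendant_nodes(tree, node)
    painting_edge[in_clade] <- fg[j]
    taken[clades[[node]]] <- TRUE
  }
  regime_painting(tree, painting_edge, regime_labels[1L])
}

# All node ids (internal and tips) inside the clade rooted at `node`,
# including `node` itself.
.descendant_nodes <- function(tree, node) {
  out <- node
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  while (length(kids) > 0L) {
    out <- c(out, kids)
    kids <- tree$edge[tree$edge[, 1L] %in% kids, 2L]
  }
  out
}

#' Synthetic study emulating the salamander genome-size dataset
#'
#' Builds a complete testbed with the statistical structure the analysis
#' assumes: a 118-tip unit-height Yule tree; four clade-structured
#' life-history regimes with tip shares of roughly 40% direct development
#' (the background), 30% gradual metamorphosis, 15% abrupt metamorphosis,
#' and 15% paedomorphosis; and ln-pg traits simulated under the four-regime
#' OUMV model at `alpha = 1.3`, `theta = (2.7, 3.7, 3.7, 4.3)` and
#' `sigma = (0.4, 0.6, 0.8, 0.4)` for (abrupt, gradual, dd, paed) — rounded
#' magnitudes typical of fitted salamander genome-size models, documented as
#' approximations.  If a tree draw admits no clade arrangement satisfying
#' the minimum regime sizes, further tree draws are made until one does.
#'
#' @param seed Master integer seed; everything is reproducible given it.
#' @param n_tips Number of tips (default 118).
#' @return An object of class `"synthetic_study"`: `tree`, `painting`
#'   (life-history codes), `data` (named tip trait vector, ln pg), `spec`,
#'   `params` (generating model), `seed`.
#' @export
study_mimic_fixture <- function(seed = 1L, n_tips = 118L) {
  seed <- as.integer(seed)
  labels <- c("dd", "meta_gradual", "meta_abrupt", "paed")
  targets <- round(n_tips * c(0.30, 0.15, 0.15))  # gradual, abrupt, paed
  min_tips <- max(3L, round(0.085 * n_tips))      # 10 at the default size
  painting <- NULL
  for (attempt in 0:49) {
    tree <- simulate_yule_tree(n_tips, seed = (seed + 7919L * attempt) %% .Machine$integer.max)
    painting <- tryCatch(
      random_clade_painting(tree, labels, min_clade_tips = min_tips,
                            target_tips = targets),
      error = function(e) NULL)
    if (!is.null(painting)) {
      counts <- table(tip_regimes(tree, painting))
      if (length(counts) == 4L && all(counts >= 5L)) break
      painting <- NULL
    }
  }
  if (is.null(painting)) stop("could not build a four-regime clade painting")

  spec <- model_spec("OUMV", "meta_abrupt_meta_gradual_paed_dd", 4L)
  params <- model_params(
    spec, alpha = 1.3,
    sigma = c(meta_abrupt = 0.4, meta_gradual = 0.6, dd = 0.8, paed = 0.4),
    theta = c(meta_abrupt = 2.7, meta_gradual = 3.7, dd = 3.7, paed = 4.3))
  data <- simulate_tips(params, tree, painting, seed = seed)
  structure(list(tree = tree, painting = painting, data = data,
                 spec = spec, params = params, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d tips, seed %d\n", ape::Ntip(x$tree), x$seed))
  print(table(tip_regimes(x$tree, x$painting)))
  invisible(x)
}

#' Write a synthetic study as a plain-text fixture directory
#'
#' Writes `tree.nwk` (Newick), `traits.tsv` (species, genome size in pg and
#' ln pg), `regimes.tsv` (tip life-history codes), and `truth.yaml`
#' (generating model, parameters, seed).
#'
#' @param study A [study_mimic_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  traits <- data.frame(species = names(study$data),
                       genome_size_pg = exp(unname(study$data)),
                       ln_pg = unname(study$data))
  utils::write.table(traits, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  regs <- tip_regimes(study$tree, study$painting)
  utils::write.table(
    data.frame(species = names(regs), life_history = unname(regs)),
    file.path(dir, "regimes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- list(
    model = study$spec$class, hypothesis = study$spec$hypothesis,
    seed = study$seed, alpha = study$params$alpha,
    sigma = as.list(study$params$sigma), theta = as.list(study$params$theta))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
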