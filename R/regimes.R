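#' The four salamander life-history codes
#'
#' Abrupt metamorphosis (`meta_abrupt`), gradual metamorphosis
#' (`meta_gradual`), direct development (`dd`), and paedomorphosis (`paed`).
#' Facultative paedomorphs and other borderline taxa are encoded by the
#' caller in the input table (conventionally as metamorphic); no special
#' casing happens here.
#'
#' @return Character vector of the four codes, in canonical order.
#' @export
life_history_codes <- function() {
  c("meta_abrupt", "meta_gradual", "dd", "paed")
}

#' Construct a regime hypothesis
#'
#' @param name Hypothesis name.
#' @param mapping Named character vector mapping every life-history code to a
#'   regime label.
#' @return An object of class `"regime_hypothesis"`.
#' @export
regime_hypothesis <- function(name, mapping) {
  codes <- life_history_codes()
  if (!setequal(names(mapping), codes)) {
    stop("mapping must cover exactly the four life-history codes")
  }
  mapping <- mapping[codes]
  structure(
    list(name = name, mapping = mapping,
         r = length(unique(unname(mapping)))),
    class = "regime_hypothesis")
}

#' @export
print.regime_hypothesis <- function(x, ...) {
  cat(sprintf("Regime hypothesis '%s' (r = %d):\n", x$name, x$r))
  for (code in names(x$mapping)) {
    cat(sprintf("  %-13s -> %s\n", code, x$mapping[[code]]))
  }
  invisible(x)
}

#' The five life-history regime hypotheses
#'
#' Builds the five groupings of the four life-history codes under which trait
#' models are fitted:
#' * `random_evolution` — a single regime (pure drift; fitted as BM only);
#' * `metamorphosis_other` — metamorphosers vs everything else;
#' * `meta_paed_dd` — metamorphosers, direct developers, paedomorphs;
#' * `meta_abrupt_meta_gradual_other` — abrupt vs gradual metamorphosis,
#'   non-metamorphosers pooled as "other";
#' * `meta_abrupt_meta_gradual_paed_dd` — all four codes distinct.
#'
#' @return Named list of five [regime_hypothesis()] objects.
#' @export
build_hypotheses <- function() {
  h <- list(
    regime_hypothesis("random_evolution", c(
      meta_abrupt = "all", meta_gradual = "all", dd = "all", paed = "all")),
    regime_hypothesis("metamorphosis_other", c(
      meta_abrupt = "meta", meta_gradual = "meta", dd = "other", paed = "other")),
    regime_hypothesis("meta_paed_dd", c(
      meta_abrupt = "meta", meta_gradual = "meta", dd = "dd", paed = "paed")),
    regime_hypothesis("meta_abrupt_meta_gradual_other", c(
      meta_abrupt = "meta_abrupt", meta_gradual = "meta_gradual",
      dd = "other", paed = "other")),
    regime_hypothesis("meta_abrupt_meta_gradual_paed_dd", c(
      meta_abrupt = "meta_abrupt", meta_gradual = "meta_gradual",
      dd = "dd", paed = "paed")))
  stats::setNames(h, vapply(h, `[[`, "", "name"))
}

#' Construct a regime painting
#'
#' A painting assigns one regime label to every edge of the tree (edges are
#' indexed by row of `tree$edge`) plus a label for the root.  Every label
#' must be used on at least one edge, otherwise that regime's parameters
#' would be unidentifiable and the painting is rejected.
#'
#' @param tree A `"phylo"` object.
#' @param edge_regime Character vector, one label per edge of `tree`.
#' @param root_regime Label at the root.
#' @return An object of class `"regime_painting"` with fields `edge`, `root`,
#'   and `labels` (unique labels, first-appearance order).
#' @export
regime_painting <- function(tree, edge_regime, root_regime) {
  validate_phylogeny(tree)
  ne <- nrow(tree$edge)
  if (length(edge_regime) != ne) {
    stop(sprintf("painting covers %d edges but tree has %d",
                 length(edge_regime), ne))
  }
  if (anyNA(edge_regime)) stop("every edge must be painted")
  labels <- unique(c(as.character(edge_regime), as.character(root_regime)))
  unused <- setdiff(labels, unique(as.character(edge_regime)))
  if (length(unused) > 0L) {
    stop(sprintf("regime label(s) used on no edge: %s",
                 paste(unused, collapse = ", ")))
  }
  structure(
    list(edge = as.character(edge_regime), root = as.character(root_regime),
         labels = unique(as.character(edge_regime)), tree = tree),
    class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat(sprintf("Regime painting: %d edges, root '%s', labels: %s\n",
              length(x$edge), x$root, paste(x$labels, collapse = ", ")))
  print(table(x$edge))
  invisible(x)
}

#' Paint regimes onto edges from tip states
#'
#' Internal-node states are reconstructed by a Fitch-style parsimony pass
#' (bottom-up state sets, then a top-down resolution that breaks ties toward
#' the parent's state), after which explicit `internal_overrides` replace the
#' reconstructed state at named nodes — the mechanism used to probe
#' alternative assignments of contested ancestral nodes.  Each edge then
#' takes the regime of its tipward (child) node, so regime shifts occur
#' exactly at nodes.
#'
#' @param tree A `"phylo"` object.
#' @param tip_states Named character vector, one life-history code (or any
#'   label) per tip label of `tree`.
#' @param internal_overrides Optional named vector: names are internal node
#'   ids (as integers, `Ntip+1 .. Ntip+Nnode`), values are states.
#' @return A [regime_painting()].
#' @export
paint_from_tip_states <- function(tree, tip_states, internal_overrides = NULL) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  names(tip_states) <- normalize_species(names(tip_states))
  tips <- normalize_species(tree$tip.label)
  missing_tips <- setdiff(tips, names(tip_states))
  if (length(missing_tips) > 0L) {
    stop(sprintf("tip(s) without a state: %s",
                 paste(missing_tips, collapse = ", ")))
  }
  states_order <- unique(unname(tip_states))

  # bottom-up Fitch pass over state sets
  sets <- vector("list", n + m)
  for (i in seq_len(n)) sets[[i]] <- unname(tip_states[tips[i]])
  post <- ape::reorder.phylo(tree, "postorder")
  children <- split(post$edge[, 2L], post$edge[, 1L])
  internal_post <- unique(post$edge[, 1L])  # postorder: children before parents
  for (p in internal_post) {
    kid_sets <- lapply(children[[as.character(p)]], function(k) sets[[k]])
    inter <- Reduce(intersect, kid_sets)
    sets[[p]] <- if (length(inter) > 0L) inter else unique(unlist(kid_sets))
  }

  # top-down resolution, ties toward the parent's state
  state <- character(n + m)
  for (i in seq_len(n)) state[i] <- sets[[i]]
  root <- n + 1L
  rs <- sets[[root]]
  state[root] <- states_order[match(TRUE, states_order %in% rs)]
  clade <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(clade$edge))) {
    p <- clade$edge[e, 1L]; ch <- clade$edge[e, 2L]
    if (ch <= n) next
    s <- sets[[ch]]
    state[ch] <- if (state[p] %in% s) state[p] else
      states_order[match(TRUE, states_order %in% s)]
  }

  if (!is.null(internal_overrides)) {
    ids <- as.integer(names(internal_overrides))
    if (anyNA(ids) || any(ids <= n) || any(ids > n + m)) {
      stop("internal_overrides must name internal node ids (Ntip+1..Ntip+Nnode)")
    }
    state[ids] <- unname(internal_overrides)
  }

  regime_painting(tree, edge_regime = state[tree$edge[, 2L]],
                  root_regime = state[root])
}

#' Relabel a painting under a regime hypothesis
#'
#' Maps every edge (and root) label of a painting through a hypothesis'
#' life-history-code mapping, pooling regimes as the hypothesis dictates.
#'
#' @param painting A [regime_painting()] whose labels are life-history codes.
#' @param hypothesis A [regime_hypothesis()].
#' @return A coarsened [regime_painting()].
#' @export
coarsen <- function(painting, hypothesis) {
  stopifnot(inherits(painting, "regime_painting"),
            inherits(hypothesis, "regime_hypothesis"))
  map <- hypothesis$mapping
  bad <- setdiff(c(painting$edge, painting$root), names(map))
  if (length(bad) > 0L) {
    stop(sprintf("painting label(s) outside the hypothesis mapping: %s",
                 paste(unique(bad), collapse = ", ")))
  }
  regime_painting(painting$tree, edge_regime = unname(map[painting$edge]),
                  root_regime = unname(map[painting$root]))
}

#' Decompose root-to-tip paths into timed regime segments
#'
#' For every tip, the path from the root (time 0) to the tip (time `T_i`) is
#' cut into contiguous segments `[a, b]` each carrying one regime; for every
#' pair of tips the shared time `t_s` equals the depth of their most recent
#' common ancestor.  The decomposition caches everything the likelihood
#' formulas integrate over: per-edge start/end times and regimes, the
#' edge-by-tip descent incidence matrix, tip depths, and the shared-time
#' matrix.
#'
#' @param tree A `"phylo"` object.
#' @param painting A [regime_painting()] on `tree`.
#' @return An object of class `"path_decomposition"`.
#' @export
decompose_paths <- function(tree, painting) {
  validate_phylogeny(tree)
  stopifnot(inherits(painting, "regime_painting"))
  n <- ape::Ntip(tree)
  nt <- node_times(tree)
  ne <- nrow(tree$edge)
  edge_a <- nt[tree$edge[, 1L]]
  edge_b <- nt[tree$edge[, 2L]]
  labels <- painting$labels
  edge_regime <- match(painting$edge, labels)

  # D[e, i] = 1 iff tip i lies below edge e (edge e is on tip i's path)
  desc <- matrix(FALSE, n + tree$Nnode, n)
  desc[cbind(seq_len(n), seq_len(n))] <- TRUE
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(ne)) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  D <- matrix(0, ne, n)
  for (e in seq_len(ne)) D[e, ] <- as.numeric(desc[tree$edge[e, 2L], ])

  tipT <- nt[seq_len(n)]
  mrca <- ape::mrca(tree)
  ts <- matrix(nt[mrca], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(ts) <- tipT

  segments <- vector("list", n)
  for (i in seq_len(n)) {
    on_path <- which(D[, i] == 1)
    on_path <- on_path[order(edge_a[on_path])]
    segments[[i]] <- data.frame(
      a = edge_a[on_path], b = edge_b[on_path],
      regime = labels[edge_regime[on_path]],
      stringsAsFactors = FALSE)
  }
  names(segments) <- tree$tip.label

  structure(
    list(tree = tree, painting = painting, n = n, tips = tree$tip.label,
         labels = labels, root_regime = painting$root,
         edge_a = edge_a, edge_b = edge_b, edge_len = edge_b - edge_a,
         edge_regime = edge_regime, D = D, tipT = tipT, ts = ts,
         segments = segments),
    class = "path_decomposition")
}

#' Tip regimes under a painting
#'
#' The regime of a tip is the regime of its terminal edge.
#'
#' @param tree A `"phylo"` object.
#' @param painting A [regime_painting()].
#' @return Named character vector over tips.
#' @export
tip_regimes <- function(tree, painting) {
  n <- ape::Ntip(tree)
  term <- match(seq_len(n), tree$edge[, 2L])
  stats::setNames(painting$edge[term], tree$tip.label)
}

#' Write a regime assignment as TSV
#' @param painting A [regime_painting()].
#' @param tree The tree it paints.
#' @param path Output file.
#' @export
write_regimes <- function(painting, tree, path) {
  df <- data.frame(edge = seq_along(painting$edge),
                   child = tree$edge[, 2L],
                   label = ifelse(tree$edge[, 2L] <= ape::Ntip(tree),
                                  tree$tip.label[pmin(tree$edge[, 2L], ape::Ntip(tree))],
                                  ""),
                   regime = painting$edge)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
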