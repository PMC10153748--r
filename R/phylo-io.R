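#' Read a Newick tree
#'
#' Parses a Newick string (or a file containing one) into an [ape::read.tree]
#' `"phylo"` object and validates it for use in regime-painted trait models:
#' every edge must carry a positive branch length and tip labels must be
#' unique.
#'
#' @param text A Newick string, or the path of a file holding one tree.
#' @return An object of class `"phylo"`, rooted, with branch lengths.
#' @seealso [write_newick()], [check_ultrametric()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    suppressWarnings(
      if (file.exists(text) && !grepl(";", text, fixed = TRUE)) {
        ape::read.tree(file = text)
      } else {
        ape::read.tree(text = text)
      }),
    error = function(e) NULL)
  if (is.null(tree)) {
    stop("malformed Newick string: could not be parsed")
  }
  validate_phylogeny(tree)
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 15, enough
#'   for round-tripping to ~1e-15 relative error).
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# Structural invariants shared by every operation that consumes a tree.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; lengths are required")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length <= 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length <= 0)[1L]
    stop(sprintf("non-positive or missing branch length on edge %d", bad))
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate tip label(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Times of all nodes measured from the root
#'
#' Time runs from 0 at the root to the tree height `T` at the tips of an
#' ultrametric tree.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric vector over node ids `1..(Nnode + Ntip)`.
#' @keywords internal
node_times <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Check ultrametricity
#'
#' A rooted tree is ultrametric when every tip sits at the same distance from
#' the root.  Trees assembled from posterior samples are ultrametric only up
#' to numerical noise, so the check is relative: it passes when the largest
#' tip-depth deviation from the tree height does not exceed `tol * T`.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param tol Relative tolerance on tip depths (default `1e-6`).
#' @return A list with elements `ultrametric` (logical) and `deviation`
#'   (largest absolute tip-depth deviation from the maximum depth).
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  validate_phylogeny(tree)
  depths <- node_times(tree)[seq_len(ape::Ntip(tree))]
  H <- max(depths)
  dev <- max(abs(depths - H))
  list(ultrametric = dev <= tol * H, deviation = dev, height = H)
}

# Canonical key for the split below an edge: sorted tip labels of the clade.
.split_keys <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(tree$edge[, 2L], function(nd) paste(sort(desc[[nd]]), collapse = "|"), "")
}

#' Mean-edge consensus of same-topology trees
#'
#' Given a set of trees that share one topology (same tip set, same splits),
#' returns that topology with every edge length replaced by the arithmetic
#' mean of the corresponding edge lengths across the set.  This is how a
#' single analysis tree is distilled from a sample of dated trees.
#'
#' @param trees A list of `"phylo"` objects (or an `ape` `"multiPhylo"`).
#' @return A `"phylo"` object.
#' @export
mean_edge_consensus <- function(trees) {
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  stopifnot(is.list(trees), length(trees) >= 1L)
  lapply(trees, validate_phylogeny)
  ref <- trees[[1L]]
  ref_keys <- .split_keys(ref)
  tips <- sort(ref$tip.label)
  acc <- ref$edge.length
  for (k in seq_along(trees)[-1L]) {
    tr <- trees[[k]]
    if (!identical(sort(tr$tip.label), tips)) {
      stop("trees do not share one tip set")
    }
    keys <- .split_keys(tr)
    idx <- match(ref_keys, keys)
    if (anyNA(idx)) {
      miss <- ref_keys[which(is.na(idx))[1L]]
      stop(sprintf("topology mismatch: split {%s} absent from tree %d",
                   gsub("|", ", ", miss, fixed = TRUE), k))
    }
    acc <- acc + tr$edge.length[idx]
  }
  out <- ref
  out$edge.length <- acc / length(trees)
  out
}

# "Genus species" and "Genus_species" refer to the same taxon.
normalize_species <- function(x) {
  gsub("\\s+", "_", trimws(as.character(x)))
}

#' Prepare trait values for model fitting
#'
#' Applies the study's data-preparation rules to a per-record genome size
#' table: drop records from excluded studies, average the remaining
#' picogram estimates per species with equal weight, exclude miniaturized
#' species (mean snout--vent length below `svl_min`), restrict to the tips of
#' the analysis tree, and natural-log transform.  Every excluded species is
#' logged with the rule that removed it.
#'
#' @param records A data frame with columns `species` and `genome_size_pg`,
#'   and optionally `svl_mm` and `study_id`.  Columns are matched by name.
#' @param tree The analysis phylogeny; only its tips are retained.
#' @param drop_study_ids Character vector of study ids whose records are
#'   discarded before averaging.
#' @param svl_min Minimum mean snout--vent length in mm (default 35); species
#'   below it are excluded as miniaturized.
#' @return A list with `x` (named numeric vector of ln-pg trait values, one
#'   per retained species) and `exclusions` (data frame `species`, `rule`).
#' @export
prepare_traits <- function(records, tree, drop_study_ids = character(),
                           svl_min = 35) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  need <- c("species", "genome_size_pg")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop(sprintf("trait table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(records$genome_size_pg <= 0, na.rm = TRUE)) {
    stop("genome sizes must be positive")
  }
  records$species <- normalize_species(records$species)
  tips <- normalize_species(tree$tip.label)

  excl <- data.frame(species = character(), rule = character(),
                     stringsAsFactors = FALSE)
  if (length(drop_study_ids) > 0L && "study_id" %in% names(records)) {
    records <- records[!(records$study_id %in% drop_study_ids), , drop = FALSE]
  }

  species <- intersect(unique(records$species), tips)
  x <- c(); keep <- character()
  for (sp in species) {
    rec <- records[records$species == sp, , drop = FALSE]
    if (nrow(rec) == 0L || all(is.na(rec$genome_size_pg))) {
      excl <- rbind(excl, data.frame(species = sp, rule = "no surviving record"))
      next
    }
    if ("svl_mm" %in% names(rec) && any(!is.na(rec$svl_mm))) {
      if (mean(rec$svl_mm, na.rm = TRUE) < svl_min) {
        excl <- rbind(excl, data.frame(
          species = sp, rule = sprintf("SVL<%g mm", svl_min)))
        next
      }
    }
    x <- c(x, log(mean(rec$genome_size_pg, na.rm = TRUE)))
    keep <- c(keep, sp)
  }
  names(x) <- keep

  no_record <- setdiff(tips, unique(records$species))
  if (length(no_record) > 0L) {
    stop(sprintf("tree tip(s) with no surviving trait record: %s",
                 paste(no_record, collapse = ", ")))
  }
  list(x = x, exclusions = excl)
}

#' Convert genome size from picograms to megabases
#'
#' Uses the standard conversion 1 pg = 978 Mb.
#'
#' @param pg Genome size(s) in picograms (haploid C-value), non-negative.
#' @return Genome size(s) in Mb.
#' @export
pg_to_mb <- function(pg) {
  if (any(pg < 0, na.rm = TRUE)) stop("genome size cannot be negative")
  978 * pg
}

#' Read a delimited trait table
#'
#' @param path TSV/CSV file with a header; columns matched by name.
#' @param sep Field separator; default tab.
#' @return A data frame.
#' @export
read_trait_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = TRUE)
}
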