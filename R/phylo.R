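# Distance-based phylogenetic grouping: Poisson-corrected protein
# distances, neighbor-joining trees, column-resampling bootstrap, unrooted
# monophyly tests, and reference-guided clustering of RT-free aRNH copies.

#' Poisson-corrected distance between two aligned proteins
#'
#' `d = -ln(1 - p)` with `p` the mismatch proportion over columns where
#' neither sequence is gapped.  `p >= 1 - exp(-d_max)` is capped at
#' `d_max`.
#'
#' @param a,b equal-length gapped protein strings.
#' @param d_max distance cap (default 10).
#' @param on_empty what to do when no column is comparable: `"error"`
#'   (default), or `"cap"` to return `d_max` (used by the tree builders,
#'   where partially aligned domain fragments may not overlap).
#' @return Non-negative distance.
#' @export
protein_distance <- function(a, b, d_max = 10,
                             on_empty = c("error", "cap")) {
  on_empty <- match.arg(on_empty)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- x != "-" & y != "-"
  if (!any(ok)) {
    if (on_empty == "cap") return(d_max)
    stop("zero comparable columns")
  }
  p <- mean(x[ok] != y[ok])
  if (p >= 1 - exp(-d_max)) return(d_max)
  -log(1 - p)
}

#' Pairwise Poisson-corrected distance matrix
#'
#' @param alignment character matrix (rows = named sequences) or named
#'   character vector of equal-length gapped strings.
#' @param d_max distance cap.
#' @param on_empty forwarded to [protein_distance()].
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment, d_max = 10,
                            on_empty = c("error", "cap")) {
  on_empty <- match.arg(on_empty)
  rows <- alignment_rows(alignment)
  n <- length(rows)
  m <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- protein_distance(rows[[i]], rows[[j]], d_max = d_max,
                            on_empty = on_empty)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

alignment_rows <- function(alignment) {
  if (is.matrix(alignment)) {
    rows <- apply(alignment, 1L, paste, collapse = "")
    names(rows) <- rownames(alignment)
  } else {
    rows <- alignment
  }
  if (is.null(names(rows)) || anyNA(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named")
  as.list(rows)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape), applied after sorting taxa
#' lexicographically so the result is invariant to the input label order.
#' Negative branch-length estimates are clamped to zero.
#'
#' @param m symmetric labelled distance matrix (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  ord <- order(rownames(m))
  tree <- ape::nj(as.dist(m[ord, ord]))
  if (any(tree$edge.length < 0))
    tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# Unrooted bipartitions of a phylo tree as canonical strings.  Each
# internal edge splits the leaves in two; the side not containing the
# lexicographically smallest label represents the split.
tree_bipartitions <- function(tree, trivial = FALSE) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    tips <- attr(parts, "labels")[p]
    size <- length(tips)
    if (!trivial && (size <= 1L || size >= length(labs) - 1L)) next
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Column-resampling bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and reports for each internal edge of the
#' original tree the percentage of replicates containing the same
#' unrooted bipartition, as node labels.
#'
#' @param alignment character matrix or named vector as in
#'   [distance_matrix()] (>= 3 rows).
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed; same seed, same supports.
#' @param d_max distance cap.
#' @return List with `tree` (node-labelled `phylo`; `""` where support is
#'   not defined), `splits` (canonical bipartition strings) and `support`
#'   (named percentage vector, one per non-trivial split; `NA` when
#'   `n_reps` is 0).
#' @export
bootstrap_support <- function(alignment, n_reps = 100L, seed = 1L,
                              d_max = 10) {
  rows <- alignment_rows(alignment)
  chars <- do.call(rbind, lapply(rows, function(s)
    strsplit(s, "", fixed = TRUE)[[1]]))
  rownames(chars) <- names(rows)
  tree <- nj_tree(distance_matrix(alignment, d_max = d_max,
                                  on_empty = "cap"))
  splits <- tree_bipartitions(tree)
  if (n_reps == 0L) {
    support <- setNames(rep(NA_real_, length(splits)), splits)
  } else {
    counts <- setNames(rep(0L, length(splits)), splits)
    with_seed(seed, {
      for (b in seq_len(n_reps)) {
        idx <- sample(ncol(chars), ncol(chars), replace = TRUE)
        rep_rows <- apply(chars[, idx, drop = FALSE], 1L, paste,
                          collapse = "")
        rep_tree <- nj_tree(distance_matrix(rep_rows, d_max = d_max,
                                            on_empty = "cap"))
        rep_splits <- tree_bipartitions(rep_tree)
        hit <- splits %in% rep_splits
        counts[hit] <- counts[hit] + 1L
      }
    })
    support <- 100 * counts / n_reps
  }
  tree$node.label <- node_support_labels(tree, support)
  list(tree = tree, splits = splits, support = support)
}

# Map split supports onto internal-node labels of the tree.
node_support_labels <- function(tree, support) {
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  parts <- ape::prop.part(tree)
  n_node <- tree$Nnode
  out <- rep("", n_node)
  for (i in seq_along(parts)) {
    tips <- attr(parts, "labels")[parts[[i]]]
    if (length(tips) <= 1L || length(tips) >= length(labs) - 1L) next
    side <- if (anchor %in% tips) setdiff(labs, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support) && !is.na(support[key]))
      out[i] <- format(support[key], digits = 3)
  }
  out
}

#' Test a taxon subset for monophyly on an unrooted tree
#'
#' TRUE iff some edge bipartition separates exactly the subset from the
#' remaining leaves (singletons and the full leaf set are trivially
#' monophyletic).
#'
#' @param tree an `ape::phylo`.
#' @param taxa non-empty character vector of leaf labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("empty taxon subset")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L) stop("unknown leaf label: ", unknown[[1]])
  taxa <- unique(taxa)
  n <- length(tree$tip.label)
  if (length(taxa) %in% c(1L, n)) return(TRUE)
  labs <- sort(tree$tip.label)
  anchor <- labs[1]
  key <- if (anchor %in% taxa)
    paste(sort(setdiff(labs, taxa)), collapse = "|")
  else paste(sort(taxa), collapse = "|")
  key %in% tree_bipartitions(tree, trivial = TRUE)
}

#' Cluster RT-free individual aRNH copies against retrotransposon
#' references
#'
#' Aligns the individual aRNH proteins together with the per-group
#' reference aRNH domains ([arnh_references()]) to the aRNH profile,
#' builds a bootstrapped NJ tree, and labels each individual by the group
#' of the smallest supported clade (bootstrap >= `support_threshold`) that
#' contains it together with references of exactly one group.  An
#' individual with no such clade founds a `novel` clade - the analogue of
#' an aRNH lineage with no significant clustering to any RT-associated
#' aRNH.
#'
#' @param proteins named character vector of individual aRNH protein
#'   sequences (>= 1).
#' @param profile the aRNH profile used for the implicit alignment.
#' @param references named character vector of reference aRNH proteins;
#'   names must be `<group>_refN`.
#' @param support_threshold bootstrap percentage required for a clade
#'   link (default 60, the conventional highlight cutoff).
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return List with `labels` (named group/`novel` labels for the
#'   individuals), `tree`, and `support`.
#' @export
cluster_individual_arnh <- function(proteins, profile,
                                    references = arnh_references(),
                                    support_threshold = 60,
                                    n_reps = 100L, seed = 1L) {
  if (length(proteins) < 1L) stop("need at least one sequence")
  if (is.null(names(proteins))) stop("proteins must be named")
  ref_group <- sub("_ref[0-9]+$", "", names(references))
  all_seq <- c(proteins, references)
  aln <- align_to_profile(profile, all_seq)
  if (length(all_seq) < 3L || length(proteins) == 0L) {
    # nearest-reference fallback (too few taxa for a tree)
    dm <- distance_matrix(aln, on_empty = "cap")
    labels <- vapply(names(proteins), function(p) {
      ref_group[which.min(dm[p, names(references)])]
    }, character(1))
    return(list(labels = labels, tree = NULL, support = NULL))
  }
  bs <- bootstrap_support(aln, n_reps = n_reps, seed = seed)
  labs <- sort(bs$tree$tip.label)
  anchor <- labs[1]
  supported <- names(bs$support)[!is.na(bs$support) &
                                   bs$support >= support_threshold]
  sides <- list()
  for (key in supported) {
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    sides <- c(sides, list(side), list(setdiff(labs, side)))
  }
  labels <- setNames(rep("novel", length(proteins)), names(proteins))
  for (p in names(proteins)) {
    best <- NULL
    for (side in sides) {
      if (!(p %in% side)) next
      refs_in <- intersect(side, names(references))
      if (length(refs_in) == 0L) next
      groups_in <- unique(ref_group[match(refs_in, names(references))])
      if (length(groups_in) != 1L) next
      if (is.null(best) || length(side) < length(best$side))
        best <- list(side = side, group = groups_in)
    }
    if (!is.null(best)) labels[p] <- best$group
  }
  list(labels = labels, tree = bs$tree, support = bs$support)
}

#' Write trees as Newick
#'
#' @param trees a `phylo` or named list of `phylo` objects.
#' @param path output file.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  txt <- vapply(trees, function(t)
    ape::write.tree(t, file = ""), character(1))
  writeLines(txt, path)
  invisible(path)
}
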