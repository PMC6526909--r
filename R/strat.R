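#' Oldest first-appearance within a clade
#'
#' @param tree rooted `phylo`.
#' @param node node id (tip or internal).
#' @param ages an [age_table] covering all descendant tips.
#' @return first-appearance date (Ma) of the clade: max of descendant FADs.
#' @export
clade_fad <- function(tree, node, ages) {
  av <- ages_for_tips(tree, ages)
  dt <- descendant_tips(tree)
  max(av$fad[dt[[node]]])
}

#' Stratigraphic consistency of one node
#'
#' A non-root internal node is stratigraphically consistent when the
#' clade it subtends first appears no earlier than its sister lineage:
#' `clade_fad(node) <= clade_fad(sister)`. With `strict = TRUE` equality
#' counts as inconsistent. At a polytomy the oldest sister lineage is
#' used for the comparison.
#'
#' @inheritParams clade_fad
#' @param strict logical; use `<` instead of `<=`.
#' @return logical.
#' @export
node_is_consistent <- function(tree, node, ages, strict = FALSE) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (node == root) stop_labeled("the root has no sister; cannot be assessed")
  if (node <= ntip) stop_labeled("consistency is defined for internal nodes")
  consistency_flags(tree, ages, strict)[[as.character(node)]]
}

## consistency of all non-root internal nodes (named logical vector)
consistency_flags <- function(tree, ages, strict = FALSE) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  av <- ages_for_tips(tree, ages)
  dt <- descendant_tips(tree)
  cf <- vapply(dt, function(tips) max(av$fad[tips]), numeric(1))
  nodes <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  out <- logical(length(nodes))
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    sisters <- setdiff(tree$edge[tree$edge[, 1] == parent[v], 2], v)
    sf <- max(cf[sisters])
    out[i] <- if (strict) cf[v] < sf else cf[v] <= sf
  }
  names(out) <- nodes
  out
}

#' Stratigraphic Consistency Index
#'
#' SCI = (number of stratigraphically consistent nodes) / (total number
#' of nodes), where the denominator counts the non-root internal nodes:
#' for a fully resolved rooted tree of T tips this equals T - 2. For a
#' partition, the index is computed on the subtree rooted at the MRCA of
#' the named tips, sisters taken within that subtree.
#'
#' @param tree rooted `phylo`.
#' @param ages an [age_table].
#' @param clade optional character vector of tip labels delimiting a
#'   partition (its MRCA subtree is evaluated).
#' @param strict logical; strict (`<`) consistency criterion.
#' @return object of class `sci_report`: `consistent`, `total`, `sci`,
#'   and the per-node flags.
#' @export
sci <- function(tree, ages, clade = NULL, strict = FALSE) {
  phy <- tree
  if (!is.null(clade)) {
    miss <- setdiff(clade, tree$tip.label)
    if (length(miss)) stop_labeled("clade tips not in tree: ",
                                   paste(miss, collapse = ", "))
    mrca <- ape::getMRCA(tree, clade)
    phy <- ape::extract.clade(tree, mrca)
  }
  if (length(phy$tip.label) < 3)
    stop_labeled("SCI needs at least 3 tips in the evaluated partition")
  flags <- consistency_flags(phy, ages, strict)
  total <- length(flags)
  if (ape::is.binary(phy) && total != length(phy$tip.label) - 2L)
    warning("unexpected node count on a resolved tree")
  if (!ape::is.binary(phy))
    warning("tree not fully resolved: denominator counts actual ",
            "non-root internal nodes, not tips - 2")
  structure(list(consistent = sum(flags), total = total,
                 sci = sum(flags) / total, flags = flags,
                 strict = strict),
            class = "sci_report")
}

#' @export
print.sci_report <- function(x, ...) {
  cat(sprintf("Stratigraphic Consistency Index: %d/%d = %.2f\n",
              x$consistent, x$total, x$sci))
  if (x$strict) cat("  (strict criterion: ties count as inconsistent)\n")
  invisible(x)
}

#' Minimum-age time-scaling of a cladogram
#'
#' Assigns each internal node the age of its oldest descendant
#' first-appearance, bottom-up, so every branch has non-negative duration;
#' `min_branch` > 0 pushes parents older to enforce a minimum branch
#' duration. Ghost durations are the gaps between a lineage's inferred
#' origin (its parent's age) and its first record (tip FAD, or the child
#' node's age for internal branches).
#'
#' @param tree rooted `phylo` (every tip must be in `ages`).
#' @param ages an [age_table].
#' @param min_branch minimum branch duration in Myr (default 0).
#' @return object of class `timescaled_tree`: the tree with branch
#'   lengths in Myr, `node_age` (Ma, tips carry their FAD), per-tip
#'   `fad`/`lad`, per-edge `ghost` durations and `root_age`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' ag <- age_table(data.frame(taxon = c("A", "B", "C"),
#'                            fad = c(10, 8, 5), lad = c(9, 8, 0)))
#' ts <- timescale(tr, ag)
#' ts$node_age   # node (A,B) and root both at 10 Ma
#' @export
timescale <- function(tree, ages, min_branch = 0) {
  stopifnot(min_branch >= 0)
  av <- ages_for_tips(tree, ages)
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  age <- numeric(n)
  age[seq_len(ntip)] <- av$fad
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    age[p] <- max(age[p], age[ch] + min_branch)
  }
  ghost <- numeric(nrow(tree$edge))
  elen <- numeric(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    elen[k] <- age[p] - age[ch]
    ghost[k] <- age[p] - if (ch <= ntip) av$fad[ch] else age[ch]
  }
  phy <- tree
  phy$edge.length <- elen
  structure(list(tree = phy, node_age = age, fad = av$fad, lad = av$lad,
                 ghost = ghost, root_age = age[ntip + 1L]),
            class = "timescaled_tree")
}

#' Construct a time-scaled tree from known ages
#'
#' Low-level constructor used by the simulators and tests when true node
#' ages are known directly.
#'
#' @param tree rooted `phylo`.
#' @param node_age ages (Ma) for all nodes, tips first.
#' @param fad,lad per-tip observed range (default: tip ages for both).
#' @return a `timescaled_tree`.
#' @export
timescaled_tree <- function(tree, node_age, fad = NULL, lad = NULL) {
  ntip <- length(tree$tip.label)
  stopifnot(length(node_age) == ntip + tree$Nnode)
  fad <- fad %||% node_age[seq_len(ntip)]
  lad <- lad %||% node_age[seq_len(ntip)]
  ghost <- numeric(nrow(tree$edge))
  elen <- numeric(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (node_age[p] < node_age[ch] - 1e-9)
      stop_labeled("parent younger than child in supplied node ages")
    elen[k] <- node_age[p] - node_age[ch]
    ghost[k] <- node_age[p] - if (ch <= ntip) fad[ch] else node_age[ch]
  }
  phy <- tree
  phy$edge.length <- elen
  structure(list(tree = phy, node_age = node_age, fad = fad, lad = lad,
                 ghost = ghost, root_age = max(node_age)),
            class = "timescaled_tree")
}

#' @export
print.timescaled_tree <- function(x, ...) {
  cat("Time-scaled tree:", length(x$tree$tip.label), "tips, root at",
      sprintf("%.2f Ma", x$root_age), "\n")
  cat(sprintf("  total ghost-lineage duration: %.2f Myr\n", sum(x$ghost)))
  invisible(x)
}

#' Range chart of a time-scaled tree
#'
#' Plots observed stratigraphic ranges as bold segments and inferred
#' (ghost) lineage durations as thin lines, tips ordered as in the tree.
#'
#' @param x a `timescaled_tree`.
#' @param ... ignored.
#' @export
plot.timescaled_tree <- function(x, ...) {
  phy <- x$tree
  ntip <- length(phy$tip.label)
  ord <- phy$edge[phy$edge[, 2] <= ntip, 2]
  y <- setNames(seq_len(ntip), ord)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  plot.new()
  plot.window(xlim = c(x$root_age, 0), ylim = c(0, ntip + 1))
  axis(1)
  title(xlab = "age (Ma)")
  for (i in seq_len(ntip)) {
    yy <- y[[as.character(i)]]
    origin <- x$node_age[parent[i]]
    segments(origin, yy, x$fad[i], yy, lwd = 0.6, col = grey(0.4))
    segments(x$fad[i], yy, x$lad[i], yy, lwd = 3)
  }
  invisible(x)
}

#' Per-node time-scaling table
#'
#' @param x a `timescaled_tree`.
#' @param path output TSV path.
#' @export
write_timescale <- function(x, path) {
  ntip <- length(x$tree$tip.label)
  df <- data.frame(node = seq_along(x$node_age),
                   label = c(x$tree$tip.label,
                             rep("", x$tree$Nnode)),
                   age = x$node_age)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
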