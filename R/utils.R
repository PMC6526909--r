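## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' Fans a single user seed out into independent per-stage seeds so that
#' pipeline stages are individually re-runnable. Deterministic, stays
#' below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + 97003 * h) %% 2147483647)
}

## tip ids of the clade below each node (list indexed by node id)
descendant_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  out <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

## canonical string key for a set of tip labels
clade_key <- function(labels) paste(sort(labels), collapse = "\r")

## keys of all non-root internal clades of a rooted tree
tree_clade_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  dt <- descendant_tips(phy)
  nodes <- setdiff(seq.int(ntip + 1L, ntip + phy$Nnode), root)
  vapply(nodes, function(v) clade_key(phy$tip.label[dt[[v]]]), character(1))
}

## clades that are informative as unrooted groups: 2 <= size <= ntip - 2
## (a clade of all-but-one tips is the trivial split of the remaining tip)
support_clade_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  dt <- descendant_tips(phy)
  nodes <- setdiff(seq.int(ntip + 1L, ntip + phy$Nnode), root)
  keep <- vapply(nodes, function(v) {
    sz <- length(dt[[v]])
    sz >= 2 && sz <= ntip - 2
  }, logical(1))
  vapply(nodes[keep], function(v) clade_key(phy$tip.label[dt[[v]]]),
         character(1))
}

## canonical topology identity (rooted): sorted clade keys joined
topology_key <- function(phy) {
  paste(sort(tree_clade_keys(phy)), collapse = "\n")
}

## age of every node given tip ages, as time before present;
## here "age" increases rootward
node_times_from_root <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  depth <- numeric(n)
  pr <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(pr$edge))) {
    e <- pr$edge[k, ]
    depth[e[2]] <- depth[e[1]] + pr$edge.length[k]
  }
  depth
}

## validate that a tree is fully resolved (binary) and rooted
is_binary_rooted <- function(phy) {
  ape::is.rooted(phy) && ape::is.binary(phy)
}

stop_labeled <- function(...) stop(..., call. = FALSE)

## match tree tips into matrix rows; error on absentees
match_tips <- function(phy, m) {
  idx <- match(phy$tip.label, m$taxa)
  if (anyNA(idx))
    stop_labeled("tree tips absent from matrix: ",
                 paste(phy$tip.label[is.na(idx)], collapse = ", "))
  idx
}
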