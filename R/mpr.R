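#' Most-parsimonious-reconstruction ancestral state-sets
#'
#' For one character on a fully resolved rooted tree, computes for every
#' node the set of states appearing in at least one most-parsimonious
#' assignment (the MPR set), via a two-pass 0/1-cost dynamic programme:
#' a postorder pass gives, per node and state, the minimum change count
#' within the subtree; a preorder pass gives the minimum outside it; a
#' state belongs to the MPR set when the two sum to the character's
#' minimum length. Tip sets equal the observed cell state-sets.
#'
#' @param tree a fully resolved rooted `phylo` (polytomies are rejected).
#' @param matrix a [char_matrix].
#' @param char character (column) index.
#' @return an object of class `ancestral_states`: list with `states`
#'   (per-node list of state-symbol vectors, tips first then internal
#'   nodes in `phylo` numbering), `steps` (the character's parsimony
#'   length) and `char`.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' mpr_states(tr, m, 1)$states[[5]]   # root MPR set: "0" "1"
#' @export
mpr_states <- function(tree, matrix, char) {
  if (!is_binary_rooted(tree))
    stop_labeled("MPR requires a fully resolved rooted tree")
  idx <- match_tips(tree, matrix)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  k <- length(matrix$symbols[[char]])
  n <- ntip + nnode
  big <- n + 10  # safe stand-in for Inf under integer-ish arithmetic

  D <- matrix(big, n, k)   # min changes inside subtree, given node state
  for (i in seq_len(ntip)) {
    mask <- matrix$bits[idx[i], char]
    D[i, bit_positions(mask)] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  ord <- unique(po$edge[, 1])           # parents, children-first order
  cost_from <- function(vec) {
    # min over t of vec[t] + (s != t), for each s
    mn <- min(vec)
    pmin(vec, mn + 1)
  }
  for (v in ord) {
    acc <- 0
    for (ch in kids[[as.character(v)]]) acc <- acc + cost_from(D[ch, ])
    D[v, ] <- acc
  }
  root <- ntip + 1L
  best <- min(D[root, ])

  U <- matrix(0, n, k)    # min changes outside subtree, given node state
  for (v in rev(ord)) {   # preorder over internal nodes
    children <- kids[[as.character(v)]]
    for (ch in children) {
      sibs <- setdiff(children, ch)
      out_v <- U[v, ]
      for (w in sibs) out_v <- out_v + cost_from(D[w, ])
      # child state t costs min over parent state s of out_v[s] + (s != t)
      U[ch, ] <- cost_from(out_v)
    }
  }

  states <- vector("list", n)
  symbols <- matrix$symbols[[char]]
  for (i in seq_len(ntip))
    states[[i]] <- symbols[bit_positions(matrix$bits[idx[i], char])]
  for (v in ord)
    states[[v]] <- symbols[which(D[v, ] + U[v, ] <= best + 1e-9)]
  structure(list(states = states, steps = best, char = char,
                 tree = tree),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("MPR ancestral state-sets, character", x$char,
      "(", x$steps, "steps )\n")
  for (v in seq.int(ntip + 1, length(x$states)))
    cat(sprintf("  node %d: {%s}\n", v, paste(x$states[[v]], collapse = ",")))
  invisible(x)
}

#' Write ancestral states as TSV
#'
#' @param x `ancestral_states` or the node-probability matrix from
#'   [mk_marginal].
#' @param path output file.
#' @export
write_ancestral <- function(x, path) {
  if (inherits(x, "ancestral_states")) {
    df <- data.frame(node = seq_along(x$states),
                     states = vapply(x$states, paste, character(1),
                                     collapse = ","))
  } else {
    df <- data.frame(node = seq_len(nrow(x)), x, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
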