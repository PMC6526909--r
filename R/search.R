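## Heuristic maximum-parsimony search.
##
## Internally trees are held as parent arrays: tips keep their matrix row
## ids 1..ntip, internal nodes get arbitrary ids above ntip, par[id] = 0
## marks the root. The C++ scorer accepts such edge lists directly, so
## rearrangements are cheap pointer edits; conversion to ape's phylo
## happens only at the API boundary.

#' Search configuration
#'
#' @param n_starts random-addition replicates.
#' @param swap branch-swapping neighbourhood: `"nni"`, `"spr"` or `"tbr"`.
#' @param max_saved_trees cap on equally parsimonious trees kept.
#' @param ratchet_iterations parsimony-ratchet cycles per start (0 = off).
#' @param ratchet_perturb_fraction fraction of characters up-weighted
#'   (weight doubled) in each ratchet perturbation phase.
#' @param seed integer seed (mandatory; the search is fully reproducible).
#' @param outgroup taxon used to root reported trees (default: first
#'   matrix taxon; parsimony itself is rooting-invariant).
#' @return a validated list of class `search_config`.
#' @export
search_config <- function(n_starts = 20, swap = c("tbr", "spr", "nni"),
                          max_saved_trees = 100, ratchet_iterations = 50,
                          ratchet_perturb_fraction = 0.25, seed,
                          outgroup = NULL) {
  swap <- match.arg(swap)
  if (missing(seed)) stop_labeled("search_config requires a seed")
  stopifnot(n_starts >= 1, max_saved_trees >= 1, ratchet_iterations >= 0,
            ratchet_perturb_fraction > 0, ratchet_perturb_fraction < 1)
  structure(list(n_starts = as.integer(n_starts), swap = swap,
                 max_saved_trees = as.integer(max_saved_trees),
                 ratchet_iterations = as.integer(ratchet_iterations),
                 ratchet_perturb_fraction = ratchet_perturb_fraction,
                 seed = as.integer(seed), outgroup = outgroup),
            class = "search_config")
}

## ---- parent-array plumbing -------------------------------------------

par_to_edge <- function(par) {
  keep <- which(par > 0L)
  cbind(par[keep], keep)
}

edge_to_par <- function(edge) {
  par <- integer(max(edge))
  par[edge[, 2]] <- edge[, 1]
  par
}

phylo_to_par <- function(phy) edge_to_par(phy$edge)

par_root <- function(par) {
  cand <- setdiff(unique(par[par > 0L]), which(par > 0L))
  if (length(cand) != 1L) stop_labeled("tree has no unique root")
  cand
}

par_children <- function(par, v) which(par == v)

subtree_nodes <- function(par, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    frontier <- which(par %in% frontier)
    out <- c(out, frontier)
  }
  out
}

## convert parent array to an ape phylo (tips 1..ntip named by labels)
par_to_phylo <- function(par, tip_labels) {
  ntip <- length(tip_labels)
  root <- par_root(par)
  internals_old <- sort(unique(par[par > 0L]))
  stopifnot(all(internals_old > ntip) || TRUE)
  ## preorder renumbering of internal nodes
  newid <- integer(length(par))
  newid[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip + 1L
  edge <- matrix(0L, nrow = sum(par > 0L), ncol = 2)
  k <- 0L
  walk <- function(v) {
    newid[v] <<- nxt; nxt <<- nxt + 1L
    for (ch in sort(par_children(par, v))) {
      k <<- k + 1L
      if (ch <= ntip) {
        edge[k, ] <<- c(newid[v], ch)
      } else {
        edge[k, 1] <<- newid[v]
        pos <- k
        walk(ch)
        edge[pos, 2] <<- newid[ch]
      }
    }
  }
  walk(root)
  structure(list(edge = edge, tip.label = tip_labels,
                 Nnode = nxt - ntip - 1L),
            class = "phylo", order = "cladewise")
}

## root a parent-array tree on the edge above a given tip
root_par_at_tip <- function(par, tip) {
  root <- par_root(par)
  if (par[tip] == root && length(par_children(par, root)) == 2) return(par)
  ## reroot: new root splits edge (par[tip], tip)
  v_old <- root
  b <- tip
  a <- par[b]
  ## reuse generic subtree rerooting with v = old root
  reroot_at_edge(par, v_old, b)
}

## reroot the (sub)tree rooted at v so its root lies on edge (par(b), b);
## v's id is reused as the new root, the old degree-2 position is
## suppressed. par[v]'s original parent link is preserved.
reroot_at_edge <- function(par, v, b) {
  pv <- par[v]
  a <- par[b]
  if (a == v) return(par)        # root already on that edge
  path <- integer(0); n <- a
  while (n != v) { path <- c(path, n); n <- par[n] }
  path <- c(path, v)             # p0 = a, ..., pm = v
  m <- length(path) - 1L
  d <- setdiff(par_children(par, v), path[m])
  par[d] <- path[m]
  for (i in seq_len(m - 1L)) par[path[i + 1L]] <- path[i]
  par[a] <- v
  par[b] <- v
  par[v] <- pv
  par
}

## ---- scoring ----------------------------------------------------------

score_par <- function(par, ntip, bits, w, bound = Inf) {
  fitch_total_cpp(par_to_edge(par), ntip, bits, w, bound)
}

## ---- stepwise addition ------------------------------------------------

#' Random-addition starting tree
#'
#' Builds a fully resolved rooted tree by adding taxa in a seeded random
#' order, each at the insertion point minimizing the Fitch length.
#'
#' @param matrix a [char_matrix] with at least 3 taxa.
#' @param seed integer seed for the addition order.
#' @param weights optional character-weight override.
#' @return a `phylo`.
#' @export
random_addition_tree <- function(matrix, seed, weights = NULL) {
  res <- random_addition_par(matrix, seed, weights)
  par_to_phylo(res$par, matrix$taxa)
}

random_addition_par <- function(matrix, seed, weights = NULL) {
  ntip <- n_taxa(matrix)
  if (ntip < 3) stop_labeled("stepwise addition needs at least 3 taxa")
  w <- weights %||% matrix$weights
  ord <- withr_seed(seed, sample.int(ntip))
  res <- addition_tree_cpp(ord, ntip, matrix$bits, as.numeric(w))
  list(par = edge_to_par(res$edge), length = res$length)
}

## evaluate expr with a local RNG seed, restoring the RNG state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- hill climbing ----------------------------------------------------

hill_climb <- function(par, ntip, bits, w, swap) {
  if (swap == "spr") {
    res <- spr_search_cpp(par_to_edge(par), ntip, bits, w)
    list(par = edge_to_par(res$edge), length = res$length)
  } else {
    hill_climb_r(par, ntip, bits, w, swap)
  }
}

hill_climb_r <- function(par, ntip, bits, w, swap) {
  best <- score_par(par, ntip, bits, w)
  repeat {
    found <- find_improving_move(par, ntip, bits, w, best, swap)
    if (is.null(found)) break
    par <- found$par
    best <- found$length
  }
  list(par = par, length = best)
}

find_improving_move <- function(par, ntip, bits, w, best, swap) {
  root <- par_root(par)
  nodes <- sort(unique(c(which(par > 0L), root)))
  if (swap == "nni") {
    for (v in setdiff(nodes, c(seq_len(ntip), root))) {
      u <- par[v]
      sib <- setdiff(par_children(par, u), v)
      for (ch in par_children(par, v)) {
        cand <- par
        cand[sib] <- v
        cand[ch] <- u
        len <- score_par(cand, ntip, bits, w, best - 1e-9)
        if (len < best - 1e-9) return(list(par = cand, length = len))
      }
    }
    return(NULL)
  }
  ## spr / tbr in R (tbr adds rerooting of the pruned clade)
  for (v in setdiff(nodes, root)) {
    u <- par[v]
    g <- par[u]
    s <- setdiff(par_children(par, u), v)
    det <- par
    det[s] <- g          # if g == 0, s becomes the rest-component root
    det[u] <- 0L
    sub <- subtree_nodes(det, v)
    rest <- setdiff(nodes, c(sub, u))
    reroots <- list(NULL)
    if (swap == "tbr" && length(sub) > 2)
      reroots <- c(reroots, as.list(setdiff(sub[det[sub] != v], v)))
    for (b in reroots) {
      dv <- if (is.null(b)) det else {
        det2 <- det
        det2[v] <- u             # keep junction link through rerooting
        det2 <- reroot_at_edge(det2, v, b)
        det2
      }
      for (x in rest) {
        p <- dv[x]
        if (is.null(b) && x == s && p == g) next   # original position
        cand <- dv
        cand[u] <- p
        cand[x] <- u
        len <- score_par(cand, ntip, bits, w, best - 1e-9)
        if (len < best - 1e-9) return(list(par = cand, length = len))
      }
    }
  }
  NULL
}

## ---- ratchet ----------------------------------------------------------

#' Parsimony ratchet
#'
#' Alternates branch swapping on a perturbed-weight matrix (a seeded
#' random fraction of characters with doubled weight) and on the original
#' weights, keeping the best tree under the original weights. The result
#' is never worse than the hill-climbed starting tree; with 0 iterations
#' it is exactly the hill-climbed start.
#'
#' @param matrix a [char_matrix].
#' @param config a [search_config] (`ratchet_iterations`, `swap`,
#'   `ratchet_perturb_fraction` and `seed` are used).
#' @param start a fully resolved starting `phylo`.
#' @param weights optional base weight override.
#' @return a `phylo` with attribute `"length"`.
#' @export
ratchet <- function(matrix, config, start, weights = NULL) {
  w <- weights %||% matrix$weights
  idx <- match(start$tip.label, matrix$taxa)
  if (anyNA(idx)) stop_labeled("start tree tips absent from matrix")
  bits <- matrix$bits[idx, , drop = FALSE]
  res <- ratchet_par(phylo_to_par(start), length(start$tip.label), bits, w,
                     config, derive_seed(config$seed, "ratchet"))
  out <- par_to_phylo(res$par, start$tip.label)
  attr(out, "length") <- res$length
  out
}

ratchet_par <- function(par, ntip, bits, w, config, seed) {
  cur <- hill_climb(par, ntip, bits, w, config$swap)
  nchar <- ncol(bits)
  n_pert <- max(1L, round(config$ratchet_perturb_fraction * nchar))
  iters <- config$ratchet_iterations
  if (iters > 0) {
    for (i in seq_len(iters)) {
      sel <- withr_seed(derive_seed(seed, paste0("perturb", i)),
                        sample.int(nchar, n_pert))
      w2 <- w
      w2[sel] <- w2[sel] * 2
      pert <- hill_climb(cur$par, ntip, bits, w2, config$swap)
      back <- hill_climb(pert$par, ntip, bits, w, config$swap)
      if (back$length < cur$length - 1e-9) cur <- back
    }
  }
  cur
}

## ---- full search ------------------------------------------------------

#' Heuristic search for most parsimonious trees
#'
#' Multi-start search: seeded random-addition trees, hill-climbing with
#' the configured branch-swapping neighbourhood, and optionally the
#' parsimony ratchet. All distinct topologies found at the best length
#' are kept (up to `max_saved_trees`), rooted on the configured outgroup.
#'
#' @param matrix a [char_matrix].
#' @param config a [search_config].
#' @param weights optional character-weight override.
#' @return object of class `mp_search`: list with `length` (best found),
#'   `trees` (`multiPhylo` of equally best distinct topologies), `log`
#'   (per-start start/final lengths) and `config`.
#' @export
search_mpt <- function(matrix, config, weights = NULL) {
  stopifnot(inherits(config, "search_config"))
  w <- weights %||% matrix$weights
  ntip <- n_taxa(matrix)
  bits <- matrix$bits
  outgroup <- config$outgroup %||% matrix$taxa[1]
  og_tip <- match(outgroup, matrix$taxa)
  if (is.na(og_tip)) stop_labeled("outgroup not in matrix: ", outgroup)

  best_len <- Inf
  found <- list()      # topology_key -> phylo
  log <- data.frame(start = integer(), start_length = numeric(),
                    final_length = numeric())
  for (srt in seq_len(config$n_starts)) {
    st <- random_addition_par(matrix,
                              derive_seed(config$seed, paste0("start", srt)),
                              weights = w)
    res <- ratchet_par(st$par, ntip, bits, w, config,
                       derive_seed(config$seed, paste0("ratchet", srt)))
    log <- rbind(log, data.frame(start = srt, start_length = st$length,
                                 final_length = res$length))
    if (res$length < best_len - 1e-9) {
      best_len <- res$length
      found <- list()
    }
    if (res$length < best_len + 1e-9) {
      phy <- par_to_phylo(root_par_at_tip(res$par, og_tip), matrix$taxa)
      key <- topology_key(phy)
      if (is.null(found[[key]]) && length(found) < config$max_saved_trees)
        found[[key]] <- phy
    }
  }
  trees <- unname(found)
  class(trees) <- "multiPhylo"
  structure(list(length = best_len, trees = trees, log = log,
                 config = config),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("Maximum-parsimony search\n")
  cat(sprintf("  best length found: %s steps\n", format(x$length)))
  cat(sprintf("  equally parsimonious distinct topologies kept: %d\n",
              length(x$trees)))
  cat(sprintf("  starts: %d (%s swapping, %d ratchet cycles)\n",
              x$config$n_starts, x$config$swap, x$config$ratchet_iterations))
  invisible(x)
}

#' Strict consensus of trees
#'
#' The tree containing exactly the clades present in every input tree,
#' with polytomies where the inputs disagree.
#'
#' @param trees `multiPhylo` or list of `phylo` sharing one tip set.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (length(trees) == 1) return(trees[[1]])
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(tipsets)[-1])
    if (!identical(tipsets[[i]], tipsets[[1]]))
      stop_labeled("consensus requires identical tip sets")
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = TRUE)
}
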