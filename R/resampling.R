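#' Resampling configuration
#'
#' @param method `"bootstrap"` (characters resampled with replacement) or
#'   `"symmetric"` (each character's weight set to 0 with probability
#'   p/2, doubled with probability p/2, else unchanged).
#' @param replicates number of replicates (>= 1).
#' @param p change probability for symmetric resampling (default 0.33).
#' @param search per-replicate [search_config]; defaults to a reduced
#'   search (5 starts, SPR, no ratchet).
#' @param seed integer seed.
#' @return list of class `resampling_config`.
#' @export
resampling_config <- function(method = c("bootstrap", "symmetric"),
                              replicates = 100, p = 0.33, search = NULL,
                              seed) {
  method <- match.arg(method)
  if (missing(seed)) stop_labeled("resampling_config requires a seed")
  stopifnot(replicates >= 1, p >= 0, p <= 1)
  structure(list(method = method, replicates = as.integer(replicates),
                 p = p, search = search, seed = as.integer(seed)),
            class = "resampling_config")
}

default_replicate_search <- function(seed) {
  search_config(n_starts = 5, swap = "spr", ratchet_iterations = 0,
                seed = seed)
}

## run replicates, returning clade-frequency environment and replicate count
run_replicates <- function(matrix, config) {
  counts <- new.env(parent = emptyenv())
  base_w <- matrix$weights
  nc <- n_chars(matrix)
  for (r in seq_len(config$replicates)) {
    rseed <- derive_seed(config$seed, paste0("replicate", r))
    w <- withr_seed(rseed, {
      if (config$method == "bootstrap") {
        base_w * as.vector(rmultinom(1, nc, rep(1 / nc, nc)))
      } else {
        u <- runif(nc)
        ifelse(u < config$p / 2, 0,
               ifelse(u < config$p, 2 * base_w, base_w))
      }
    })
    scfg <- config$search %||% default_replicate_search(rseed)
    scfg$seed <- derive_seed(rseed, "search")
    res <- search_mpt(matrix, scfg, weights = w)
    cons <- strict_consensus(res$trees)
    for (key in support_clade_keys(cons)) {
      prev <- if (exists(key, counts)) get(key, counts) else 0L
      assign(key, prev + 1L, counts)
    }
  }
  counts
}

support_from_counts <- function(reference, counts, replicates, gc = FALSE) {
  ref_keys <- support_clade_keys(reference)
  all_keys <- ls(counts)
  freq_of <- function(key)
    100 * (if (exists(key, counts)) get(key, counts) else 0L) / replicates
  tipsets <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(clade = vapply(strsplit(ref_keys, "\r", fixed = TRUE),
                                   paste, character(1), collapse = ","),
                    frequency = vapply(ref_keys, freq_of, numeric(1)),
                    row.names = NULL)
  if (gc) {
    out$gc <- vapply(seq_along(ref_keys), function(i) {
      A <- strsplit(ref_keys[i], "\r", fixed = TRUE)[[1]]
      contra <- vapply(seq_along(all_keys), function(j) {
        B <- tipsets[[j]]
        ov <- length(intersect(A, B))
        ov > 0 && ov < length(A) && ov < length(B)
      }, logical(1))
      best_contra <- if (any(contra))
        max(vapply(all_keys[contra], freq_of, numeric(1))) else 0
      out$frequency[i] - best_contra
    }, numeric(1))
  }
  others <- setdiff(all_keys, ref_keys)
  attr(out, "other_groups") <- data.frame(
    clade = vapply(strsplit(others, "\r", fixed = TRUE), paste,
                   character(1), collapse = ","),
    frequency = vapply(others, freq_of, numeric(1)), row.names = NULL)
  class(out) <- c("support_table", "data.frame")
  out
}

#' Bootstrap clade support
#'
#' Nonparametric bootstrap: each replicate resamples the characters with
#' replacement (implemented as multinomial weights), reruns the search,
#' and takes the replicate's strict consensus; a reference clade's
#' support is the percentage of replicate consensuses containing it.
#'
#' @param matrix a [char_matrix].
#' @param reference rooted reference `phylo` whose clades are scored.
#' @param config a [resampling_config] with `method = "bootstrap"`.
#' @return a `support_table` data.frame (`clade`, `frequency` in
#'   percent); groups found in replicates but absent from the reference
#'   are in `attr(, "other_groups")`.
#' @export
bootstrap_support <- function(matrix, reference, config) {
  stopifnot(config$method == "bootstrap")
  counts <- run_replicates(matrix, config)
  support_from_counts(reference, counts, config$replicates, gc = FALSE)
}

#' Symmetric-resampling clade support (GC)
#'
#' Each replicate perturbs every character weight symmetrically (to 0 or
#' to double, each with probability p/2), reruns the search and takes the
#' strict consensus. Support is reported both as the raw frequency and as
#' the frequency difference GC = frequency(group) - frequency(its most
#' frequent contradictory group), between -100 and 100.
#'
#' @inheritParams bootstrap_support
#' @param config a [resampling_config] with `method = "symmetric"`.
#' @return a `support_table` with `clade`, `frequency` and `gc`.
#' @export
symmetric_resampling <- function(matrix, reference, config) {
  stopifnot(config$method == "symmetric")
  counts <- run_replicates(matrix, config)
  support_from_counts(reference, counts, config$replicates, gc = TRUE)
}

#' @export
print.support_table <- function(x, ...) {
  cat("Clade support (", nrow(x), "reference groups )\n")
  NextMethod()
}

#' Annotate a tree with support values
#'
#' Attaches the support column as internal node labels of the reference
#' tree (root unlabelled), for Newick export.
#'
#' @param reference the reference `phylo`.
#' @param table a `support_table`.
#' @param column column to use (default `"gc"` if present else
#'   `"frequency"`).
#' @return the tree with `node.label` set.
#' @export
annotate_support <- function(reference, table,
                             column = if ("gc" %in% names(table)) "gc"
                                      else "frequency") {
  ntip <- length(reference$tip.label)
  root <- ntip + 1L
  dt <- descendant_tips(reference)
  labs <- character(reference$Nnode)
  keys <- vapply(table$clade, function(cl)
    clade_key(strsplit(cl, ",", fixed = TRUE)[[1]]), character(1))
  for (v in seq.int(ntip + 1L, ntip + reference$Nnode)) {
    if (v == root) next
    key <- clade_key(reference$tip.label[dt[[v]]])
    i <- match(key, keys)
    if (!is.na(i)) labs[v - ntip] <- format(table[[column]][i])
  }
  reference$node.label <- labs
  reference
}
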