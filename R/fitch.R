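#' Fitch parsimony length of a tree
#'
#' Scores a rooted tree against a [char_matrix] under unordered (Fitch)
#' parsimony. Polytomies are scored as hard polytomies with Hartigan's
#' generalization; missing cells carry the full state-set and therefore
#' never force a change; entirely missing characters contribute 0 steps.
#' The total is the weighted sum of per-character step counts.
#'
#' @param tree a rooted `phylo`; tip labels must occur in `matrix`.
#' @param matrix a [char_matrix].
#' @param weights optional override of the matrix character weights
#'   (used by resampling and the ratchet).
#' @return an [index_report] with `length` and per-character observed
#'   steps filled in.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_length(tr, m)$length   # 1
#' @export
fitch_length <- function(tree, matrix, weights = NULL) {
  w <- weights %||% matrix$weights
  s <- fitch_steps(tree, matrix)
  new_index_report(length = sum(w * s), s = s, w = w)
}

## per-character observed steps (integer vector)
fitch_steps <- function(tree, matrix) {
  idx <- match_tips(tree, matrix)
  bits <- matrix$bits[idx, , drop = FALSE]
  fitch_counts_cpp(tree$edge, length(tree$tip.label), bits)
}

## weighted total with branch-and-bound cutoff, for search internals
fitch_total <- function(edge, ntip, bits, w, bound = Inf) {
  fitch_total_cpp(edge, ntip, bits, w, bound)
}

#' Per-character minimum steps
#'
#' The minimum number of steps a character can require on any tree:
#' (size of the smallest set of states intersecting every non-missing
#' cell state-set) - 1. Without polymorphism this is the number of
#' distinct observed states minus one.
#'
#' @param matrix a [char_matrix].
#' @param chars character indices (default all).
#' @return integer vector of minima.
#' @export
char_min_steps <- function(matrix, chars = seq_len(n_chars(matrix))) {
  vapply(chars, function(j) {
    masks <- matrix$bits[!matrix$missing[, j], j]
    if (!length(masks)) return(0L)
    k <- length(matrix$symbols[[j]])
    if (all(bitwAnd(masks, masks - 1L) == 0L))  # no polymorphism
      return(length(unique(masks)) - 1L)
    # smallest hitting set over the alphabet, sizes ascending
    for (size in 1:k) {
      for (comb in utils::combn(k, size, simplify = FALSE)) {
        sel <- as.integer(sum(bitwShiftL(1L, comb - 1L)))
        if (all(bitwAnd(masks, sel) != 0L)) return(size - 1L)
      }
    }
    k - 1L # unreachable: full alphabet always hits
  }, integer(1))
}

#' Per-character maximum steps
#'
#' The character's length on the star tree: (number of non-missing cells)
#' minus the largest achievable count of a single state, polymorphic cells
#' resolved in favour of the majority state.
#'
#' @inheritParams char_min_steps
#' @return integer vector of maxima.
#' @export
char_max_steps <- function(matrix, chars = seq_len(n_chars(matrix))) {
  vapply(chars, function(j) {
    masks <- matrix$bits[!matrix$missing[, j], j]
    n <- length(masks)
    if (!n) return(0L)
    k <- length(matrix$symbols[[j]])
    counts <- vapply(seq_len(k) - 1L, function(s)
      sum(bitwAnd(masks, bitwShiftL(1L, s)) != 0L), integer(1))
    as.integer(n - max(counts))
  }, integer(1))
}

#' Ensemble parsimony fit indices
#'
#' Tree length and the ensemble Consistency, Retention, Homoplasy and
#' Rescaled Consistency indices:
#' CI = sum(w m) / sum(w s), RI = (sum(w g) - sum(w s)) / (sum(w g) - sum(w m)),
#' HI = 1 - CI, RC = CI * RI, with parsimony-uninformative characters
#' (g = m) excluded from the RI sums. A matrix with zero total length
#' reports the indices as `NA` (undefined).
#'
#' @inheritParams fitch_length
#' @return an [index_report].
#' @examples
#' m <- char_matrix(rbind(A = c("0","0"), B = c("0","1"),
#'                        C = c("1","0"), D = c("1","1")))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' ensemble_indices(tr, m)   # CI = 2/3
#' @export
ensemble_indices <- function(tree, matrix, weights = NULL) {
  w <- weights %||% matrix$weights
  s <- fitch_steps(tree, matrix)
  m <- char_min_steps(matrix)
  g <- char_max_steps(matrix)
  new_index_report(length = sum(w * s), s = s, w = w, m = m, g = g)
}

new_index_report <- function(length, s, w, m = NULL, g = NULL) {
  rep <- list(length = length,
              per_char = data.frame(char = seq_along(s), steps = s,
                                    weight = w,
                                    min = if (is.null(m)) NA else m,
                                    max = if (is.null(g)) NA else g),
              ci = NA_real_, ri = NA_real_, hi = NA_real_, rc = NA_real_)
  if (!is.null(m) && !is.null(g)) {
    S <- sum(w * s); M <- sum(w * m)
    if (S > 0) {
      rep$ci <- M / S
      inf <- g > m
      denom <- sum(w[inf] * g[inf]) - sum(w[inf] * m[inf])
      rep$ri <- if (denom > 0)
        (sum(w[inf] * g[inf]) - sum(w[inf] * s[inf])) / denom else NA_real_
      rep$hi <- 1 - rep$ci
      rep$rc <- rep$ci * rep$ri
    }
  }
  structure(rep, class = "index_report")
}

#' Assemble an index report from published statistics
#'
#' Given a tree length and/or the ensemble CI and RI as printed in a
#' publication, derives the remaining ensemble indices (HI = 1 - CI,
#' RC = CI x RI). Useful for checking or completing reported cladogram
#' statistics without the underlying matrix.
#'
#' @param length tree length in steps (optional).
#' @param ci,ri ensemble consistency and retention indices.
#' @return an [index_report].
#' @examples
#' r <- index_report(length = 1604, ci = 0.291, ri = 0.756)
#' tnt_display(r)
#' @export
index_report <- function(length = NA_real_, ci = NA_real_, ri = NA_real_) {
  structure(list(length = length, per_char = NULL,
                 ci = ci, ri = ri,
                 hi = 1 - ci, rc = ci * ri),
            class = "index_report")
}

#' TNT-style display values of an index report
#'
#' Rounds CI, RI and HI to three decimals and truncates RC (TNT prints the
#' rescaled consistency index truncated, not rounded, to three decimals).
#'
#' @param x an [index_report].
#' @return named numeric vector `length, ci, ri, hi, rc`.
#' @export
tnt_display <- function(x) {
  stopifnot(inherits(x, "index_report"))
  c(length = x$length,
    ci = round(x$ci, 3), ri = round(x$ri, 3), hi = round(x$hi, 3),
    rc = floor(x$rc * 1000 + 1e-9) / 1000)
}

#' @export
print.index_report <- function(x, ...) {
  cat("Parsimony index report\n")
  cat(sprintf("  tree length: %s steps\n", format(x$length)))
  if (!is.na(x$ci)) {
    d <- tnt_display(x)
    cat(sprintf("  CI = %.3f  RI = %.3f  HI = %.3f  RC = %.3f\n",
                d["ci"], d["ri"], d["hi"], d["rc"]))
  }
  if (!is.null(x$per_char))
    cat("  per-character table available ($per_char)\n")
  invisible(x)
}

#' @export
as.data.frame.index_report <- function(x, ...) x$per_char

#' Write an index report as TSV
#'
#' One row per character plus a summary row.
#'
#' @param x an [index_report].
#' @param path output file.
#' @export
write_index_report <- function(x, path) {
  df <- x$per_char
  if (is.null(df)) df <- data.frame(char = integer(), steps = numeric(),
                                    weight = numeric(), min = numeric(),
                                    max = numeric())
  summ <- data.frame(char = NA, steps = x$length, weight = NA,
                     min = x$ci, max = x$ri)
  names(summ) <- names(df)
  utils::write.table(rbind(df, summ), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
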