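#' Mk(1) model of discrete character evolution
#'
#' The k-state equal-rates continuous-time Markov model: all transitions
#' share one rate, the stationary and root distributions are uniform.
#' `rate` is the expected number of substitutions per unit branch length,
#' so the per-pair rate is `rate / (k - 1)` and
#' `P_ii(t) = 1/k + (k-1)/k * exp(-k * rate/(k-1) * t)`.
#'
#' @param k number of states (`NULL` = use each character's own alphabet
#'   size).
#' @param rate substitution rate per unit branch length (> 0).
#' @return object of class `mk_model`.
#' @export
mk_model <- function(k = NULL, rate = 1) {
  if (!is.null(k)) stopifnot(k >= 2)
  stopifnot(rate > 0)
  structure(list(k = k, rate = rate), class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat(sprintf("Mk model: k = %s, rate = %g\n",
              if (is.null(x$k)) "per character" else x$k, x$rate))
  invisible(x)
}

#' Mk transition-probability matrix
#'
#' Closed form for the equal-rates model; rows sum to 1.
#'
#' @param model an [mk_model] with fixed `k`.
#' @param t branch length (>= 0).
#' @param k optional state count overriding the model's.
#' @return k x k stochastic matrix.
#' @examples
#' mk_transition(mk_model(k = 2, rate = 0.5), 1)[1, 1]  # 0.5 + 0.5*exp(-1)
#' @export
mk_transition <- function(model, t, k = model$k) {
  if (is.null(k)) stop_labeled("state count k required")
  if (t < 0) stop_labeled("negative branch length")
  beta <- model$rate / (k - 1)
  e <- exp(-k * beta * t)
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k - 1 / k * e
  P <- matrix(p_diff, k, k)
  diag(P) <- p_same
  P
}

## per-character tip likelihood matrices (chars handled independently);
## returns list(k, tipL): tipL is ntip x k 0/1 matrix for one character
tip_likelihoods <- function(matrix, idx, char, k) {
  ntip <- length(idx)
  L <- matrix(0, ntip, k)
  for (i in seq_len(ntip)) {
    if (matrix$missing[idx[i], char]) L[i, ] <- 1
    else L[i, bit_positions(matrix$bits[idx[i], char])] <- 1
  }
  L
}

char_k <- function(matrix, char, model) {
  kc <- length(matrix$symbols[[char]])
  k <- model$k %||% max(kc, 2L)
  if (kc > k) stop_labeled("character ", char, " has more states (", kc,
                           ") than the model's k = ", k)
  as.integer(k)
}

## Felsenstein pruning for one character; returns list(loglik, down)
## where down[[v]] is the scaled conditional likelihood vector of node v
## and attr "logscale" the accumulated per-node log scalers.
prune_char <- function(tree, matrix, idx, char, model) {
  k <- char_k(matrix, char, model)
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  tipL <- tip_likelihoods(matrix, idx, char, k)
  down <- vector("list", n)
  logscale <- numeric(n)
  for (i in seq_len(ntip)) down[[i]] <- tipL[i, ]
  po <- ape::reorder.phylo(tree, "postorder")
  P_edge <- lapply(seq_len(nrow(po$edge)), function(e)
    mk_transition(model, po$edge.length[e], k = k))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    msg <- as.vector(P_edge[[e]] %*% down[[ch]])
    if (is.null(down[[p]])) { down[[p]] <- msg; logscale[p] <- logscale[ch] }
    else { down[[p]] <- down[[p]] * msg; logscale[p] <- logscale[p] + logscale[ch] }
    mx <- max(down[[p]])
    if (mx > 0 && (mx < 1e-280 || mx > 1e280)) {
      down[[p]] <- down[[p]] / mx
      logscale[p] <- logscale[p] + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- sum(down[[root]] / k)
  list(loglik = log(lik) + logscale[root], down = down,
       logscale = logscale, k = k, P_edge = P_edge, po = po)
}

#' Mk log-likelihood of characters on a tree
#'
#' Felsenstein pruning with a uniform root prior. Missing tips carry a
#' vector of ones and do not alter the likelihood of the remaining data.
#'
#' @param tree rooted `phylo` with branch lengths (>= 0).
#' @param matrix a [char_matrix].
#' @param model an [mk_model].
#' @param chars character indices (default: all).
#' @return named numeric vector of per-character log-likelihoods.
#' @export
mk_loglik <- function(tree, matrix, model = mk_model(), chars = NULL) {
  if (is.null(tree$edge.length)) stop_labeled("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop_labeled("negative branch length")
  idx <- match_tips(tree, matrix)
  chars <- chars %||% seq_len(n_chars(matrix))
  prep <- prepare_tip_lik(tree, matrix, idx, chars, model)
  out <- mk_loglik_core(tree, prep, model)
  names(out) <- chars
  out
}

## tip conditional-likelihood matrices, grouped by state count; rate-free,
## so the rate optimizer builds them once
prepare_tip_lik <- function(tree, matrix, idx, chars, model) {
  kvals <- vapply(chars, function(j) char_k(matrix, j, model), integer(1))
  ntip <- length(tree$tip.label)
  groups <- lapply(unique(kvals), function(k) {
    sel <- which(kvals == k)
    nc <- length(sel)
    tips <- vector("list", ntip)
    for (i in seq_len(ntip)) {
      Li <- matrix(0, nc, k)
      for (ci in seq_len(nc)) {
        j <- chars[sel[ci]]
        if (matrix$missing[idx[i], j]) Li[ci, ] <- 1
        else Li[ci, bit_positions(matrix$bits[idx[i], j])] <- 1
      }
      tips[[i]] <- Li
    }
    list(k = k, sel = sel, nc = nc, tips = tips)
  })
  list(groups = groups, n_total = length(chars),
       po = ape::reorder.phylo(tree, "postorder"))
}

## pruning vectorized across characters sharing a state count
mk_loglik_core <- function(tree, prep, model) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- prep$po
  out <- numeric(prep$n_total)
  for (grp in prep$groups) {
    k <- grp$k; nc <- grp$nc
    P_edge <- lapply(po$edge.length, function(t) mk_transition(model, t, k = k))
    L <- vector("list", n)
    ls <- vector("list", n)
    for (i in seq_len(ntip)) { L[[i]] <- grp$tips[[i]]; ls[[i]] <- numeric(nc) }
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      msg <- L[[ch]] %*% P_edge[[e]]      # P is symmetric
      if (is.null(L[[p]])) { L[[p]] <- msg; ls[[p]] <- ls[[ch]] }
      else { L[[p]] <- L[[p]] * msg; ls[[p]] <- ls[[p]] + ls[[ch]] }
      mx <- L[[p]][cbind(seq_len(nc), max.col(L[[p]], ties.method = "first"))]
      mx[mx <= 0] <- 1
      L[[p]] <- L[[p]] / mx
      ls[[p]] <- ls[[p]] + log(mx)
    }
    out[grp$sel] <- log(rowSums(L[[root]]) / k) + ls[[root]]
  }
  out
}

#' Marginal ancestral-state probabilities under Mk
#'
#' Standard up/down-pass marginal reconstruction: each node's posterior
#' combines the conditional likelihood of its subtree with the likelihood
#' of the rest of the tree, under a uniform root prior. Vectors sum to 1.
#'
#' @inheritParams mk_loglik
#' @param char single character index.
#' @return matrix (nodes x states) of posterior probabilities, tips
#'   included (rows sum to 1 wherever defined).
#' @export
mk_marginal <- function(tree, matrix, char, model = mk_model()) {
  idx <- match_tips(tree, matrix)
  pr <- prune_char(tree, matrix, idx, char, model)
  k <- pr$k
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- pr$po
  ## up[v]: likelihood of everything outside v's subtree, given v's state
  up <- vector("list", n)
  up[[root]] <- rep(1 / k, k)
  edges <- rev(seq_len(nrow(po$edge)))   # preorder traversal
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (e in edges) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sib_edges <- setdiff(kids[[as.character(p)]], e)
    acc <- up[[p]]
    for (se in sib_edges)
      acc <- acc * as.vector(pr$P_edge[[se]] %*% pr$down[[po$edge[se, 2]]])
    up[[ch]] <- as.vector(t(pr$P_edge[[e]]) %*% acc)
    mx <- max(up[[ch]])
    if (mx > 0) up[[ch]] <- up[[ch]] / mx
  }
  out <- matrix(NA_real_, n, k)
  for (v in seq_len(n)) {
    if (is.null(up[[v]]) || is.null(pr$down[[v]])) next
    post <- up[[v]] * pr$down[[v]]
    out[v, ] <- post / sum(post)
  }
  nm <- matrix$symbols[[char]]
  if (length(nm) < k) nm <- c(nm, paste0("s", seq_len(k - length(nm))))
  colnames(out) <- nm[seq_len(k)]
  out
}

#' Maximum-likelihood Mk rate
#'
#' Maximizes the summed Mk log-likelihood over the substitution rate by
#' bounded one-dimensional optimization.
#'
#' @inheritParams mk_loglik
#' @param interval search interval for the rate.
#' @return object of class `mk_fit`: `rate`, `loglik`, `k`, `interval`.
#'   All-constant data drives the rate to the lower bound (with a
#'   warning).
#' @export
mk_fit_rate <- function(tree, matrix, model = mk_model(), chars = NULL,
                        interval = c(1e-6, 100)) {
  chars <- chars %||% seq_len(n_chars(matrix))
  idx <- match_tips(tree, matrix)
  prep <- prepare_tip_lik(tree, matrix, idx, chars, model)
  f <- function(r) {
    m2 <- mk_model(k = model$k, rate = r)
    sum(mk_loglik_core(tree, prep, m2))
  }
  ## coarse log-spaced bracketing first: the likelihood flattens at high
  ## rates (saturation), where golden-section search alone can drift
  grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 40))
  fg <- vapply(grid, f, numeric(1))
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  rate <- opt$maximum
  if (rate < interval[1] * 2)
    warning("fitted rate at the lower bound (data may be constant)")
  structure(list(rate = rate, loglik = opt$objective, k = model$k,
                 interval = interval, n_chars = length(chars)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk rate fit: rate = %.6g (logL = %.4f, %d characters)\n",
              x$rate, x$loglik, x$n_chars))
  invisible(x)
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = 1, class = "logLik")
}

#' @export
coef.mk_fit <- function(object, ...) c(rate = object$rate)
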