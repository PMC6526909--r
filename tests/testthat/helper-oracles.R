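# Independent oracles and fixture builders used across the suite.

# Brute-force parsimony: minimize the number of state changes over all
# assignments of single states to internal nodes; a terminal edge costs 0
# when the parent state lies in the tip's state-set. Independent of the
# package's Fitch/Hartigan code path.
brute_fitch <- function(tree, tipsets, k) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L), nn)))
  e <- tree$edge
  cost <- numeric(nrow(grid))
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1] - ntip
    ch <- e[i, 2]
    ps <- grid[, p]
    if (ch <= ntip) cost <- cost + !(ps %in% tipsets[[ch]])
    else cost <- cost + (ps != grid[, ch - ntip])
  }
  min(cost)
}

# MPR oracle: union, over all minimum-cost internal assignments, of the
# state used at each internal node.
brute_mpr <- function(tree, tipsets, k) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L), nn)))
  e <- tree$edge
  cost <- numeric(nrow(grid))
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1] - ntip
    ch <- e[i, 2]
    ps <- grid[, p]
    if (ch <= ntip) cost <- cost + !(ps %in% tipsets[[ch]])
    else cost <- cost + (ps != grid[, ch - ntip])
  }
  best <- min(cost)
  sets <- lapply(seq_len(nn), function(j) sort(unique(grid[cost == best, j])))
  list(steps = best, sets = sets)
}

# random rooted tree without branch lengths, optionally with polytomies
rand_topology <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- NULL
  if (polytomies && n >= 5) {
    tr <- ape::di2multi(ape::rtree(n, rooted = TRUE), tol = 0.6)
    tr$edge.length <- NULL
    if (tr$Nnode < 2) tr <- rand_topology(n, FALSE)
  }
  tr
}

# random cell-string matrix: k states, optional missing and polymorphism
rand_cells <- function(taxa, nchar, k = 2, p_missing = 0.1, p_poly = 0.05) {
  n <- length(taxa)
  cells <- matrix(as.character(sample(0:(k - 1), n * nchar, TRUE)), n,
                  dimnames = list(taxa, NULL))
  pick <- runif(n * nchar)
  cells[pick < p_poly & k > 1] <- paste0("{", paste(sample(0:(k - 1), 2),
                                                    collapse = ""), "}")
  cells[pick >= p_poly & pick < p_poly + p_missing] <- "?"
  cells
}

rand_char_matrix <- function(taxa, nchar, k = 2, p_missing = 0.1,
                             p_poly = 0.05) {
  char_matrix(rand_cells(taxa, nchar, k, p_missing, p_poly),
              symbols = rep(list(as.character(0:(k - 1))), nchar))
}

# tip state-sets of a char_matrix column as 0-based integers
column_tipsets <- function(m, tree, j) {
  idx <- match(tree$tip.label, m$taxa)
  lapply(idx, function(i) {
    which(bitwAnd(m$bits[i, j], bitwShiftL(1L, 0:30)) != 0L) - 1L
  })
}

# conflict-free ("clean signal") matrix: binary indicator characters for
# every non-root clade of a generating tree, n_per copies each
clean_matrix <- function(tree, n_per = 3) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  labs <- tree$tip.label
  cols <- list()
  for (v in setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)) {
    tips <- ape::extract.clade(tree, v)$tip.label
    col <- ifelse(labs %in% tips, "1", "0")
    for (r in seq_len(n_per)) cols[[length(cols) + 1]] <- col
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- labs
  char_matrix(cells)
}

# pectinate ("ladder") rooted tree: (((...,t3),t2),t1); with strictly
# rootward-older tip FADs every non-root node is consistent
ladder_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  txt <- paste0(paste(rep("(", n - 1), collapse = ""), labels[n])
  for (i in (n - 1):1) txt <- paste0(txt, ",", labels[i], ")")
  ape::read.tree(text = paste0(txt, ";"))
}

# ladder tree + ages with exactly `consistent` consistent nodes out of
# n - 2: one anomalously old tip makes every node on the path above it
# inconsistent
ladder_with_consistency <- function(n, consistent) {
  stopifnot(consistent >= 0, consistent <= n - 2)
  tr <- ladder_tree(n)
  fad <- n:1                       # tip i has FAD n - i + 1: all consistent
  p <- n - 1 - consistent          # one anomalously old tip at position p
  if (p >= 2) fad[p] <- 1000       # breaks nodes v_2..v_p (p - 1 of them)
  ages <- age_table(data.frame(taxon = sprintf("t%02d", seq_len(n)),
                               fad = fad, lad = 0))
  list(tree = tr, ages = ages)
}

expect_same_topology <- function(a, b) {
  expect_identical(morphostrat:::topology_key(a), morphostrat:::topology_key(b))
}

# semantic matrix identity: same taxa, missing flags, observed state-sets
# and weights (the extent of a missing cell's full set is the column
# alphabet, which legitimately collapses to the observed symbols on disk)
expect_same_cells <- function(a, b) {
  expect_identical(a$taxa, b$taxa)
  expect_identical(a$missing, b$missing)
  expect_equal(a$weights, b$weights)
  for (i in seq_len(n_taxa(a)))
    for (j in seq_len(n_chars(a)))
      if (!a$missing[i, j])
        expect_identical(sort(cell_states(a, i, j)),
                         sort(cell_states(b, i, j)),
                         info = sprintf("cell (%d, %d)", i, j))
}
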