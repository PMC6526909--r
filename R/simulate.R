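## Synthetic data with known ground truth. A single integer seed fans out
## into per-stage sub-streams (derive_seed) so that trees, characters and
## fossil ranges are independently reproducible.

#' Simulate a pure-birth (Yule) tree with known node ages
#'
#' Forward simulation from two lineages: with `n` lineages alive the
#' waiting time to the next split is Exp(n * birth_rate); after the
#' n_tips-th tip appears an extra Exp(n_tips * birth_rate) hold separates
#' the last split from the present, so the expected root age is
#' sum_{k=2..n_tips} 1 / (k * birth_rate). Ages are in Ma before present;
#' all tips are extant (age 0). `topology = "ladder"` keeps the same
#' waiting-time process but always splits the same trunk lineage,
#' producing a pectinate tree (useful for stratigraphic calibration
#' fixtures where every internal node has a terminal child).
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate per lineage per Myr (> 0).
#' @param seed integer seed.
#' @param topology `"random"` or `"ladder"`.
#' @return a `timescaled_tree` whose `truth` attribute records the
#'   generating parameters and per-tip lineage origin times.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed,
                               topology = c("random", "ladder")) {
  topology <- match.arg(topology)
  if (n_tips < 3) stop_labeled("need at least 3 tips")
  if (birth_rate <= 0) stop_labeled("birth_rate must be positive")
  withr_seed(derive_seed(seed, "yule"), {
    ## lineage records: parent node of each live lineage + its birth time
    split_time <- numeric(n_tips - 1)     # time of i-th split (root = 1st)
    t <- 0
    split_time[1] <- 0
    for (k in 2:(n_tips - 1)) {
      t <- t + rexp(1, k * birth_rate)
      split_time[k] <- t
    }
    present <- t + rexp(1, n_tips * birth_rate)

    ## build topology: maintain list of live lineages; each split picks one
    ntip <- n_tips
    n_int <- n_tips - 1
    par <- integer(ntip + n_int)
    node_time <- numeric(ntip + n_int)    # time from root start
    root <- ntip + 1L
    node_time[root] <- 0
    live <- c(1L, 2L)                      # provisional tip ids
    par[1L] <- root; par[2L] <- root
    birth <- numeric(ntip); birth[1:2] <- 0
    next_tip <- 3L
    for (k in 2:n_int) {
      pick <- if (topology == "ladder") length(live)
              else sample.int(length(live), 1)
      lin <- live[pick]
      v <- ntip + k                        # new internal node
      node_time[v] <- split_time[k]
      par[v] <- par[lin]
      par[lin] <- v
      par[next_tip] <- v
      live <- c(live[-pick], lin, next_tip)
      next_tip <- next_tip + 1L
    }
    node_time[seq_len(ntip)] <- present
    age <- present - node_time
    labels <- sprintf("t%02d", seq_len(ntip))
    phy <- par_to_phylo(par, labels)
    ## par_to_phylo renumbers internal nodes; recover ages by mapping:
    ## tips keep ids, internal ages recomputed from the preorder walk
    age_new <- numeric(ntip + n_int)
    age_new[seq_len(ntip)] <- 0
    ## map: replay the renumbering by matching clades
    dt_old <- descendant_tips_par(par, ntip)
    dt_new <- descendant_tips(phy)
    key_old <- vapply(dt_old$nodes, function(v)
      paste(sort(dt_old$tips[[v]]), collapse = ","), character(1))
    for (v in seq.int(ntip + 1L, ntip + n_int)) {
      key <- paste(sort(dt_new[[v]]), collapse = ",")
      old <- dt_old$nodes[match(key, key_old)]
      age_new[v] <- age[old]
    }
    ts <- timescaled_tree(phy, age_new)
    attr(ts, "truth") <- list(n_tips = n_tips, birth_rate = birth_rate,
                              seed = seed, topology = topology,
                              root_age = max(age_new))
    ts
  })
}

## descendant tips in parent-array form
descendant_tips_par <- function(par, ntip) {
  nodes <- sort(unique(par[par > 0L]))
  tips <- vector("list", length(par))
  for (i in seq_len(ntip)) tips[[i]] <- i
  remaining <- nodes
  while (length(remaining)) {
    for (v in remaining) {
      ch <- which(par == v)
      if (all(vapply(tips[ch], Negate(is.null), logical(1)))) {
        tips[[v]] <- unlist(tips[ch])
        remaining <- setdiff(remaining, v)
      }
    }
  }
  list(nodes = nodes, tips = tips)
}

#' Simulate discrete characters under the Mk model
#'
#' Root states are uniform; states evolve along branches with the
#' closed-form Mk transition probabilities; a random fraction of tip
#' cells is then masked as missing. Generating states at every node are
#' recorded as ground truth.
#'
#' @param ts a `timescaled_tree` (branch durations are the Mk branch
#'   lengths).
#' @param n_chars number of characters.
#' @param k states per character: a scalar, or a vector of probabilities
#'   over state counts 2, 3, ... from which each character's k is drawn.
#' @param rate substitution rate per Myr.
#' @param missing_frac fraction of tip cells masked as missing, in [0, 1).
#' @param seed integer seed.
#' @return a [char_matrix]; attribute `"truth"` holds the node-state
#'   matrix (nodes x characters, states 0-based) and parameters.
#' @export
simulate_mk_matrix <- function(ts, n_chars, k = 2, rate = 0.05,
                               missing_frac = 0, seed) {
  stopifnot(rate > 0, missing_frac >= 0, missing_frac < 1, n_chars >= 1)
  phy <- ts$tree
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  withr_seed(derive_seed(seed, "mk_matrix"), {
    kvec <- if (length(k) == 1) rep(as.integer(k), n_chars)
            else sample(seq_along(k) + 1L, n_chars, replace = TRUE, prob = k)
    states <- matrix(NA_integer_, n, n_chars)
    pr <- ape::reorder.phylo(phy, "cladewise")   # preorder edges
    root <- ntip + 1L
    for (j in seq_len(n_chars)) {
      kk <- kvec[j]
      model <- mk_model(k = kk, rate = rate)
      states[root, j] <- sample.int(kk, 1) - 1L
      for (e in seq_len(nrow(pr$edge))) {
        p <- pr$edge[e, 1]; ch <- pr$edge[e, 2]
        P <- mk_transition(model, pr$edge.length[e])
        states[ch, j] <- sample.int(kk, 1, prob = P[states[p, j] + 1L, ]) - 1L
      }
    }
    cells <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                    nrow = ntip, dimnames = list(phy$tip.label, NULL))
    if (missing_frac > 0) {
      mask <- matrix(runif(ntip * n_chars) < missing_frac, ntip, n_chars)
      cells[mask] <- "?"
    }
    symbols <- lapply(kvec, function(kk) as.character(seq_len(kk) - 1L))
    m <- char_matrix(cells, taxa = phy$tip.label, symbols = symbols)
    attr(m, "truth") <- list(states = states, k = kvec, rate = rate,
                             missing_frac = missing_frac, seed = seed)
    m
  })
}

#' Simulate fossil first/last-appearance ranges
#'
#' `perfect` preservation records each tip lineage from its true origin
#' (the age of its parent node) to its true end (the tip age);
#' `uniform_thinning` delays the first appearance below the true origin
#' by an exponential gap with mean `1/q` Myr (clamped at the last
#' appearance).
#'
#' @param ts a `timescaled_tree`.
#' @param preservation `"perfect"` or `"uniform_thinning"`.
#' @param q preservation rate: mean first-appearance gap is `1/q` Myr.
#' @param seed integer seed.
#' @return an [age_table]; attribute `"truth"` records true origins.
#' @export
simulate_fossil_ranges <- function(ts, preservation = c("perfect",
                                                        "uniform_thinning"),
                                   q = 1, seed = 1) {
  preservation <- match.arg(preservation)
  phy <- ts$tree
  ntip <- length(phy$tip.label)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  origin <- ts$node_age[parent[seq_len(ntip)]]
  lad <- ts$node_age[seq_len(ntip)]
  fad <- origin
  if (preservation == "uniform_thinning") {
    stopifnot(q > 0)
    gap <- withr_seed(derive_seed(seed, "preservation"),
                      rexp(ntip, rate = q))
    fad <- pmax(lad, origin - gap)
  }
  at <- age_table(data.frame(taxon = phy$tip.label, fad = fad, lad = lad))
  attr(at, "truth") <- list(origin = origin, preservation = preservation,
                            q = q, seed = seed)
  at
}

#' Simulate a complete study-scale dataset
#'
#' Convenience wrapper producing a tree, a character matrix and an age
#' table with full ground truth. The defaults emulate a large fossil
#' mysticete-type analysis: 82 taxa scored for 350 mostly binary
#' characters (state counts 2-6), 30% missing data, a speciation rate
#' giving a root age of roughly 35-40 Ma, a substitution rate in the
#' highly homoplastic regime typical of morphological matrices, and
#' exponential first-appearance gaps averaging 3 Myr.
#'
#' @param seed integer seed (drives every stage).
#' @param n_tips,n_chars dimensions.
#' @param birth_rate speciation rate (per lineage per Myr).
#' @param k per-character state-count distribution (see
#'   [simulate_mk_matrix]).
#' @param rate Mk substitution rate per Myr.
#' @param missing_frac missing-data fraction.
#' @param preservation,q fossil preservation model (see
#'   [simulate_fossil_ranges]).
#' @param topology tree shape (see [simulate_yule_tree]).
#' @return list with `ts` (`timescaled_tree`), `matrix` ([char_matrix]),
#'   `ages` ([age_table]) and `seed`.
#' @export
simulate_dataset <- function(seed, n_tips = 82, n_chars = 350,
                             birth_rate = 0.11,
                             k = c(0.6, 0.2, 0.1, 0.05, 0.05),
                             rate = 0.02, missing_frac = 0.3,
                             preservation = "uniform_thinning", q = 1 / 3,
                             topology = "random") {
  ts <- simulate_yule_tree(n_tips, birth_rate, seed, topology)
  m <- simulate_mk_matrix(ts, n_chars, k, rate, missing_frac, seed)
  ages <- simulate_fossil_ranges(ts, preservation, q, seed)
  list(ts = ts, matrix = m, ages = ages, seed = seed)
}
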