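fixture_abc <- function() {
  list(tree = ape::read.tree(text = "((A,B),C);"),
       ages = age_table(data.frame(taxon = c("A", "B", "C"),
                                   fad = c(10, 8, 5), lad = c(9, 8, 0))))
}

test_that("clade first-appearance is the max FAD of its tips", {
  fx <- fixture_abc()
  # tips: their own fad; internal: oldest descendant; root: oldest overall
  expect_equal(clade_fad(fx$tree, 1, fx$ages), 10)
  expect_equal(clade_fad(fx$tree, 5, fx$ages), 10)   # (A,B)
  expect_equal(clade_fad(fx$tree, 4, fx$ages), 10)   # root
  ages2 <- age_table(data.frame(taxon = c("A", "B", "C"),
                                fad = c(8.7, 5.3, 11.6), lad = 0))
  expect_equal(clade_fad(fx$tree, 4, ages2), 11.6)
  expect_error(clade_fad(fx$tree, 5,
                         age_table(data.frame(taxon = "A", fad = 1, lad = 0))),
               "missing")
})

test_that("node consistency compares a clade's FAD with its sister's", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  ages <- age_table(data.frame(taxon = c("A", "B", "C", "D"),
                               fad = c(8, 6, 12, 4), lad = 0))
  # clade (A,B) fad 8 vs sister (C,D) fad 12: consistent
  expect_true(node_is_consistent(tr, 6, ages))
  # mirror: (C,D) fad 12 vs 8: inconsistent
  expect_false(node_is_consistent(tr, 7, ages))
  # equal fads: consistent under <=, inconsistent under strict
  ages_eq <- age_table(data.frame(taxon = c("A", "B", "C", "D"),
                                  fad = c(8, 6, 8, 4), lad = 0))
  expect_true(node_is_consistent(tr, 6, ages_eq))
  expect_true(node_is_consistent(tr, 7, ages_eq))
  expect_false(node_is_consistent(tr, 6, ages_eq, strict = TRUE))
  expect_error(node_is_consistent(tr, 5, ages), "root")
})

test_that("SCI counts consistent nodes over tips - 2", {
  # rootward-older ladder: SCI 1, denominator n - 2
  n <- 10
  lw <- ladder_with_consistency(n, n - 2)
  rep <- sci(lw$tree, lw$ages)
  expect_equal(rep$total, n - 2)
  expect_equal(rep$sci, 1.0)
  # engineered counts
  lw2 <- ladder_with_consistency(12, 4)
  rep2 <- sci(lw2$tree, lw2$ages)
  expect_equal(rep2$consistent, 4)
  expect_equal(rep2$total, 10)
  # uniform age shift leaves SCI unchanged
  sh <- lw2$ages
  sh$fad <- sh$fad + 7.5
  sh$lad <- sh$lad + 7.5
  expect_equal(sci(lw2$tree, sh)$sci, rep2$sci)
  expect_error(sci(ape::read.tree(text = "(A,B);"),
                   age_table(data.frame(taxon = c("A", "B"), fad = 1,
                                        lad = 0))), "3 tips")
})

test_that("SCI matches per-node enumeration on random trees and ages", {
  set.seed(40)
  for (rep in 1:10) {
    n <- 10
    tr <- rand_topology(n)
    ages <- age_table(data.frame(taxon = tr$tip.label,
                                 fad = round(runif(n, 1, 30), 1), lad = 0))
    got <- sci(tr, ages)
    # independent per-node check from first principles
    dt <- morphostrat:::descendant_tips(tr)
    fad <- ages$fad[match(tr$tip.label, ages$taxon)]
    parent <- integer(n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    manual <- 0
    for (v in setdiff((n + 1):(n + tr$Nnode), n + 1)) {
      cf <- max(fad[dt[[v]]])
      sis <- setdiff(tr$edge[tr$edge[, 1] == parent[v], 2], v)
      sf <- max(vapply(sis, function(s) max(fad[dt[[s]]]), numeric(1)))
      manual <- manual + (cf <= sf)
    }
    expect_equal(got$consistent, manual)
    expect_equal(got$total, n - 2)
  }
})

test_that("partition SCI evaluates the subtree rooted at the clade MRCA", {
  n <- 14
  lw <- ladder_with_consistency(n, 5)
  sub_tips <- sprintf("t%02d", 6:14)   # a nested ladder clade
  rep <- sci(lw$tree, lw$ages, clade = sub_tips)
  expect_equal(rep$total, length(sub_tips) - 2)
  expect_error(sci(lw$tree, lw$ages, clade = c("t06", "nope")), "nope")
})

test_that("minimum-age time-scaling reproduces the worked fixture", {
  fx <- fixture_abc()
  ts <- timescale(fx$tree, fx$ages)
  # node (A,B) at 10 Ma, root at 10 Ma
  expect_equal(ts$node_age[5], 10)
  expect_equal(ts$node_age[4], 10)
  # ghosts: B originates at 10, first appears at 8; C at 10 vs 5
  ghosts <- setNames(ts$ghost, fx$tree$edge[, 2])
  expect_equal(unname(ghosts[as.character(2)]), 2)
  expect_equal(unname(ghosts[as.character(3)]), 5)
  expect_equal(sum(ts$ghost), 7)
})

test_that("equal tip ages collapse to zero ghosts; min_branch pushes apart", {
  tr <- ladder_tree(3)
  ages <- age_table(data.frame(taxon = tr$tip.label, fad = 6, lad = 0))
  ts <- timescale(tr, ages)
  expect_true(all(ts$node_age[4:5] == 6))
  expect_true(all(ts$ghost == 0))
  ts2 <- timescale(tr, ages, min_branch = 1)
  age_in <- ts2$node_age[4:5]
  expect_equal(sort(age_in), c(7, 8))   # strictly increasing rootward by >= 1
  expect_true(all(ts2$ghost >= 0))
})

test_that("time-scaled trees satisfy ordering and ghost-sum invariants", {
  set.seed(50)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    tr <- rand_topology(n)
    fad <- round(runif(n, 2, 25), 2)
    ages <- age_table(data.frame(taxon = tr$tip.label, fad = fad,
                                 lad = round(fad * runif(n), 2)))
    ts <- timescale(tr, ages)
    for (k in seq_len(nrow(tr$edge)))
      expect_gte(ts$node_age[tr$edge[k, 1]], ts$node_age[tr$edge[k, 2]])
    expect_true(all(ts$ghost >= -1e-12))
    # sum of ghosts decomposes into tip gaps plus internal origin gaps
    parent <- integer(n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    tip_gap <- sum(ts$node_age[parent[1:n]] - ts$fad)
    int_nodes <- setdiff((n + 1):(n + tr$Nnode), n + 1)
    int_gap <- sum(ts$node_age[parent[int_nodes]] - ts$node_age[int_nodes])
    expect_equal(sum(ts$ghost), tip_gap + int_gap, tolerance = 1e-9)
  }
})

test_that("perfect preservation recovers true node ages on ladder trees", {
  sim <- simulate_yule_tree(12, 0.5, seed = 61, topology = "ladder")
  ranges <- simulate_fossil_ranges(sim, "perfect")
  ts <- timescale(sim$tree, ranges)
  # internal node ages recovered exactly (tips carry their FAD by design)
  internal <- seq.int(13, 12 + sim$tree$Nnode)
  expect_equal(ts$node_age[internal], sim$node_age[internal],
               tolerance = 1e-9)
  # every terminal lineage is recorded from its true origin: no tip ghosts
  tip_edges <- ts$tree$edge[, 2] <= 12
  expect_equal(sum(ts$ghost[tip_edges]), 0, tolerance = 1e-9)
})
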