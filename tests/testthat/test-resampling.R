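# taxa ordered so the default outgroup (first taxon) stays outside the
# clades whose support is being measured
six_taxa <- c("t5", "t6", "t3", "t4", "t1", "t2")

support_of <- function(tab, tips) {
  i <- match(paste(sort(tips), collapse = ","),
             vapply(strsplit(tab$clade, ","), function(x)
               paste(sort(x), collapse = ","), character(1)))
  tab$frequency[i]
}

gc_of <- function(tab, tips) {
  i <- match(paste(sort(tips), collapse = ","),
             vapply(strsplit(tab$clade, ","), function(x)
               paste(sort(x), collapse = ","), character(1)))
  tab$gc[i]
}

test_that("a unanimously supported clade bootstraps to 100", {
  cells <- matrix("0", 6, 50, dimnames = list(six_taxa, NULL))
  cells[c("t1", "t2"), ] <- "1"   # 50 identical characters for (t1,t2)
  m <- char_matrix(cells)
  ref <- ape::read.tree(text = "(t5,(t6,(t3,(t4,(t1,t2)))));")
  cfg <- resampling_config("bootstrap", replicates = 30,
                           search = search_config(n_starts = 2, swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 1),
                           seed = 42)
  tab <- bootstrap_support(m, ref, cfg)
  expect_equal(support_of(tab, c("t1", "t2")), 100)
})

test_that("an uninformative matrix gives no resolved support", {
  set.seed(6)
  cells <- matrix("0", 6, 30, dimnames = list(six_taxa, NULL))
  cells[cbind(sample(1:6, 30, TRUE), 1:30)] <- "1"  # all autapomorphies
  m <- char_matrix(cells)
  ref <- ape::read.tree(text = "(t5,(t6,(t3,(t4,(t1,t2)))));")
  ## enough starts that each replicate finds many equally-best topologies,
  ## whose strict consensus is (near-)star: no resolved group is supported
  cfg <- resampling_config("bootstrap", replicates = 20,
                           search = search_config(n_starts = 10,
                                                  swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 2),
                           seed = 7)
  tab <- bootstrap_support(m, ref, cfg)
  expect_true(all(tab$frequency <= 10))
})

test_that("two equal conflicting blocks split the support evenly", {
  cells <- matrix("0", 6, 40, dimnames = list(six_taxa, NULL))
  cells[c("t1", "t2"), 1:20] <- "1"   # block 1: (t1,t2)
  cells[c("t1", "t3"), 21:40] <- "1"  # block 2: (t1,t3)
  m <- char_matrix(cells)
  ref <- ape::read.tree(text = "(t5,(t6,(t4,(t3,(t1,t2)))));")
  cfg <- resampling_config("bootstrap", replicates = 200,
                           search = search_config(n_starts = 2, swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 3),
                           seed = 101)
  tab <- bootstrap_support(m, ref, cfg)
  f_ab <- support_of(tab, c("t1", "t2"))
  others <- attr(tab, "other_groups")
  key_ac <- paste(sort(c("t1", "t3")), collapse = ",")
  f_ac <- others$frequency[match(key_ac, vapply(strsplit(others$clade, ","),
                                                function(x) paste(sort(x), collapse = ","),
                                                character(1)))]
  if (is.na(f_ac)) f_ac <- 0
  # symmetry of the two blocks (binomial noise at 200 replicates)
  expect_lt(abs(f_ab - f_ac), 12)
  expect_gt(f_ab, 25)
  expect_lt(f_ab, 65)
})

test_that("symmetric resampling at p = 0 gives GC = 100 for true clades", {
  set.seed(10)
  tr <- rand_topology(7)
  m <- clean_matrix(tr, n_per = 2)
  base <- search_mpt(m, search_config(n_starts = 3, swap = "spr",
                                      ratchet_iterations = 0, seed = 20))
  ref <- strict_consensus(base$trees)
  cfg <- resampling_config("symmetric", replicates = 10, p = 0,
                           search = search_config(n_starts = 2, swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 4),
                           seed = 55)
  tab <- symmetric_resampling(m, ref, cfg)
  expect_true(all(tab$gc == 100))
  expect_true(all(tab$frequency == 100))
})

test_that("GC reaches -100 when a contradictory group is unanimous", {
  cells <- matrix("0", 6, 30, dimnames = list(six_taxa, NULL))
  cells[c("t1", "t3"), ] <- "1"       # data support (t1,t3) only
  m <- char_matrix(cells)
  ref <- ape::read.tree(text = "(t5,(t6,(t4,(t3,(t1,t2)))));")  # claims (t1,t2)
  cfg <- resampling_config("symmetric", replicates = 10, p = 0,
                           search = search_config(n_starts = 2, swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 5),
                           seed = 66)
  tab <- symmetric_resampling(m, ref, cfg)
  expect_equal(gc_of(tab, c("t1", "t2")), -100)
})

test_that("support is seed-reproducible and GC never exceeds the frequency", {
  set.seed(12)
  tr <- rand_topology(6)
  m <- rand_char_matrix(tr$tip.label, 25, k = 2, p_missing = 0.1)
  cfg <- resampling_config("symmetric", replicates = 15, p = 0.33,
                           search = search_config(n_starts = 2, swap = "spr",
                                                  ratchet_iterations = 0,
                                                  seed = 6),
                           seed = 77)
  t1 <- symmetric_resampling(m, tr, cfg)
  t2 <- symmetric_resampling(m, tr, cfg)
  expect_identical(t1$frequency, t2$frequency)
  expect_identical(t1$gc, t2$gc)
  expect_true(all(t1$gc <= t1$frequency + 1e-9))
  expect_true(all(t1$gc >= -100 & t1$gc <= 100))
})
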