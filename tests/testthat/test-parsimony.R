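test_that("fitch_length matches hand-checkable 4-tip cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- char_matrix(rbind(A = c("0", "0", "1"), B = c("0", "1", "1"),
                         C = c("1", "0", "1"), D = c("1", "1", "1")))
  s <- fitch_length(tr, m)$per_char$steps
  expect_equal(s, c(1L, 2L, 0L))   # grouping char, conflicting char, constant
  expect_equal(fitch_length(tr, m)$length, 3)
})

test_that("fitch_length equals the brute-force oracle on random trees", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(2:4, 1)
    poly <- rep %% 3 == 0
    tr <- rand_topology(n, polytomies = poly)
    m <- rand_char_matrix(tr$tip.label, 8, k = k, p_missing = 0.15,
                          p_poly = 0.1)
    s <- fitch_length(tr, m)$per_char$steps
    for (j in 1:8) {
      expect_equal(s[j], brute_fitch(tr, column_tipsets(m, tr, j), k),
                   info = sprintf("rep %d char %d", rep, j))
    }
  }
})

test_that("fitch_length is invariant under re-rooting", {
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(6:8, 1)
    tr <- rand_topology(n)
    m <- rand_char_matrix(tr$tip.label, 15, k = 3)
    base <- fitch_length(tr, m)$length
    for (og in tr$tip.label) {
      rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                            resolve.root = TRUE)
      expect_equal(fitch_length(rerooted, m)$length, base)
    }
  }
})

test_that("fitch_length agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    tr <- rand_topology(n)
    cells <- rand_cells(tr$tip.label, 30, k = 3, p_missing = 0.2, p_poly = 0)
    m <- char_matrix(cells, symbols = rep(list(c("0", "1", "2")), 30))
    pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1", "2"),
                           ambiguity = "?")
    s_ph <- phangorn::fitch(tr, pd, site = "site")[attr(pd, "index")]
    expect_equal(fitch_length(tr, m)$per_char$steps, as.integer(s_ph))
  }
})

test_that("char_min_steps handles distinct states, missing and polymorphism", {
  m <- char_matrix(rbind(A = c("0", "?", "0"), B = c("1", "?", "1"),
                         C = c("2", "?", "{01}")))
  expect_equal(char_min_steps(m), c(2L, 0L, 1L))
  # polymorphism can be absorbed: {0},{1},{0,1} needs 2 states -> 1 step
  m2 <- char_matrix(rbind(A = "0", B = "1", C = "{01}"))
  expect_equal(char_min_steps(m2), 1L)
  # the polymorphic cell can also cover both: {0},{0,1} -> 0 steps
  m3 <- char_matrix(rbind(A = "0", B = "{01}", C = "0"))
  expect_equal(char_min_steps(m3), 0L)
})

test_that("char_max_steps equals the star-tree score", {
  m <- char_matrix(rbind(A = "0", B = "0", C = "0", D = "1", E = "1",
                         F = "2"))
  expect_equal(char_max_steps(m), 3L)
  m2 <- char_matrix(rbind(A = "0", B = "0", C = "0"))
  expect_equal(char_max_steps(m2), 0L)
  m3 <- char_matrix(rbind(A = "0", B = "1"))
  expect_equal(char_max_steps(m3), 1L)
  # star-tree Fitch oracle on random columns
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    star <- ape::read.tree(text = paste0("(", paste(sprintf("t%d", 1:n),
                                                    collapse = ","), ");"))
    m <- rand_char_matrix(star$tip.label, 6, k = 3, p_poly = 0.15)
    expect_equal(char_max_steps(m), fitch_length(star, m)$per_char$steps)
  }
})

test_that("m_i <= s_i <= g_i on random tree/matrix pairs", {
  set.seed(9)
  for (rep in 1:10) {
    tr <- rand_topology(sample(5:10, 1))
    m <- rand_char_matrix(tr$tip.label, 20, k = sample(2:4, 1))
    s <- fitch_length(tr, m)$per_char$steps
    expect_true(all(char_min_steps(m) <= s))
    expect_true(all(s <= char_max_steps(m)))
  }
})

test_that("ensemble indices follow their definitions", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- char_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
                         C = c("1", "0"), D = c("1", "1")))
  idx <- ensemble_indices(tr, m)
  expect_equal(idx$ci, 2 / 3)           # (1+1)/(1+2)
  expect_equal(idx$hi, 1 - idx$ci)
  expect_equal(idx$rc, idx$ci * idx$ri)
  # perfect fit
  mclean <- clean_matrix(tr, n_per = 2)
  idx2 <- ensemble_indices(tr, mclean)
  expect_equal(idx2$ci, 1)
  expect_equal(idx2$hi, 0)
  expect_equal(idx2$length, sum(char_min_steps(mclean)))
  # all-constant matrix: undefined, not 0/0
  mconst <- char_matrix(rbind(A = "0", B = "0", C = "0", D = "0"))
  idx3 <- ensemble_indices(tr, mconst)
  expect_true(is.na(idx3$ci))
})

test_that("ensemble indices agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tr <- rand_topology(9)
  cells <- rand_cells(tr$tip.label, 40, k = 2, p_missing = 0.1, p_poly = 0)
  m <- char_matrix(cells, symbols = rep(list(c("0", "1")), 40))
  pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  idx <- ensemble_indices(tr, m)
  expect_equal(idx$ci, phangorn::CI(tr, pd), tolerance = 1e-12)
  expect_equal(idx$ri, phangorn::RI(tr, pd), tolerance = 1e-12)
})

test_that("weights scale the total length", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- char_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
                         C = c("1", "0"), D = c("1", "1")),
                   weights = c(3, 2))
  expect_equal(fitch_length(tr, m)$length, 3 * 1 + 2 * 2)
})

test_that("MPR state-sets match the enumeration oracle", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # conflicting character: root MPR set is {0,1}
  m <- char_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
  mp <- mpr_states(tr, m, 1)
  expect_equal(mp$states[[5]], c("0", "1"))
  # grouping character: cherries fixed, root ambiguous
  m2 <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  mp2 <- mpr_states(tr, m2, 1)
  expect_equal(mp2$states[[6]], "0")
  expect_equal(mp2$states[[7]], "1")
  expect_equal(mp2$states[[5]], c("0", "1"))
  # constant character: every node that state
  m3 <- char_matrix(rbind(A = "2", B = "2", C = "2", D = "2"),
                    symbols = list(c("0", "1", "2")))
  mp3 <- mpr_states(tr, m3, 1)
  for (v in 5:7) expect_equal(mp3$states[[v]], "2")
  # random cases against the oracle
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tr <- rand_topology(n)
    k <- sample(2:3, 1)
    m <- rand_char_matrix(tr$tip.label, 1, k = k, p_missing = 0.2,
                          p_poly = 0.1)
    mp <- mpr_states(tr, m, 1)
    or <- brute_mpr(tr, column_tipsets(m, tr, 1), k)
    expect_equal(mp$steps, or$steps)
    for (j in seq_len(tr$Nnode)) {
      got <- sort(match(mp$states[[n + j]], as.character(0:(k - 1))) - 1L)
      expect_equal(got, or$sets[[j]], info = sprintf("rep %d node %d", rep, j))
    }
  }
})

test_that("MPR rejects polytomies and keeps observed tip sets", {
  tr <- ape::read.tree(text = "(A,B,C);")
  m <- char_matrix(rbind(A = "0", B = "1", C = "0"))
  expect_error(mpr_states(tr, m, 1), "resolved")
  tr2 <- ape::read.tree(text = "((A,B),C);")
  m2 <- char_matrix(rbind(A = "{01}", B = "1", C = "0"))
  expect_equal(mpr_states(tr2, m2, 1)$states[[1]], c("0", "1"))
})

test_that("published-statistics index_report derives HI and RC", {
  r <- index_report(length = 100, ci = 0.5, ri = 0.8)
  expect_equal(r$hi, 0.5)
  expect_equal(r$rc, 0.4)
  d <- tnt_display(index_report(ci = 0.333, ri = 0.5))
  expect_equal(unname(d["rc"]), 0.166)   # truncated, not rounded
})
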