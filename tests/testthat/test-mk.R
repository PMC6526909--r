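test_that("Mk transition matrices follow the closed form", {
  mod <- mk_model(k = 2, rate = 0.5)
  expect_equal(mk_transition(mod, 0), diag(2))
  # k=2, rate 0.5 => beta = 0.5, P_ii(1) = 0.5 + 0.5 * exp(-1)
  expect_equal(mk_transition(mod, 1)[1, 1], 0.5 + 0.5 * exp(-1))
  # stationary limit
  P <- mk_transition(mk_model(k = 4, rate = 1), 1e6)
  expect_true(all(abs(P - 0.25) < 1e-9))
  expect_error(mk_transition(mod, -1), "negative")
})

test_that("Mk transitions match a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (k in 2:6) {
    for (r in c(0.1, 1, 3)) {
      for (t in c(0.01, 0.5, 2)) {
        Q <- matrix(r / (k - 1), k, k)
        diag(Q) <- -r
        P_oracle <- as.matrix(Matrix::expm(Q * t))
        P <- mk_transition(mk_model(k = k, rate = r), t)
        expect_lt(max(abs(P - P_oracle)), 1e-10)
        expect_true(all(abs(rowSums(P) - 1) < 1e-12))
      }
    }
  }
})

test_that("mk_loglik degenerate cases are exact", {
  # all branch lengths 0, all tips in state 0: likelihood = 1/k
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  m <- char_matrix(rbind(A = "0", B = "0", C = "0"),
                   symbols = list(c("0", "1")))
  expect_equal(mk_loglik(tr, m, mk_model(k = 2))[[1]], log(1 / 2))
  # both tips missing: likelihood 1
  tr2 <- ape::read.tree(text = "(A:1,B:2);")
  m2 <- char_matrix(rbind(A = "?", B = "?"), symbols = list(c("0", "1")))
  expect_equal(mk_loglik(tr2, m2, mk_model(k = 2))[[1]], 0)
  # two-tip explicit enumeration
  m3 <- char_matrix(rbind(A = "0", B = "1"), symbols = list(c("0", "1")))
  tr3 <- ape::read.tree(text = "(A:0.3,B:0.8);")
  mod <- mk_model(k = 2, rate = 1)
  Pa <- mk_transition(mod, 0.3)
  Pb <- mk_transition(mod, 0.8)
  brute <- sum(vapply(1:2, function(s) 0.5 * Pa[s, 1] * Pb[s, 2],
                      numeric(1)))
  expect_equal(mk_loglik(tr3, m3, mod)[[1]], log(brute))
})

test_that("missing tips do not alter the likelihood of the remaining data", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m_full <- char_matrix(rbind(A = "0", B = "1", C = "?", D = "?"),
                        symbols = list(c("0", "1")))
  drop <- ape::drop.tip(tr, c("C", "D"))
  m_two <- char_matrix(rbind(A = "0", B = "1"), symbols = list(c("0", "1")))
  mod <- mk_model(k = 2, rate = 0.4)
  expect_equal(mk_loglik(tr, m_full, mod)[[1]],
               mk_loglik(drop, m_two, mod)[[1]], tolerance = 1e-10)
})

test_that("mk_loglik is invariant under re-rooting", {
  set.seed(19)
  for (rep in 1:5) {
    tr <- ape::rtree(7)
    m <- rand_char_matrix(tr$tip.label, 10, k = 3, p_missing = 0.15,
                          p_poly = 0)
    mod <- mk_model(rate = 0.7)
    base <- sum(mk_loglik(tr, m, mod))
    for (og in tr$tip.label[1:3]) {
      re <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
      expect_equal(sum(mk_loglik(re, m, mod)), base, tolerance = 1e-8)
    }
  }
})

test_that("mk_loglik matches an independent pruning implementation", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  tr <- ape::rtree(9)
  cells <- rand_cells(tr$tip.label, 25, k = 2, p_missing = 0.2, p_poly = 0)
  m <- char_matrix(cells, symbols = rep(list(c("0", "1")), 25))
  pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  fit <- phangorn::pml(tr, pd)
  expect_equal(sum(mk_loglik(tr, m, mk_model(k = 2, rate = 1))),
               as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("marginal reconstructions are proper and respect symmetry", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  marg <- mk_marginal(tr, m, 1, mk_model(k = 2, rate = 0.3))
  expect_true(all(abs(rowSums(marg) - 1) < 1e-10))
  expect_equal(unname(marg[5, ]), c(0.5, 0.5))   # symmetric root
  # unanimous short-branch data: root nearly certain
  tr2 <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  m2 <- char_matrix(rbind(A = "0", B = "0", C = "0", D = "0"),
                    symbols = list(c("0", "1")))
  marg2 <- mk_marginal(tr2, m2, 1, mk_model(k = 2, rate = 1))
  expect_gt(marg2[5, "0"], 0.99)
  # saturation limit: uniform everywhere
  tr3 <- ape::read.tree(text = "((A:50,B:50):50,(C:50,D:50):50);")
  marg3 <- mk_marginal(tr3, m, 1, mk_model(k = 2, rate = 5))
  expect_true(all(abs(marg3[5:7, ] - 0.5) < 1e-3))
})

test_that("fitted rate scales inversely with branch lengths", {
  sim_tree <- simulate_yule_tree(16, 0.4, seed = 31)
  m <- simulate_mk_matrix(sim_tree, 120, k = 2, rate = 0.3,
                          missing_frac = 0, seed = 31)
  f1 <- mk_fit_rate(sim_tree$tree, m)
  doubled <- sim_tree$tree
  doubled$edge.length <- doubled$edge.length * 2
  f2 <- mk_fit_rate(doubled, m)
  expect_equal(f1$rate / f2$rate, 2, tolerance = 1e-3)
  # constant data: boundary warning
  mconst <- char_matrix(matrix("0", 16, 4,
                               dimnames = list(sim_tree$tree$tip.label, NULL)),
                        symbols = rep(list(c("0", "1")), 4))
  expect_warning(mk_fit_rate(sim_tree$tree, mconst), "lower bound")
})
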