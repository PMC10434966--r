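test_that("correlation matrices match a textbook Pearson oracle", {
  ds <- toy_profiles()
  m <- correlation_matrix(ds)
  expect_equal(m$scores["A", "B"], 1.0)   # scaled copy
  expect_equal(m$scores["A", "C"], -1.0)  # reflection around the mean
  expect_equal(m$scores["A", "D"],
               pearson_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_true(is.na(m$scores["A", "A"]))

  set.seed(42)
  ab <- matrix(stats::rlnorm(8 * 10), 8,
               dimnames = list(paste0("P", 1:8), paste0("f", 1:10)))
  m2 <- correlation_matrix(profile_dataset(ab, "d", "c", "s"))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(m2$scores[i, j], pearson_oracle(ab[i, ], ab[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance profiles are excluded from rankings", {
  ab <- rbind(A = c(1, 2, 3), B = c(2, 4, 6), FLAT = c(5, 5, 5))
  colnames(ab) <- paste0("f", 1:3)
  m <- correlation_matrix(profile_dataset(ab, "d", "c", "s"))
  expect_true(all(is.na(m$scores["FLAT", ])))
  prof <- rank_interactors(m, "A")
  expect_identical(prof$ranked, "B")
})

test_that("interactor ranking sorts by score with lexicographic tie-break", {
  sc <- matrix(c(NA, 0.9, 0.1, 0.9, NA, 0.5, 0.1, 0.5, NA), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- interaction_matrix(sc, "d", "c", "s")
  expect_identical(rank_interactors(m, "A")$ranked, c("B", "C"))
  sc2 <- matrix(0.5, 3, 3, dimnames = list(c("A", "C", "B"), c("A", "C", "B")))
  m2 <- interaction_matrix(sc2, "d", "c", "s")
  expect_identical(rank_interactors(m2, "A")$ranked, c("B", "C"))
  expect_error(rank_interactors(m2, "Z"), "not in dataset")

  # full ranking equals a direct sort oracle on random input
  set.seed(1)
  m3 <- random_interaction_matrix(6)
  for (p in m3$proteins) {
    s <- m3$scores[p, setdiff(m3$proteins, p)]
    oracle <- names(s)[order(-s, names(s))]
    expect_identical(rank_interactors(m3, p)$ranked, oracle)
  }
})

test_that("rbo_depth returns the smallest depth reaching the coverage", {
  expect_identical(rbo_depth(0.9, 0.99), 44L)
  expect_identical(rbo_depth(0.5, 0.99), 7L)
  expect_identical(rbo_depth(0.9, 1e-9), 1L)
  # brute-force scan agreement over a parameter grid
  for (p in c(0.3, 0.5, 0.8, 0.9, 0.95)) {
    for (cov in c(0.5, 0.9, 0.99)) {
      k <- 1L
      while (1 - p^k < cov) k <- k + 1L
      expect_identical(rbo_depth(p, cov), k)
    }
  }
})

test_that("rbo_score matches closed forms and hand-worked examples", {
  # identical long lists: geometric sum 1 - p^k
  ids <- sprintf("P%03d", 1:100)
  expect_equal(rbo_score(ids, ids, p = 0.9), 1 - 0.9^44, tolerance = 1e-12)
  # identical short lists: exactly 1 - p^L
  expect_equal(rbo_score(ids[1:5], ids[1:5], p = 0.9), 1 - 0.9^5,
               tolerance = 1e-12)
  # disjoint lists
  expect_identical(rbo_score(c("A", "B"), c("X", "Y"), p = 0.9), 0)
  # hand-evaluated agreement sum
  expect_equal(rbo_score(c("A", "B", "C"), c("A", "C", "B"), p = 0.5, k = 3),
               0.75)
  # cross-species agreement through an orthology translation
  expect_equal(rbo_score(c("hA", "hB"), c("yB", "yA"), p = 0.5, k = 2,
                         mapping = c(yA = "hA", yB = "hB")), 0.25)
  # empty profile
  expect_identical(rbo_score(character(), c("A"), p = 0.9), 0)
})

test_that("rbo_score equals the brute-force prefix-overlap oracle", {
  set.seed(99)
  universe <- sprintf("U%03d", 1:60)
  for (rep in 1:250) {
    p <- stats::runif(1, 0.3, 0.95)
    k <- sample(1:20, 1)
    la <- sample(universe, sample(1:30, 1))
    lb <- sample(universe, sample(1:30, 1))
    expect_equal(rbo_score(la, lb, p = p, k = k),
                 rbo_bruteforce(la, lb, p = p, k = k), tolerance = 1e-12)
  }
})

test_that("rbo_score is symmetric, bounded and label-invariant", {
  set.seed(7)
  universe <- sprintf("U%02d", 1:40)
  bij <- stats::setNames(sprintf("V%02d", sample(40)), universe)
  for (rep in 1:50) {
    la <- sample(universe, sample(5:25, 1))
    lb <- sample(universe, sample(5:25, 1))
    s <- rbo_score(la, lb)
    expect_gte(s, 0)
    expect_lt(s, 1)
    expect_equal(rbo_score(lb, la), s, tolerance = 1e-12)
    expect_equal(rbo_score(unname(bij[la]), unname(bij[lb])), s,
                 tolerance = 1e-12)
  }
  # adding agreement at the bottom never decreases the score
  la <- sprintf("A%02d", 1:10)
  lb <- c(sprintf("B%02d", 1:9), "X")
  s0 <- rbo_score(c(la, "X"), lb, p = 0.8, k = 15)
  s1 <- rbo_score(c(la, "X"), c(lb[1:9], "A01"), p = 0.8, k = 15)
  expect_gte(s1, s0)
})

test_that("cross-species mapping never creates accidental identifier matches", {
  # unmapped b-identifiers textually equal to a-identifiers must not count
  la <- c("P1", "P2")
  lb <- c("P1", "P2")  # same strings, different species, no orthology
  expect_identical(rbo_score(la, lb, p = 0.5, k = 2,
                             mapping = stats::setNames(character(), character())),
                   0)
})
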