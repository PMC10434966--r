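test_that("all-pairs similarity equals the element-wise rbo oracle", {
  set.seed(3)
  ma <- random_interaction_matrix(6, "d1", "c1", "s1", prefix = "A")
  mb <- random_interaction_matrix(5, "d2", "c2", "s2", prefix = "B")
  map <- orthology_map(data.frame(a = c("A01", "A02", "A03"),
                                  b = c("B01", "B02", "B03")), "s1", "s2")
  S <- pairwise_interactor_similarity(ma, mb, map, p = 0.8, coverage = 0.95)
  lut <- orthology_lookup(map, "s2")
  k <- rbo_depth(0.8, 0.95)
  for (i in ma$proteins) for (j in mb$proteins) {
    expect_equal(S[i, j],
                 rbo_bruteforce(rank_interactors(ma, i)$ranked,
                                rank_interactors(mb, j)$ranked,
                                p = 0.8, k = k, mapping = lut),
                 tolerance = 1e-12)
  }
  # a cross-species pair without an orthology map is a configuration error
  expect_error(pairwise_interactor_similarity(ma, mb, NULL), "orthology")
})

test_that("self-comparison puts each protein's own counterpart at the row maximum", {
  set.seed(5)
  ma <- random_interaction_matrix(8, "d1", "c1", "s1")
  mb <- ma; mb$dataset_id <- "d2"
  S <- pairwise_interactor_similarity(ma, mb, NULL)
  for (i in seq_along(ma$proteins))
    expect_identical(which.max(S[i, ]), stats::setNames(i, ma$proteins[i]))
})

test_that("datasets sharing no orthologous interactors score zero everywhere", {
  set.seed(6)
  ma <- random_interaction_matrix(5, "d1", "c1", "s1", prefix = "A")
  mb <- random_interaction_matrix(5, "d2", "c2", "s2", prefix = "B")
  map <- orthology_map(data.frame(a = character(), b = character()),
                       "s1", "s2")
  S <- pairwise_interactor_similarity(ma, mb, map)
  expect_true(all(S == 0))
})

test_that("reciprocal top-hit selection is mutual, tie-tolerant and symmetric", {
  set.seed(8)
  S <- matrix(stats::runif(100 * 100), 100,
              dimnames = list(sprintf("A%03d", 1:100),
                              sprintf("B%03d", 1:100)))
  keep <- select_reciprocal_top_hits(S, 0.01)
  # brute-force reciprocal-rank oracle: top-ceil(0.01*100)=1 of each side,
  # ties at the cutoff kept
  kr <- 1L
  oracle <- matrix(FALSE, 100, 100)
  row_thr <- apply(S, 1, function(x) sort(x, decreasing = TRUE)[kr])
  col_thr <- apply(S, 2, function(x) sort(x, decreasing = TRUE)[kr])
  for (i in 1:100) for (j in 1:100)
    oracle[i, j] <- S[i, j] >= row_thr[i] && S[i, j] >= col_thr[j] && S[i, j] > 0
  expect_identical(unname(keep), oracle)
  # each protein contributes at most its single best score, only if mutual
  expect_lte(max(rowSums(keep)), 1)
  expect_lte(max(colSums(keep)), 1)
  # symmetry under swapping the dataset order
  keep_t <- select_reciprocal_top_hits(t(S), 0.01)
  expect_identical(unname(t(keep_t)), unname(keep))
  # an asymmetric best hit is dropped
  S2 <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  dimnames(S2) <- list(c("x1", "x2"), c("y1", "y2"))
  k2 <- select_reciprocal_top_hits(S2, 0.5)  # top-1 per protein
  expect_true(k2["x1", "y1"])
  expect_false(k2["x2", "y1"])  # y1 prefers x1
  # fraction 1 keeps every nonzero pair
  S2[1, 2] <- 0
  expect_identical(select_reciprocal_top_hits(S2, 1), S2 > 0)
})

test_that("edge counts after selection respect the fraction-implied bound", {
  set.seed(80)
  for (rep in 1:5) {
    na <- sample(20:60, 1); nb <- sample(20:60, 1)
    S <- matrix(stats::runif(na * nb), na,
                dimnames = list(sprintf("A%02d", 1:na), sprintf("B%02d", 1:nb)))
    frac <- sample(c(0.01, 0.05, 0.1), 1)
    keep <- select_reciprocal_top_hits(S, frac)
    bound <- min(na, nb) * ceiling(frac * max(na, nb))
    expect_lte(sum(keep), bound)
  }
})

test_that("per-pair normalization rescales to mean 1 and preserves order", {
  es1 <- edge_set(matrix(c(2, 0, 0, 4), 2,
                         dimnames = list(c("a1", "a2"), c("b1", "b2"))),
                  matrix(c(TRUE, FALSE, FALSE, TRUE), 2), "d1", "d2")
  out <- normalize_pair_scores(list(es1))[[1]]
  expect_equal(sort(out$edges$weight), c(2 / 3, 4 / 3))
  # two sets with different means both end at mean 1
  es2 <- edge_set(matrix(c(0.2, 0, 0, 0.3), 2,
                         dimnames = list(c("a1", "a2"), c("c1", "c2"))),
                  matrix(c(TRUE, FALSE, FALSE, TRUE), 2), "d1", "d3")
  outs <- normalize_pair_scores(list(es1, es2))
  for (es in outs) expect_equal(mean(es$edges$weight), 1, tolerance = 1e-9)
  # idempotence on an already-mean-1 set
  again <- normalize_pair_scores(outs)
  expect_equal(again[[1]]$edges$weight, outs[[1]]$edges$weight)
})

test_that("hypernetwork assembly unions edges and reports isolated elements", {
  m1 <- matrix(c(0.9, 0, 0, 0.8), 2,
               dimnames = list(c("p1", "p2"), c("p1", "p2")))
  es1 <- edge_set(m1, m1 > 0, "d1", "d2")
  m2 <- matrix(0.7, 1, 1, dimnames = list("q1", "q1"))
  es2 <- edge_set(m2, m2 > 0, "d3", "d4")
  net <- build_hypernetwork(normalize_pair_scores(list(es1, es2)))
  expect_identical(length(net$nodes), 6L)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 3)
  # duplicate edges across sets violate the construction invariant
  expect_error(build_hypernetwork(list(es1, es1)), "duplicate")
  # isolated detected proteins are excluded but reported
  ds <- toy_profiles("d1", "c1", "s1")
  net2 <- build_hypernetwork(list(es1), datasets = list(ds))
  expect_true("d1::C" %in% net2$isolated)
  expect_false("d1::C" %in% net2$nodes)
})
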