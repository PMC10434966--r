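# A small multi-collection fixture used across the post-processing tests:
# two collections of one species (4 + 2 datasets) and one of a second
# species, with a partial orthology.
pp_fixture <- function() {
  mk <- function(id, coll, sp) {
    ab <- matrix(stats::runif(8), 2, dimnames = list(c("X", "Y"), NULL))
    rownames(ab) <- paste0(sp, c("X", "Y"))
    profile_dataset(ab, id, coll, sp)
  }
  datasets <- c(
    lapply(1:4, function(i) mk(paste0("h", i), "humA", "hs")),
    lapply(1:2, function(i) mk(paste0("g", i), "humB", "hs")),
    lapply(1:2, function(i) mk(paste0("y", i), "yst", "sc")))
  orth <- orthology_map(data.frame(a = "hsX", b = "scX"), "hs", "sc")
  list(datasets = datasets, orthologies = list(orth))
}

test_that("superclusters split into per-collection element sets", {
  fx <- pp_fixture()
  el <- c("h1::hsX", "h2::hsX", "g1::hsX", "y1::scX", "y2::scY")
  sp <- split_supercluster(el, fx$datasets)
  expect_setequal(names(sp), c("humA", "humB", "yst"))
  expect_setequal(sp$humA, c("h1::hsX", "h2::hsX"))
  expect_setequal(sp$yst, c("y1::scX", "y2::scY"))
  expect_error(split_supercluster(c(el, "zz::p"), fx$datasets), "unknown")
})

test_that("FrC divides by the collection's total dataset count", {
  # clustered in 3 of the collection's 4 datasets -> 3/4
  el <- c("h1::hsX", "h2::hsX", "h3::hsX")
  expect_equal(fraction_clustered(el, 4L)[["hsX"]], 3 / 4)
  # in all datasets -> 1
  expect_equal(fraction_clustered(c(el, "h4::hsX"), 4L)[["hsX"]], 1)
  # detection does not change the denominator: a protein detected (and
  # clustered) in a single dataset of a 4-dataset collection scores 1/4
  expect_equal(fraction_clustered("h1::hsY", 4L)[["hsY"]], 1 / 4)
})

test_that("best-guess selection rescues low-FrC proteins with a qualifying equivalent", {
  fx <- pp_fixture()
  # humA: hsX in 3/4 (0.75); humB: hsX in 1/2 (0.5, not > 1/2);
  # yst: scX in 2/2 (1.0), scY in 1/2
  cl <- list(c("h1::hsX", "h2::hsX", "h3::hsX", "g1::hsX",
               "y1::scX", "y2::scX", "y1::scY"))
  sup <- process_clusters(cl, fx$datasets, fx$orthologies)[[1]]
  expect_equal(sup$subclusters$humA$members[["hsX"]], 0.75)
  expect_true("hsX" %in% sup$subclusters$humA$best_guess)
  # humB hsX has FrC exactly 1/2 (not above threshold) but its
  # same-species equivalent in humA scores 0.75 -> rescued
  expect_equal(sup$subclusters$humB$members[["hsX"]], 0.5)
  expect_true("hsX" %in% sup$subclusters$humB$best_guess)
  # yst scY at 0.5 has no qualifying equivalent (hsY not present above
  # threshold, and no orthology for Y) -> excluded
  expect_false("scY" %in% sup$subclusters$yst$best_guess)
  # scX qualifies on its own and via orthology
  expect_true("scX" %in% sup$subclusters$yst$best_guess)
  # raising the threshold never adds members
  sup_hi <- process_clusters(cl, fx$datasets, fx$orthologies,
                             best_guess_threshold = 0.9)[[1]]
  for (cc in names(sup$subclusters))
    expect_true(all(sup_hi$subclusters[[cc]]$best_guess %in%
                      sup$subclusters[[cc]]$best_guess))
})

test_that("matches count equivalent elements with min(n,k) possible per pair", {
  fx <- pp_fixture()
  # same species pair: {P1,P2} vs {P1,P3} -> 1 actual, 2 possible
  el <- c("h1::hsX", "h1::hsY", "h2::hsX")
  mm <- count_matches(el, fx$datasets)
  expect_identical(mm$actual, 1L)
  expect_identical(mm$possible, 1L)  # min(2, 1)
  # cross-species through orthology
  el2 <- c("h1::hsX", "h1::hsY", "y1::scX", "y1::scY")
  mm2 <- count_matches(el2, fx$datasets, fx$orthologies)
  # only hsX-scX are orthologous; hsY/scY are not equivalent
  expect_identical(mm2$actual, 1L)
  expect_identical(mm2$possible, 2L)
  expect_true(all(mm2$pairs$actual <= mm2$pairs$possible))
})

test_that("per-pair match counts match a hand enumeration on a 3-collection toy", {
  fx <- pp_fixture()
  el <- c("h1::hsX", "h1::hsY", "h2::hsX", "g1::hsX", "y1::scX", "y2::scX")
  mm <- count_matches(el, fx$datasets, fx$orthologies)
  want <- list(
    "g1 h1" = c(1L, 1L), "g1 h2" = c(1L, 1L), "g1 y1" = c(1L, 1L),
    "g1 y2" = c(1L, 1L), "h1 h2" = c(1L, 1L), "h1 y1" = c(1L, 1L),
    "h1 y2" = c(1L, 1L), "h2 y1" = c(1L, 1L), "h2 y2" = c(1L, 1L),
    "y1 y2" = c(1L, 1L))
  got <- stats::setNames(
    lapply(seq_len(nrow(mm$pairs)), function(i)
      c(mm$pairs$actual[i], mm$pairs$possible[i])),
    paste(mm$pairs$dataset_a, mm$pairs$dataset_b))
  expect_identical(got[order(names(got))], want[order(names(want))])
  # supercluster coherence and the per-collection restriction
  expect_equal(coherence_score(mm$actual, mm$possible), 1)
  expect_equal(subcluster_coherence(mm$pairs, "yst", fx$datasets), 1)
  expect_equal(subcluster_coherence(mm$pairs, "absent", fx$datasets), 0)
})

test_that("coherence aggregates actual over possible matches", {
  expect_equal(round(coherence_score(46, 71), 3), 0.648)
  expect_identical(coherence_score(0, 5), 0)
  expect_identical(coherence_score(5, 5), 1)
  expect_identical(coherence_score(0, 0), 0)
  pairs <- data.frame(actual = c(2, 3), possible = c(4, 3))
  expect_equal(coherence_from_pairs(pairs), 5 / 7)
})

test_that("the retention filter needs 2 matches and one FrC at or above 0.5", {
  fx <- pp_fixture()
  # 1 match, max FrC 1 -> fails
  cl1 <- c("h1::hsX", "h2::hsX", "h3::hsX", "h4::hsX")
  # one protein at FrC exactly 0.5 with 2 matches -> passes (inclusive)
  cl2 <- c("h1::hsX", "h2::hsX", "h1::hsY", "h3::hsY")
  sup <- process_clusters(list(cl1, cl2), fx$datasets, fx$orthologies)
  expect_identical(sup[[1]]$actual_matches, 6L)
  expect_true(sup[[1]]$passed_filter)
  expect_identical(sup[[2]]$actual_matches, 2L)
  expect_equal(max(unlist(lapply(sup[[2]]$subclusters,
                                 function(s) s$members))), 0.5)
  expect_true(sup[[2]]$passed_filter)
  # enough matches but no protein reaching the FrC bound -> fails on the
  # FrC arm alone
  clA <- c("h1::hsX", "h2::hsX", "h3::hsY", "h4::hsY")
  supA <- process_clusters(list(clA), fx$datasets, fx$orthologies,
                           min_frc = 0.6)[[1]]
  expect_identical(supA$actual_matches, 2L)
  expect_false(supA$passed_filter)
  # a single match is not enough even with FrC 1
  cl0 <- c("y1::scY", "y2::scY")
  sup0 <- process_clusters(list(cl0), fx$datasets, fx$orthologies)[[1]]
  expect_identical(sup0$actual_matches, 1L)
  expect_false(sup0$passed_filter)
})

test_that("reference annotation picks the best cluster above the strict majority", {
  fx <- pp_fixture()
  # build clusters by hand: cluster 1 holds hsX in humA, cluster 2 holds hsY
  cl <- list(c("h1::hsX", "h2::hsX", "y1::scX", "y2::scX"),
             c("h1::hsY", "h2::hsY", "h3::hsY"))
  sup <- process_clusters(cl, fx$datasets, fx$orthologies)
  ref <- reference_complexes(list(goodC = c("hsX", "hsZ"),
                                  exactHalf = c("hsY", "hsQ"),
                                  absentC = c("hsW", "hsV", "hsU")))
  ann <- annotate_with_reference(sup, ref, "humA", min_fraction = 0.4)
  asg <- attr(ann, "assignments")
  # goodC: 1 of 2 members in cluster 1 -> fraction 0.5 > 0.4 -> annotated
  expect_identical(asg$cluster_id[asg$complex == "goodC"], 1L)
  expect_true("goodC" %in% ann[[1]]$annotation)
  # strict threshold: exactly at min_fraction is not enough
  ann2 <- annotate_with_reference(sup, ref, "humA", min_fraction = 0.5)
  asg2 <- attr(ann2, "assignments")
  expect_false("goodC" %in% asg2$complex)
  # absent complex annotates nothing
  expect_false("absentC" %in% asg$complex)
  # each complex assigned at most once
  expect_false(anyDuplicated(asg$complex) > 0)
})

test_that("subcluster element counts always sum to the supercluster size", {
  sim <- generate_collections(sim_config(seed = 4, background_proteins = 80L,
                                         n_complexes = 4L))
  res <- profclust(sim$datasets, sim$orthologies,
                   params = profclust_params(top_fraction = 0.05))
  for (sc in res$superclusters) {
    expect_identical(sum(vapply(sc$subclusters,
                                function(s) length(s$elements), 1L)),
                     length(sc$elements))
    expect_true(sc$coherence >= 0 && sc$coherence <= 1)
    expect_lte(sc$actual_matches, sc$possible_matches)
    frc <- unlist(lapply(sc$subclusters, function(s) s$members))
    expect_true(all(frc > 0 & frc <= 1))
  }
})
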