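# Independent oracles, deliberately naive: they recompute quantities by
# direct enumeration so the package's optimised paths can be checked
# against them.

# Truncated RBO by explicit prefix-overlap enumeration. `mapping` is a
# named character vector translating b-identifiers into a's namespace.
rbo_bruteforce <- function(a, b, p, k, mapping = NULL) {
  if (!is.null(mapping)) {
    hit <- b %in% names(mapping)
    b[hit] <- unname(mapping[b[hit]])
    b[!hit] <- paste0("#only-b#", b[!hit])
  }
  K <- min(k, max(length(a), length(b)))
  total <- 0
  for (d in seq_len(K)) {
    ov <- length(intersect(a[seq_len(min(d, length(a)))],
                           b[seq_len(min(d, length(b)))]))
    total <- total + (1 - p) * p^(d - 1) * ov / d
  }
  total
}

# Two-pass textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive maximum-weight bipartite matching over all injective
# assignments of complexes to clusters (feasible for <= 6 complexes).
mmr_bruteforce <- function(clusters, ref, min_overlap = 0.25) {
  ncx <- length(ref)
  ncl <- length(clusters)
  om <- matrix(0, ncx, ncl)
  for (i in seq_len(ncx)) for (j in seq_len(ncl))
    if (length(clusters[[j]]))
      om[i, j] <- overlap_score(ref[[i]], clusters[[j]])
  om[om < min_overlap] <- 0
  best <- 0
  assign_next <- function(i, used, total) {
    if (i > ncx) {
      best <<- max(best, total)
      return(invisible())
    }
    assign_next(i + 1L, used, total)  # leave complex i unmatched
    for (j in seq_len(ncl)) {
      if (!used[j] && om[i, j] > 0) {
        used[j] <- TRUE
        assign_next(i + 1L, used, total + om[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, ncl), 0)
  best / ncx
}

# Random symmetric interaction matrix with named proteins.
random_interaction_matrix <- function(n, dataset_id = "d1",
                                      collection_id = "c1",
                                      species_id = "s1", prefix = "P") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  m <- matrix(stats::runif(n * n, -1, 1), n, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2
  interaction_matrix(m, dataset_id, collection_id, species_id)
}

# Small deterministic profile dataset fixture.
toy_profiles <- function(dataset_id = "d1", collection_id = "c1",
                         species_id = "s1") {
  ab <- rbind(
    A = c(1, 2, 3, 4),
    B = c(2, 4, 6, 8),
    C = c(4, 3, 2, 1),
    D = c(1, 3, 2, 4))
  colnames(ab) <- paste0("f", 1:4)
  profile_dataset(ab, dataset_id, collection_id, species_id)
}
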