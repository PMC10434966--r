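## Interactor profiles and rank-biased overlap (RBO).
##
## Each protein's interactor profile is the list of all other proteins in
## its dataset ranked by interaction score. Two profiles are compared with
## the truncated (non-extrapolated) RBO: rank d carries weight
## (1-p) p^(d-1) and contributes that weight times the prefix-overlap
## fraction A_d = |top-d(A) n top-d(B)| / d. Orthologous proteins count as
## common elements when the profiles come from different species.

#' Pearson correlation interaction matrix of a profile dataset
#'
#' Computes Pearson's correlation between every pair of migration profiles
#' (rows of the abundance matrix). Proteins with zero variance across
#' fractions have no defined correlation; their rows/columns are `NA` and
#' they are excluded from interactor rankings.
#'
#' @param ds a [profile_dataset()].
#' @return An [interaction_matrix()] over the same proteins.
#' @export
correlation_matrix <- function(ds) {
  stopifnot(inherits(ds, "profile_dataset"))
  if (ncol(ds$abundances) < 2L)
    stop("correlation needs at least 2 fractions", call. = FALSE)
  sc <- suppressWarnings(stats::cor(t(ds$abundances)))
  v <- apply(ds$abundances, 1L, stats::var)
  flat <- v == 0
  sc[flat, ] <- NA_real_
  sc[, flat] <- NA_real_
  interaction_matrix(sc, ds$dataset_id, ds$collection_id, ds$species_id)
}

#' Rank a protein's interactors
#'
#' Orders all other proteins of the dataset by interaction score,
#' descending. Ties are broken by identifier (C-locale lexicographic,
#' ascending) so rankings are deterministic. Proteins with undefined
#' scores (`NA`) are excluded.
#'
#' @param m an [interaction_matrix()].
#' @param protein protein identifier present in `m`.
#' @return An object of class `interactor_profile`: list with `owner`
#'   (`dataset_id`, `protein`), `ranked` (identifiers, best first) and
#'   `scores` (parallel numeric vector, non-increasing).
#' @export
rank_interactors <- function(m, protein) {
  stopifnot(inherits(m, "interaction_matrix"))
  if (!protein %in% m$proteins)
    stop("protein not in dataset ", m$dataset_id, ": ", protein,
         call. = FALSE)
  s <- m$scores[protein, ]
  s <- s[names(s) != protein]
  s <- s[!is.na(s)]
  o <- order(-s, names(s), method = "radix")
  structure(
    list(owner = c(dataset_id = m$dataset_id, protein = protein),
         ranked = names(s)[o], scores = unname(s[o])),
    class = "interactor_profile")
}

# Ranked interactor lists for every protein of a dataset, truncated to
# `keep` ranks (full profile lengths are retained in `len`). Used by the
# all-pairs similarity stage; single-profile access goes through
# rank_interactors().
ranked_lists <- function(m, keep = Inf) {
  n <- length(m$proteins)
  lists <- vector("list", n)
  names(lists) <- m$proteins
  len <- integer(n)
  names(len) <- m$proteins
  for (i in seq_len(n)) {
    p <- m$proteins[i]
    s <- m$scores[p, ]
    s <- s[names(s) != p]
    s <- s[!is.na(s)]
    o <- order(-s, names(s), method = "radix")
    len[i] <- length(o)
    lists[[i]] <- names(s)[o][seq_len(min(length(o), keep))]
  }
  list(ranked = lists, len = len)
}

#' Evaluation depth implied by the RBO weight distribution
#'
#' Rank d of an RBO comparison carries weight \eqn{(1-p)p^{d-1}}. The
#' evaluation depth is the smallest k whose ranks jointly carry at least
#' `coverage` of the total weight, i.e. the smallest k with
#' \eqn{1 - p^k \ge} `coverage`. Lower ranks are ignored, bounding the
#' cost of each comparison with negligible effect on the score.
#'
#' @param p top-heaviness parameter, in (0,1).
#' @param coverage cumulative weight to retain, in (0,1); default 0.99.
#' @return Integer depth k (at least 1).
#' @export
rbo_depth <- function(p, coverage = 0.99) {
  stopifnot(p > 0, p < 1, coverage > 0, coverage < 1)
  k <- max(1L, as.integer(ceiling(log(1 - coverage) / log(p)) + 1e-9))
  # guard against floating point at the boundary
  while (1 - p^k < coverage) k <- k + 1L
  while (k > 1L && 1 - p^(k - 1L) >= coverage) k <- k - 1L
  k
}

# Weight tail sums used by the truncated RBO: C[m] = sum_{d=m..k} w_d / d
# with w_d = (1-p) p^(d-1), plus a trailing 0 so C[K+1] is defined for any
# evaluation depth K <= k. A common element with ranks (ra, rb) contributes
# C[max(ra, rb)] - C[K+1] to the score.
rbo_tail_weights <- function(p, k) {
  d <- seq_len(k)
  w <- (1 - p) * p^(d - 1)
  c(rev(cumsum(rev(w / d))), 0)
}

# Core truncated-RBO kernel on two already-mapped ranked identifier vectors.
# la/lb may be pre-truncated to k; lena/lenb are the full profile lengths.
rbo_kernel <- function(la, lb, lena, lenb, C, k) {
  K <- min(k, max(lena, lenb))
  if (K < 1L) return(0)
  if (length(la) > K) la <- la[seq_len(K)]
  if (length(lb) > K) lb <- lb[seq_len(K)]
  rb <- match(la, lb)
  ok <- which(!is.na(rb))
  if (!length(ok)) return(0)
  m <- pmax(ok, rb[ok])
  sum(C[m]) - length(ok) * C[K + 1L]
}

#' Rank-biased overlap between two ranked lists
#'
#' Truncated (non-extrapolated) RBO: \eqn{\sum_{d=1}^{K} (1-p) p^{d-1}
#' A_d} where \eqn{A_d} is the fraction of the top-d prefixes shared by the
#' two lists and K is the evaluation depth (`k`, capped at the longer
#' list's length, so two identical lists of length L < k score exactly
#' \eqn{1 - p^L}). No extrapolation or residual correction is applied, so
#' scores live in [0, 1).
#'
#' When the lists come from different species, a translation table maps
#' list-b identifiers into list-a's namespace: orthologous proteins count
#' as common elements, unmapped proteins as unique to their list.
#'
#' @param a,b character vectors: ranked identifiers, best first, or
#'   `interactor_profile` objects.
#' @param p top-heaviness parameter in (0,1); default 0.9.
#' @param coverage cumulative weight retained when `k` is derived; see
#'   [rbo_depth()].
#' @param k evaluation depth; defaults to `rbo_depth(p, coverage)`.
#' @param mapping `NULL` for a shared namespace (identity), or a named
#'   character vector translating `b` identifiers to `a`'s namespace (e.g.
#'   from [orthology_lookup()]).
#' @return RBO score in [0, 1).
#' @export
rbo_score <- function(a, b, p = 0.9, coverage = 0.99,
                      k = rbo_depth(p, coverage), mapping = NULL) {
  if (inherits(a, "interactor_profile")) a <- a$ranked
  if (inherits(b, "interactor_profile")) b <- b$ranked
  a <- as.character(a); b <- as.character(b)
  stopifnot(p > 0, p < 1, k >= 1)
  if (!is.null(mapping)) b <- map_to_namespace(b, mapping)
  C <- rbo_tail_weights(p, k)
  rbo_kernel(a, b, length(a), length(b), C, k)
}

# Translate identifiers through a one-to-one map; identifiers without an
# entry are replaced by sentinel tokens ("\r" prefix) that cannot collide
# with real identifiers in the target namespace.
map_to_namespace <- function(ids, mapping) {
  out <- unname(mapping[ids])
  miss <- is.na(out)
  out[miss] <- paste0("\r", ids[miss])
  out
}
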