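## Cross-dataset comparison: all-pairs interactor-profile similarity,
## reciprocal top-hit selection, per-pair mean normalization, and assembly
## of the combined hypernetwork whose nodes are (dataset, protein)
## elements.

#' All-pairs interactor-profile similarity between two datasets
#'
#' Computes the RBO similarity between the interactor profiles of every
#' protein of dataset A and every protein of dataset B. For a
#' cross-species pair the orthology map defines which interactors count as
#' common; for a same-species pair identifiers are compared directly.
#'
#' @param ma,mb [interaction_matrix()] objects for the two datasets.
#' @param mapping `NULL` (same species, identity) or an [orthology_map()]
#'   covering the two species.
#' @param p,coverage RBO parameters; see [rbo_score()].
#' @return Numeric matrix of RBO scores, rows = proteins of `ma`, columns
#'   = proteins of `mb`.
#' @export
pairwise_interactor_similarity <- function(ma, mb, mapping = NULL,
                                           p = 0.9, coverage = 0.99) {
  stopifnot(inherits(ma, "interaction_matrix"),
            inherits(mb, "interaction_matrix"))
  if (ma$species_id != mb$species_id) {
    if (is.null(mapping))
      stop(sprintf("datasets %s/%s are from different species (%s/%s); %s",
                   ma$dataset_id, mb$dataset_id, ma$species_id,
                   mb$species_id, "an orthology map is required"),
           call. = FALSE)
    lut <- orthology_lookup(mapping, mb$species_id)  # b ids -> a namespace
  } else {
    lut <- NULL
  }
  k <- rbo_depth(p, coverage)
  C <- rbo_tail_weights(p, k)
  ra <- ranked_lists(ma, keep = k)
  rb <- ranked_lists(mb, keep = k)
  lb <- rb$ranked
  if (!is.null(lut)) lb <- lapply(lb, map_to_namespace, mapping = lut)
  la <- ra$ranked
  na <- length(la); nb <- length(lb)
  out <- matrix(0, na, nb, dimnames = list(ma$proteins, mb$proteins))
  if (na == 0L || nb == 0L) return(out)
  # integer-code all tokens once so the per-row matching is cheap
  tokens <- unique(c(unlist(la, use.names = FALSE),
                     unlist(lb, use.names = FALSE)))
  la_i <- lapply(la, match, tokens)
  lb_len <- lengths(lb)
  lb_flat <- match(unlist(lb, use.names = FALSE), tokens)
  grp <- rep.int(seq_len(nb), lb_len)          # which B list a token is in
  rb_rank <- sequence(lb_len)                  # its rank there
  for (i in seq_len(na)) {
    # per-pair evaluation depth K: k capped at the longer full profile
    K <- pmin(k, pmax(ra$len[[i]], rb$len))
    ra_rank <- match(lb_flat, la_i[[i]])
    ok <- which(!is.na(ra_rank))
    if (!length(ok)) next
    m <- pmax(ra_rank[ok], rb_rank[ok])
    g <- grp[ok]
    keep <- m <= K[g]
    m <- m[keep]; g <- g[keep]
    if (!length(m)) next
    sums <- rowsum(C[m], g)
    cnts <- rowsum(rep(1, length(g)), g)
    j <- as.integer(rownames(sums))
    out[i, j] <- sums - cnts * C[K[j] + 1L]
  }
  out
}

#' Select reciprocal top hits from a pairwise score table
#'
#' A protein pair (a, b) is kept only if its score lies in the top
#' `fraction` of a's scores against dataset B *and* in the top `fraction`
#' of b's scores against dataset A. The per-protein cutoff is the
#' `ceiling(fraction * n_opposite)`-th largest score; ties at the cutoff
#' value are kept. Scores of exactly 0 are never edges.
#'
#' @param scores numeric matrix from [pairwise_interactor_similarity()].
#' @param fraction top fraction retained per protein, in (0,1]; default
#'   0.01 (top 1 percent).
#' @return Logical matrix of the same shape marking retained pairs.
#' @export
select_reciprocal_top_hits <- function(scores, fraction = 0.01) {
  stopifnot(is.matrix(scores), fraction > 0, fraction <= 1)
  nr <- nrow(scores); nc <- ncol(scores)
  if (nr == 0L || nc == 0L) return(scores > 0)
  kr <- min(nc, as.integer(ceiling(fraction * nc)))  # hits kept per row
  kc <- min(nr, as.integer(ceiling(fraction * nr)))  # hits kept per column
  row_thr <- apply(scores, 1L, function(x) sort(x, decreasing = TRUE)[kr])
  col_thr <- apply(scores, 2L, function(x) sort(x, decreasing = TRUE)[kc])
  keep <- (scores >= row_thr) & (scores >= rep(col_thr, each = nr)) &
    (scores > 0)
  keep
}

# Assemble the retained pairs of one dataset pair into an edge set.
edge_set <- function(scores, keep, dataset_a, dataset_b) {
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    from = element_id(dataset_a, rownames(scores)[idx[, 1L]]),
    to = element_id(dataset_b, colnames(scores)[idx[, 2L]]),
    weight = scores[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(dataset_pair = c(dataset_a, dataset_b), edges = edges),
            class = "edge_set")
}

#' Normalize per-pair edge weights to a common mean
#'
#' Datasets differ in size and in how many proteins they share, so raw
#' RBO scores are not comparable across dataset pairs. Each pair's
#' retained edge weights are therefore rescaled multiplicatively so that
#' every pair's mean weight is 1, preserving the order within a pair.
#'
#' @param edge_sets list of `edge_set` objects (one per dataset pair).
#' @return The same list with rescaled weights; empty sets pass through.
#' @export
normalize_pair_scores <- function(edge_sets) {
  lapply(edge_sets, function(es) {
    stopifnot(inherits(es, "edge_set"))
    if (nrow(es$edges) == 0L) return(es)
    m <- mean(es$edges$weight)
    if (m <= 0)
      stop("cannot normalize edge set ",
           paste(es$dataset_pair, collapse = "/"),
           ": mean weight is not positive", call. = FALSE)
    es$edges$weight <- es$edges$weight / m
    es
  })
}

#' Assemble normalized edge sets into the combined hypernetwork
#'
#' Nodes are `dataset_id::protein` elements; edges are the union of all
#' per-pair edge sets. Detected proteins without any surviving edge are
#' excluded from the network but reported.
#'
#' @param edge_sets list of normalized `edge_set` objects.
#' @param datasets optional list of the input datasets, used to report
#'   isolated (edge-less) elements.
#' @return Object of class `hypernetwork`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `weight`) and `isolated`.
#' @export
build_hypernetwork <- function(edge_sets, datasets = NULL) {
  tabs <- lapply(edge_sets, function(es) {
    stopifnot(inherits(es, "edge_set"))
    es$edges
  })
  edges <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key))
      stop("duplicate edges across edge sets; each dataset pair must be ",
           "compared once", call. = FALSE)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("hypernetwork edge weights must be finite and positive",
           call. = FALSE)
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  isolated <- character()
  if (!is.null(datasets)) {
    all_el <- unlist(lapply(datasets, function(d)
      element_id(d$dataset_id, d$proteins)), use.names = FALSE)
    isolated <- sort(setdiff(all_el, nodes))
  }
  structure(list(nodes = nodes, edges = edges, isolated = isolated),
            class = "hypernetwork")
}
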