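## Reference-based evaluation: pruning of a reference complex set to what
## the data can support, the squared-overlap score, and the maximum
## matching ratio (MMR) between result clusters and reference complexes.

#' Count in how many datasets of a collection each protein was detected
#'
#' @param datasets list of datasets (profiles or score matrices).
#' @param collection_id collection whose datasets are counted; `NULL`
#'   counts across all datasets.
#' @return Named integer vector: protein -> number of datasets listing it.
#' @export
detection_counts <- function(datasets, collection_id = NULL) {
  if (!is.null(collection_id))
    datasets <- Filter(function(d) d$collection_id == collection_id, datasets)
  prot <- unlist(lapply(datasets, `[[`, "proteins"), use.names = FALSE)
  tab <- table(prot)
  stats::setNames(as.integer(tab), names(tab))
}

#' Prune a reference complex set against the analysed data
#'
#' Applies, in order: removal of duplicate complexes (identical member
#' sets), removal of complexes that are proper subsets of another complex
#' (sub-assemblies), removal of member proteins detected in fewer than
#' `min_detected` datasets, and removal of complexes left with fewer than
#' `min_size` members.
#'
#' @param ref a [reference_complexes()] set.
#' @param detected named integer vector of per-protein detection counts
#'   (see [detection_counts()]).
#' @param min_detected minimum datasets a protein must be detected in;
#'   default 2.
#' @param min_size minimum complex size after pruning; default 3 (drops
#'   complexes of two or fewer proteins).
#' @return A pruned [reference_complexes()] set.
#' @export
process_reference_set <- function(ref, detected, min_detected = 2L,
                                  min_size = 3L) {
  stopifnot(inherits(ref, "reference_complexes"))
  sets <- lapply(unclass(ref), function(x) sort(unique(x)))
  # 1. deduplicate identical member sets (first name wins)
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets <- sets[!duplicated(keys)]
  # 2. drop proper subsets of other complexes
  nm <- names(sets)
  is_sub <- vapply(seq_along(sets), function(i) {
    any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, TRUE))
  }, TRUE)
  sets <- sets[!is_sub]
  # 3. drop insufficiently detected proteins
  cnt <- function(p) {
    x <- detected[p]
    x[is.na(x)] <- 0L
    x
  }
  sets <- lapply(sets, function(x) x[cnt(x) >= min_detected])
  # 4. drop complexes that became too small
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  reference_complexes(sets)
}

#' Squared-overlap score between two protein sets
#'
#' \eqn{\omega(A, B) = |A \cap B|^2 / (|A| |B|)}: 1 iff the sets are
#' identical, 0 iff disjoint.
#'
#' @param a,b character vectors of protein identifiers; `a` must be
#'   nonempty.
#' @return Overlap score in [0, 1].
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a)) stop("overlap_score: first set is empty", call. = FALSE)
  if (!length(b)) return(0)
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Maximum matching ratio between clusters and a reference
#'
#' Builds the bipartite graph of reference complexes versus clusters with
#' edge weights \eqn{\omega} = squared overlap, keeping edges with
#' \eqn{\omega \ge} `min_overlap`, computes the maximum-weight matching
#' (each complex and each cluster used at most once), and divides the
#' matched weight by the number of reference complexes.
#'
#' @param clusters list of character vectors (cluster member sets, e.g.
#'   per-collection subcluster proteins).
#' @param ref a (processed) [reference_complexes()] set.
#' @param min_overlap minimum \eqn{\omega} for a candidate pairing;
#'   default 0.25.
#' @return List of class `matching_result`: `mmr`, and `assignment`, a
#'   data frame with one row per matched complex (`complex`,
#'   `cluster`, `omega`).
#' @export
maximum_matching_ratio <- function(clusters, ref, min_overlap = 0.25) {
  stopifnot(inherits(ref, "reference_complexes"))
  ncx <- length(ref)
  ncl <- length(clusters)
  empty <- data.frame(complex = character(), cluster = integer(),
                      omega = numeric(), stringsAsFactors = FALSE)
  if (ncx == 0L)
    return(structure(list(mmr = 0, assignment = empty),
                     class = "matching_result"))
  keep <- vapply(clusters, length, 1L) > 0L
  om <- matrix(0, ncx, ncl)
  for (i in seq_len(ncx)) {
    for (j in seq_len(ncl)) {
      if (keep[j]) om[i, j] <- overlap_score(ref[[i]], clusters[[j]])
    }
  }
  om[om < min_overlap] <- 0
  idx <- which(om > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(structure(list(mmr = 0, assignment = empty),
                     class = "matching_result"))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ncx), rep(TRUE, ncl)),
    edges = as.vector(t(cbind(idx[, 1L], ncx + idx[, 2L]))))
  igraph::E(g)$weight <- om[idx]
  mt <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  matched <- mt$matching[seq_len(ncx)]
  rows <- list()
  total <- 0
  for (i in seq_len(ncx)) {
    v <- matched[i]
    if (is.na(v)) next
    j <- as.integer(v) - ncx
    w <- om[i, j]
    total <- total + w
    rows[[length(rows) + 1L]] <- data.frame(
      complex = names(ref)[i], cluster = j, omega = w,
      stringsAsFactors = FALSE)
  }
  assignment <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(mmr = total / ncx, assignment = assignment),
            class = "matching_result")
}

#' Jaccard recovery of a known complex by a selected member set
#'
#' True positives over true positives + false positives + false
#' negatives, i.e. \eqn{|S \cap K| / |S \cup K|} for selected set S and
#' known (detected) complex members K.
#'
#' @param selected character vector of selected proteins.
#' @param known character vector of known complex members detected in the
#'   data.
#' @return Jaccard index in [0, 1]; 0 when both sets are empty.
#' @export
recovery_jaccard <- function(selected, known) {
  selected <- unique(selected); known <- unique(known)
  u <- union(selected, known)
  if (!length(u)) return(0)
  length(intersect(selected, known)) / length(u)
}

#' Evaluate a clustering result against a reference complex set
#'
#' Prunes the reference against the reference collection's detection
#' counts ([process_reference_set()]) and computes the maximum matching
#' ratio of that collection's subcluster member sets against it.
#'
#' @param result a `profclust` result object.
#' @param ref a [reference_complexes()] set.
#' @param reference_collection collection the reference describes.
#' @param selection `"clustered"` (all clustered proteins of the
#'   collection per cluster; default) or `"best_guess"`.
#' @param min_overlap,min_detected,min_size passed through to
#'   [maximum_matching_ratio()] and [process_reference_set()].
#' @return A `matching_result` with the processed reference attached as
#'   attribute `reference`.
#' @export
evaluate_reference <- function(result, ref, reference_collection,
                               selection = c("clustered", "best_guess"),
                               min_overlap = 0.25, min_detected = 2L,
                               min_size = 3L) {
  stopifnot(inherits(result, "profclust"))
  selection <- match.arg(selection)
  det <- detection_counts(result$datasets, reference_collection)
  pref <- process_reference_set(ref, det, min_detected, min_size)
  clusters <- lapply(result$superclusters, function(sc) {
    s <- sc$subclusters[[reference_collection]]
    if (is.null(s)) return(character())
    if (selection == "clustered") names(s$members) else s$best_guess
  })
  res <- maximum_matching_ratio(clusters, pref, min_overlap)
  attr(res, "reference") <- pref
  res
}
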