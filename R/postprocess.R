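## Post-processing of raw MCL clusters: split superclusters into
## per-collection subclusters, score proteins with the fraction-clustered
## (FrC) statistic, select best-guess members, count equivalent-element
## matches, compute coherence, filter, and annotate against a reference
## complex set.

# dataset_index: lookup tables from dataset id to collection / species.
dataset_index <- function(datasets) {
  ds <- vapply(datasets, `[[`, "", "dataset_id")
  list(
    collection = stats::setNames(vapply(datasets, `[[`, "", "collection_id"), ds),
    species = stats::setNames(vapply(datasets, `[[`, "", "species_id"), ds))
}

#' Split a raw cluster's elements by collection
#'
#' @param elements character vector of `dataset_id::protein` element ids.
#' @param index dataset index (internal) or list of datasets.
#' @return Named list: collection id -> element ids.
#' @export
split_supercluster <- function(elements, index) {
  if (!is.list(index) || is.null(index$collection)) index <- dataset_index(index)
  ds <- element_dataset(elements)
  unknown <- setdiff(unique(ds), names(index$collection))
  if (length(unknown))
    stop("elements reference unknown dataset(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sp <- split(elements, index$collection[ds])
  lapply(sp, sort)
}

#' Fraction-clustered (FrC) score of a subcluster's proteins
#'
#' For each unique protein among one collection's elements of a cluster,
#' the number of the collection's datasets contributing it to the cluster
#' divided by the collection's *total* dataset count. A protein absent
#' from a dataset counts as lack of evidence, not as a smaller
#' denominator: a protein clustered in 3 of a collection's 4 datasets has
#' FrC 3/4 even if it was detected in fewer.
#'
#' @param elements element ids of one collection within one cluster.
#' @param n_datasets the collection's total dataset count (FrC
#'   denominator).
#' @return Named numeric vector: protein -> FrC in (0, 1].
#' @export
fraction_clustered <- function(elements, n_datasets) {
  stopifnot(n_datasets >= 1)
  if (!length(elements)) return(stats::setNames(numeric(), character()))
  prot <- element_protein(elements)
  cnt <- table(prot)
  frc <- as.numeric(cnt) / n_datasets
  stats::setNames(frc, names(cnt))[order(names(cnt), method = "radix")]
}

# Equivalence lookup between two datasets' protein namespaces: returns a
# named vector translating dataset-a proteins into dataset-b's namespace,
# or NULL for the identity (same species).
equivalence_lookup <- function(species_a, species_b, orthologies) {
  if (species_a == species_b) return(NULL)
  m <- find_orthology(orthologies, species_a, species_b)
  orthology_lookup(m, species_a)
}

#' Count equivalent-element matches within a supercluster
#'
#' A match is a pair of equivalent elements from two different datasets in
#' the same cluster: the same protein for two datasets of one species, or
#' a one-to-one orthologous pair across species. For a dataset pair
#' contributing n and k elements, at most min(n, k) matches are possible;
#' totals sum over all unordered dataset pairs represented in the cluster.
#'
#' @param elements the supercluster's element ids.
#' @param index list of datasets or an internal dataset index.
#' @param orthologies list of [orthology_map()] objects (cross-species
#'   pairs only).
#' @return List with `actual`, `possible` (integer totals) and `pairs`, a
#'   data frame with per-dataset-pair counts (`dataset_a`, `dataset_b`,
#'   `actual`, `possible`).
#' @export
count_matches <- function(elements, index, orthologies = list()) {
  if (!is.list(index) || is.null(index$collection)) index <- dataset_index(index)
  ds <- element_dataset(elements)
  prot <- element_protein(elements)
  by_ds <- split(prot, ds)
  ids <- sort(names(by_ds))
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        pa <- by_ds[[ids[i]]]; pb <- by_ds[[ids[j]]]
        lut <- equivalence_lookup(index$species[[ids[i]]],
                                  index$species[[ids[j]]], orthologies)
        translated <- if (is.null(lut)) pa else unname(lut[pa])
        actual <- sum(!is.na(translated) & translated %in% pb)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = ids[i], dataset_b = ids[j],
          actual = actual, possible = min(length(pa), length(pb)),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset_a = character(), dataset_b = character(),
               actual = integer(), possible = integer(),
               stringsAsFactors = FALSE)
  list(actual = sum(pairs$actual), possible = sum(pairs$possible),
       pairs = pairs)
}

#' Cluster coherence score
#'
#' The fraction of possible matches realised in a cluster: total actual
#' matches divided by total possible matches (0 when no match is
#' possible).
#'
#' @param actual,possible non-negative match counts.
#' @return Coherence in [0, 1].
#' @export
coherence_score <- function(actual, possible) {
  stopifnot(actual >= 0, possible >= 0, actual <= possible || possible == 0)
  if (possible == 0) return(0)
  actual / possible
}

#' Aggregate per-dataset-pair match counts into a coherence score
#'
#' @param pairs data frame with columns `actual` and `possible`, one row
#'   per dataset pair (as produced by [count_matches()]).
#' @return Coherence: sum of actual over sum of possible matches.
#' @export
coherence_from_pairs <- function(pairs) {
  coherence_score(sum(pairs$actual), sum(pairs$possible))
}

#' Per-collection (subcluster) coherence
#'
#' Restricts the match-count aggregation to dataset pairs in which at
#' least one dataset belongs to the named collection, reflecting how
#' coherent the cluster is in that specific system while retaining its
#' cross-system evidence.
#'
#' @param pairs per-pair match counts from [count_matches()].
#' @param collection_id the collection of interest.
#' @param index dataset index or list of datasets.
#' @return Coherence in [0, 1]; 0 if the collection is absent.
#' @export
subcluster_coherence <- function(pairs, collection_id, index) {
  if (!is.list(index) || is.null(index$collection)) index <- dataset_index(index)
  inc <- index$collection[pairs$dataset_a] == collection_id |
    index$collection[pairs$dataset_b] == collection_id
  if (!any(inc)) return(0)
  coherence_from_pairs(pairs[inc, , drop = FALSE])
}

# Best-guess member selection for every subcluster of one supercluster.
# sub_frc: named list collection -> FrC vector; coll_species: named vector
# collection -> species.
best_guess_sets <- function(sub_frc, coll_species, orthologies,
                            threshold = 0.5) {
  colls <- names(sub_frc)
  out <- vector("list", length(colls))
  names(out) <- colls
  for (ci in colls) {
    frc <- sub_frc[[ci]]
    keep <- names(frc)[frc > threshold]
    low <- setdiff(names(frc), keep)
    if (length(low)) {
      for (cj in setdiff(colls, ci)) {
        frc_j <- sub_frc[[cj]]
        high_j <- names(frc_j)[frc_j > threshold]
        if (!length(high_j)) next
        lut <- equivalence_lookup(coll_species[[ci]], coll_species[[cj]],
                                  orthologies)
        translated <- if (is.null(lut)) low else unname(lut[low])
        hit <- !is.na(translated) & translated %in% high_j
        keep <- union(keep, low[hit])
      }
    }
    out[[ci]] <- sort(keep)
  }
  out
}

#' Process raw MCL clusters into scored superclusters
#'
#' For every raw cluster: splits it into per-collection subclusters,
#' scores each protein with FrC, selects best-guess members (FrC above
#' `best_guess_threshold`, plus lower-scoring proteins whose equivalent in
#' another subcluster of the same supercluster exceeds it), counts
#' equivalent-element matches, derives supercluster and per-collection
#' coherence, and applies the retention filter (at least `min_matches`
#' matches and at least one protein with FrC >= `min_frc`). Non-passing
#' clusters are retained but flagged.
#'
#' @param clusters list of element-id vectors from [run_mcl()].
#' @param datasets the input datasets (for collection/species lookup).
#' @param orthologies list of [orthology_map()] objects.
#' @param min_matches,min_frc retention filter thresholds (defaults 2 and
#'   0.5, the latter inclusive).
#' @param best_guess_threshold strict FrC threshold for best-guess
#'   membership (default 0.5).
#' @return List of `supercluster` objects.
#' @export
process_clusters <- function(clusters, datasets, orthologies = list(),
                             min_matches = 2L, min_frc = 0.5,
                             best_guess_threshold = 0.5) {
  index <- dataset_index(datasets)
  colls <- collection_table(datasets)
  coll_species <- stats::setNames(colls$species_id, colls$collection_id)
  n_ds <- stats::setNames(colls$n_datasets, colls$collection_id)
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    el <- clusters[[ci]]
    sub_el <- split_supercluster(el, index)
    sub_frc <- lapply(names(sub_el), function(cc)
      fraction_clustered(sub_el[[cc]], n_ds[[cc]]))
    names(sub_frc) <- names(sub_el)
    bg <- best_guess_sets(sub_frc, coll_species, orthologies,
                          best_guess_threshold)
    mm <- count_matches(el, index, orthologies)
    coh <- coherence_score(mm$actual, mm$possible)
    sub_coh <- vapply(names(sub_el), function(cc)
      subcluster_coherence(mm$pairs, cc, index), 0)
    max_frc <- if (length(sub_frc)) max(unlist(sub_frc)) else 0
    passed <- mm$actual >= min_matches && max_frc >= min_frc
    subclusters <- lapply(names(sub_el), function(cc)
      list(collection_id = cc, elements = sub_el[[cc]],
           members = sub_frc[[cc]], best_guess = bg[[cc]],
           coherence = unname(sub_coh[[cc]])))
    names(subclusters) <- names(sub_el)
    out[[ci]] <- structure(
      list(cluster_id = ci, elements = sort(el), subclusters = subclusters,
           actual_matches = mm$actual, possible_matches = mm$possible,
           pair_matches = mm$pairs, coherence = coh,
           passed_filter = passed, annotation = character()),
      class = "supercluster")
  }
  out
}

#' Annotate superclusters with reference complexes
#'
#' For each reference complex, finds the supercluster whose subcluster of
#' the reference collection contains the most complex members; the
#' cluster is annotated with the complex name if it holds strictly more
#' than `min_fraction` of the complex (ties between clusters broken by
#' larger contained count, then smaller cluster size, then cluster id).
#' Each reference complex annotates at most one cluster.
#'
#' @param superclusters list from [process_clusters()].
#' @param ref a [reference_complexes()] set in the reference collection's
#'   namespace.
#' @param reference_collection collection id whose subclusters the
#'   reference describes.
#' @param min_fraction strict lower bound on the contained fraction of a
#'   complex; default 0.5 ("more than half").
#' @return The superclusters, with `annotation` fields filled; attribute
#'   `assignments` holds a data frame complex -> cluster.
#' @export
annotate_with_reference <- function(superclusters, ref,
                                    reference_collection,
                                    min_fraction = 0.5) {
  stopifnot(inherits(ref, "reference_complexes"))
  members <- lapply(superclusters, function(sc) {
    s <- sc$subclusters[[reference_collection]]
    if (is.null(s)) character() else names(s$members)
  })
  sizes <- vapply(superclusters, function(sc) length(sc$elements), 1L)
  rows <- list()
  for (nm in names(ref)) {
    cx <- ref[[nm]]
    contained <- vapply(members, function(m) length(intersect(cx, m)), 1L)
    if (all(contained == 0L)) next
    ord <- order(-contained, sizes, seq_along(superclusters))
    best <- ord[1L]
    if (contained[best] / length(cx) > min_fraction) {
      rows[[length(rows) + 1L]] <- data.frame(
        complex = nm, cluster_id = superclusters[[best]]$cluster_id,
        contained = contained[best], complex_size = length(cx),
        stringsAsFactors = FALSE)
      superclusters[[best]]$annotation <-
        c(superclusters[[best]]$annotation, nm)
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex = character(), cluster_id = integer(),
               contained = integer(), complex_size = integer(),
               stringsAsFactors = FALSE)
  attr(superclusters, "assignments") <- assignments
  superclusters
}
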