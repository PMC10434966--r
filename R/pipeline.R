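## End-to-end orchestration: correlation -> interactor-profile RBO ->
## reciprocal top hits -> per-pair normalization -> Markov clustering ->
## supercluster post-processing -> optional reference evaluation.

#' Analysis parameter set
#'
#' Collects every tunable parameter of the comparative clustering
#' pipeline with its default.
#'
#' @param p RBO top-heaviness; default 0.9.
#' @param coverage cumulative RBO weight retained when choosing the
#'   evaluation depth; default 0.99.
#' @param top_fraction reciprocal top-hit fraction; default 0.01.
#' @param inflation,expansion,prune,max_iter,tol MCL parameters; see
#'   [mcl_params()].
#' @param min_matches,min_frc cluster retention filter; defaults 2
#'   matches and FrC 0.5 (inclusive).
#' @param best_guess_threshold strict FrC threshold for best-guess
#'   membership; default 0.5.
#' @param annotation_threshold strict contained-fraction threshold for
#'   reference annotation; default 0.5.
#' @param mmr_min_overlap minimum squared-overlap for MMR candidate
#'   pairings; default 0.25.
#' @return List of class `profclust_params`.
#' @export
profclust_params <- function(p = 0.9, coverage = 0.99, top_fraction = 0.01,
                             inflation = 2, expansion = 2L, prune = 1e-5,
                             max_iter = 100L, tol = 1e-8,
                             min_matches = 2L, min_frc = 0.5,
                             best_guess_threshold = 0.5,
                             annotation_threshold = 0.5,
                             mmr_min_overlap = 0.25) {
  stopifnot(p > 0, p < 1, coverage > 0, coverage < 1,
            top_fraction > 0, top_fraction <= 1,
            min_matches >= 0, min_frc >= 0, min_frc <= 1)
  structure(list(
    p = p, coverage = coverage, top_fraction = top_fraction,
    mcl = mcl_params(inflation, expansion, prune, max_iter, tol),
    min_matches = as.integer(min_matches), min_frc = min_frc,
    best_guess_threshold = best_guess_threshold,
    annotation_threshold = annotation_threshold,
    mmr_min_overlap = mmr_min_overlap), class = "profclust_params")
}

#' Comparative clustering of co-fractionation interaction datasets
#'
#' Runs the full analysis: Pearson correlation of migration profiles
#' (profile inputs only; precomputed score matrices are used as-is),
#' orthology-aware rank-biased overlap between the interactor profiles of
#' every cross-dataset protein pair, reciprocal top-hit selection,
#' per-dataset-pair mean normalization, Markov clustering of the combined
#' hypernetwork, and post-processing into scored, filtered, annotated
#' superclusters with per-collection subclusters.
#'
#' @param datasets list of [profile_dataset()] and/or
#'   [interaction_matrix()] objects. Datasets of one collection must share
#'   one identifier namespace; datasets of one species are compared by
#'   identifier, cross-species pairs through `orthologies`.
#' @param orthologies list of [orthology_map()] objects, one per species
#'   pair present (checked up front).
#' @param params a [profclust_params()] set.
#' @param reference optional [reference_complexes()] set for annotation
#'   and evaluation.
#' @param reference_collection collection id the reference describes
#'   (required with `reference`).
#' @return Object of class `profclust`; see [print.profclust()] and
#'   [summary.profclust()]. Components include `network` (the
#'   hypernetwork), `superclusters`, `members` (long per-protein table),
#'   `cluster_summary`, and optionally `annotation_assignments` and
#'   `evaluation`.
#' @export
profclust <- function(datasets, orthologies = list(),
                      params = profclust_params(), reference = NULL,
                      reference_collection = NULL) {
  stopifnot(inherits(params, "profclust_params"))
  if (!length(datasets)) stop("no datasets given", call. = FALSE)
  colls <- collection_table(datasets)
  if (!is.null(reference)) {
    if (is.null(reference_collection) ||
        !reference_collection %in% colls$collection_id)
      stop("reference_collection must name a collection of the input",
           call. = FALSE)
  }
  # fail fast on missing orthology before any computation
  species <- unique(colls$species_id)
  if (length(species) > 1L) {
    for (i in seq_len(length(species) - 1L))
      for (j in seq((i + 1L), length(species)))
        find_orthology(orthologies, species[i], species[j])
  }
  mats <- lapply(datasets, function(d) {
    if (inherits(d, "profile_dataset")) correlation_matrix(d)
    else if (inherits(d, "interaction_matrix")) d
    else stop("datasets must be profile_dataset or interaction_matrix ",
              "objects", call. = FALSE)
  })
  nd <- length(mats)
  edge_sets <- list()
  if (nd >= 2L) {
    for (i in seq_len(nd - 1L)) {
      for (j in seq((i + 1L), nd)) {
        ma <- mats[[i]]; mb <- mats[[j]]
        mapping <- if (ma$species_id == mb$species_id) NULL else
          find_orthology(orthologies, ma$species_id, mb$species_id)
        sc <- pairwise_interactor_similarity(ma, mb, mapping,
                                             p = params$p,
                                             coverage = params$coverage)
        keep <- select_reciprocal_top_hits(sc, params$top_fraction)
        edge_sets[[length(edge_sets) + 1L]] <-
          edge_set(sc, keep, ma$dataset_id, mb$dataset_id)
      }
    }
  }
  edge_sets <- normalize_pair_scores(edge_sets)
  net <- build_hypernetwork(edge_sets, datasets)
  clusters <- run_mcl(net, params$mcl)
  supers <- process_clusters(clusters, datasets, orthologies,
                             min_matches = params$min_matches,
                             min_frc = params$min_frc,
                             best_guess_threshold = params$best_guess_threshold)
  assignments <- NULL
  if (!is.null(reference)) {
    supers <- annotate_with_reference(supers, reference,
                                      reference_collection,
                                      params$annotation_threshold)
    assignments <- attr(supers, "assignments")
    attr(supers, "assignments") <- NULL
  }
  res <- structure(list(
    params = params, collections = colls, datasets = datasets,
    network = net, superclusters = supers,
    members = members_table(supers),
    cluster_summary = cluster_summary_table(supers),
    annotation_assignments = assignments,
    evaluation = NULL), class = "profclust")
  if (!is.null(reference)) {
    res$evaluation <- evaluate_reference(res, reference,
                                         reference_collection,
                                         min_overlap = params$mmr_min_overlap)
  }
  res
}

#' Run the pipeline from files
#'
#' Thin wrapper over [profclust()] that reads a sample sheet, loads its
#' datasets, reads all two-column orthology files of a directory
#' (`orthology_<speciesA>_<speciesB>.tsv`), and optionally a reference
#' complex file.
#'
#' @param sample_sheet path to the sample sheet (see
#'   [read_sample_sheet()]).
#' @param ortho_dir directory of orthology files; `NULL` if all datasets
#'   share one species.
#' @param reference_path optional reference complex file.
#' @param reference_collection collection the reference describes.
#' @param params a [profclust_params()] set.
#' @param out_dir if given, [write_cluster_tables()] is called on the
#'   result.
#' @return A `profclust` object.
#' @export
run_pipeline <- function(sample_sheet, ortho_dir = NULL,
                         reference_path = NULL, reference_collection = NULL,
                         params = profclust_params(), out_dir = NULL) {
  datasets <- load_samples(sample_sheet)
  orthologies <- list()
  if (!is.null(ortho_dir)) {
    files <- list.files(ortho_dir, pattern = "^orthology_.*\\.tsv$",
                        full.names = TRUE)
    orthologies <- lapply(files, function(f) {
      parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_", fixed = TRUE)[[1L]]
      if (length(parts) != 3L)
        stop("orthology file name must be orthology_<speciesA>_<speciesB>.tsv: ",
             basename(f), call. = FALSE)
      load_orthology(f, parts[2L], parts[3L])
    })
  }
  reference <- if (!is.null(reference_path))
    load_reference_complexes(reference_path) else NULL
  res <- profclust(datasets, orthologies, params, reference,
                   reference_collection)
  if (!is.null(out_dir)) write_cluster_tables(res, out_dir)
  res
}

members_table <- function(supers) {
  rows <- list()
  for (sc in supers) {
    for (s in sc$subclusters) {
      if (!length(s$members)) next
      rows[[length(rows) + 1L]] <- data.frame(
        supercluster_id = sc$cluster_id, collection_id = s$collection_id,
        protein = names(s$members), frc = unname(s$members),
        best_guess = names(s$members) %in% s$best_guess,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(supercluster_id = integer(), collection_id = character(),
               protein = character(), frc = numeric(),
               best_guess = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

cluster_summary_table <- function(supers) {
  if (!length(supers))
    return(data.frame(supercluster_id = integer(), n_elements = integer(),
                      n_subclusters = integer(), actual_matches = integer(),
                      possible_matches = integer(), coherence = numeric(),
                      passed_filter = logical(), annotation = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    supercluster_id = vapply(supers, `[[`, 1L, "cluster_id"),
    n_elements = vapply(supers, function(s) length(s$elements), 1L),
    n_subclusters = vapply(supers, function(s) length(s$subclusters), 1L),
    actual_matches = vapply(supers, `[[`, 1L, "actual_matches"),
    possible_matches = vapply(supers, `[[`, 1L, "possible_matches"),
    coherence = vapply(supers, `[[`, 1, "coherence"),
    passed_filter = vapply(supers, `[[`, TRUE, "passed_filter"),
    annotation = vapply(supers, function(s)
      paste(s$annotation, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' @rdname profclust
#' @param x,object a `profclust` result.
#' @param ... unused.
#' @method print profclust
#' @export
print.profclust <- function(x, ...) {
  cs <- x$cluster_summary
  cat("Comparative clustering of", length(x$datasets), "datasets in",
      nrow(x$collections), "collections\n")
  cat(sprintf("  hypernetwork: %d elements, %d edges (%d isolated)\n",
              length(x$network$nodes), nrow(x$network$edges),
              length(x$network$isolated)))
  cat(sprintf("  superclusters: %d (%d passed filtering)\n",
              nrow(cs), sum(cs$passed_filter)))
  if (!is.null(x$annotation_assignments))
    cat(sprintf("  annotated clusters: %d\n",
                length(unique(x$annotation_assignments$cluster_id))))
  if (!is.null(x$evaluation))
    cat(sprintf("  maximum matching ratio vs reference: %.3f\n",
                x$evaluation$mmr))
  invisible(x)
}

#' @rdname profclust
#' @method summary profclust
#' @export
summary.profclust <- function(object, ...) {
  cs <- object$cluster_summary
  structure(list(
    n_datasets = length(object$datasets),
    collections = object$collections,
    n_superclusters = nrow(cs),
    n_passed = sum(cs$passed_filter),
    n_multi = sum(cs$n_subclusters > 1L & cs$passed_filter),
    mmr = if (!is.null(object$evaluation)) object$evaluation$mmr else NA_real_,
    cluster_summary = cs), class = "summary.profclust")
}

#' @method print summary.profclust
#' @export
print.summary.profclust <- function(x, ...) {
  cat(sprintf("%d superclusters; %d passed filtering; %d multi-complexome\n",
              x$n_superclusters, x$n_passed, x$n_multi))
  if (!is.na(x$mmr)) cat(sprintf("MMR vs reference: %.3f\n", x$mmr))
  top <- x$cluster_summary[x$cluster_summary$passed_filter, , drop = FALSE]
  top <- utils::head(top[order(-top$n_elements), , drop = FALSE], 10L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Plot supercluster size against coherence
#'
#' One point per supercluster; filtered-out clusters are hollow.
#'
#' @param x a `profclust` result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.profclust <- function(x, ...) {
  cs <- x$cluster_summary
  graphics::plot(cs$n_elements, cs$coherence,
                 pch = ifelse(cs$passed_filter, 19, 1),
                 col = ifelse(cs$passed_filter, "steelblue4", "grey60"),
                 xlab = "cluster size (elements)",
                 ylab = "cluster coherence", ...)
  invisible(x)
}
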