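# Element identifiers combine a dataset id and a protein id. "::" is the
# separator, so neither component may contain it.
ELEMENT_SEP <- "::"

element_id <- function(dataset_id, protein) {
  paste0(dataset_id, ELEMENT_SEP, protein)
}

element_dataset <- function(elements) {
  sub("::.*$", "", elements)
}

element_protein <- function(elements) {
  sub("^[^:]*::", "", elements)
}

check_id <- function(x, what) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || !nzchar(x))
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  if (grepl("::", x, fixed = TRUE))
    stop(sprintf("%s must not contain '::' (reserved separator): %s", what, x),
         call. = FALSE)
  x
}

#' Construct a co-fractionation profile dataset
#'
#' A profile dataset holds one co-fractionation (complexome profiling)
#' experiment: a protein-by-fraction abundance matrix together with the
#' identifiers that place it in the analysis (which dataset it is, which
#' collection/complexome it belongs to, and which species' protein
#' identifier namespace it uses).
#'
#' @param abundances numeric matrix, rows = proteins, columns = fractions.
#'   Row names are the protein identifiers.
#' @param dataset_id,collection_id,species_id single strings identifying the
#'   dataset, the collection (complexome) it belongs to, and the species
#'   whose identifier namespace its proteins use. None may contain `"::"`.
#' @return An object of class `profile_dataset`.
#' @export
profile_dataset <- function(abundances, dataset_id, collection_id, species_id) {
  check_id(dataset_id, "dataset_id")
  check_id(collection_id, "collection_id")
  check_id(species_id, "species_id")
  if (!is.matrix(abundances) || !is.numeric(abundances))
    stop("abundances must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(abundances)))
    stop("abundances must have protein identifiers as row names", call. = FALSE)
  if (ncol(abundances) < 2L)
    stop("a profile dataset needs at least 2 fractions", call. = FALSE)
  prot <- rownames(abundances)
  dup <- unique(prot[duplicated(prot)])
  if (length(dup))
    stop("duplicate protein identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- grepl("::", prot, fixed = TRUE)
  if (any(bad))
    stop("protein identifiers must not contain '::': ",
         paste(prot[bad], collapse = ", "), call. = FALSE)
  if (any(!is.finite(abundances)))
    stop("abundances must be finite (missing cells are read as 0)",
         call. = FALSE)
  structure(
    list(dataset_id = dataset_id, collection_id = collection_id,
         species_id = species_id, proteins = prot, abundances = abundances),
    class = "profile_dataset")
}

#' Construct a within-dataset interaction score matrix
#'
#' @param scores symmetric numeric matrix of interaction scores (e.g. Pearson
#'   correlations between migration profiles) with protein identifiers as
#'   dimnames. The diagonal is never consulted and is stored as `NA`.
#'   `NA` rows/columns mark proteins that cannot be ranked (e.g. zero
#'   variance profiles).
#' @inheritParams profile_dataset
#' @param tol maximum tolerated asymmetry `max |S - t(S)|`.
#' @return An object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(scores, dataset_id, collection_id, species_id,
                               tol = 1e-9) {
  check_id(dataset_id, "dataset_id")
  check_id(collection_id, "collection_id")
  check_id(species_id, "species_id")
  if (!is.matrix(scores) || nrow(scores) != ncol(scores))
    stop("scores must be a square matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must carry protein identifiers as dimnames", call. = FALSE)
  if (!identical(rownames(scores), colnames(scores))) {
    if (setequal(rownames(scores), colnames(scores))) {
      scores <- scores[, rownames(scores), drop = FALSE]  # reorder to row order
    } else {
      stop("row and column identifier sets differ", call. = FALSE)
    }
  }
  prot <- rownames(scores)
  dup <- unique(prot[duplicated(prot)])
  if (length(dup))
    stop("duplicate protein identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  diag(scores) <- NA_real_
  dev <- abs(scores - t(scores))
  mx <- suppressWarnings(max(dev, na.rm = TRUE))
  if (is.finite(mx) && mx > tol)
    stop(sprintf("score matrix is asymmetric (max deviation %.3g)", mx),
         call. = FALSE)
  structure(
    list(dataset_id = dataset_id, collection_id = collection_id,
         species_id = species_id, proteins = prot, scores = scores),
    class = "interaction_matrix")
}

#' Construct a one-to-one orthology map between two species
#'
#' @param pairs two-column character matrix or data frame; column 1 holds
#'   identifiers of `species_a`, column 2 of `species_b`. Each identifier may
#'   appear in at most one pair.
#' @param species_a,species_b species identifiers.
#' @return An object of class `orthology_map`.
#' @export
orthology_map <- function(pairs, species_a, species_b) {
  check_id(species_a, "species_a")
  check_id(species_b, "species_b")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L)
    stop("orthology pairs need two columns", call. = FALSE)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  dup_a <- unique(a[duplicated(a)])
  dup_b <- unique(b[duplicated(b)])
  if (length(dup_a) || length(dup_b))
    stop("orthology is not one-to-one; repeated identifiers: ",
         paste(unique(c(dup_a, dup_b)), collapse = ", "), call. = FALSE)
  structure(
    list(species_pair = c(species_a, species_b),
         a = a, b = b),
    class = "orthology_map")
}

#' Look up the translation table of an orthology map
#'
#' @param map an [orthology_map()].
#' @param from species whose identifiers are to be translated.
#' @return Named character vector mapping `from`-identifiers to the partner
#'   species' identifiers.
#' @export
orthology_lookup <- function(map, from) {
  stopifnot(inherits(map, "orthology_map"))
  if (from == map$species_pair[1L]) {
    stats::setNames(map$b, map$a)
  } else if (from == map$species_pair[2L]) {
    stats::setNames(map$a, map$b)
  } else {
    stop("species ", from, " is not part of this orthology map", call. = FALSE)
  }
}

# Find the orthology map for a species pair in a list of maps; identity
# (NULL) for a same-species pair, error if a cross-species map is missing.
find_orthology <- function(orthologies, species_a, species_b) {
  if (species_a == species_b) return(NULL)
  for (m in orthologies) {
    sp <- m$species_pair
    if ((sp[1L] == species_a && sp[2L] == species_b) ||
        (sp[1L] == species_b && sp[2L] == species_a))
      return(m)
  }
  stop(sprintf("no orthology map provided for species pair %s / %s",
               species_a, species_b), call. = FALSE)
}

#' Construct a reference complex set
#'
#' @param complexes named list of character vectors: complex name ->
#'   member protein identifiers (one collection's namespace).
#' @return An object of class `reference_complexes`.
#' @export
reference_complexes <- function(complexes) {
  if (!is.list(complexes) || is.null(names(complexes)) ||
      any(!nzchar(names(complexes))))
    stop("complexes must be a named list", call. = FALSE)
  nm <- names(complexes)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate complex names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  empty <- vapply(complexes, length, 1L) == 0L
  if (any(empty)) {
    warning("dropping empty reference complexes: ",
            paste(nm[empty], collapse = ", "), call. = FALSE)
    complexes <- complexes[!empty]
  }
  structure(complexes, class = "reference_complexes")
}

#' Summarise datasets into their collections
#'
#' A collection groups the datasets that profile one complexome (one
#' species/tissue/life-stage context). Its dataset count is the denominator
#' of the fraction-clustered (FrC) score.
#'
#' @param datasets list of [profile_dataset()] / [interaction_matrix()]
#'   objects.
#' @return data frame with one row per collection: `collection_id`,
#'   `species_id`, `n_datasets`, and a list column `dataset_ids`.
#' @export
collection_table <- function(datasets) {
  ds_id <- vapply(datasets, `[[`, "", "dataset_id")
  dup <- unique(ds_id[duplicated(ds_id)])
  if (length(dup))
    stop("duplicate dataset ids: ", paste(dup, collapse = ", "), call. = FALSE)
  coll <- vapply(datasets, `[[`, "", "collection_id")
  sp_ids <- vapply(datasets, `[[`, "", "species_id")
  u <- !duplicated(coll)
  for (cid in coll[u]) {
    sp <- unique(sp_ids[coll == cid])
    if (length(sp) > 1L)
      stop("collection ", cid, " mixes species: ", paste(sp, collapse = ", "),
           call. = FALSE)
  }
  out <- data.frame(collection_id = coll[u], species_id = sp_ids[u],
                    n_datasets = as.integer(table(coll)[coll[u]]),
                    stringsAsFactors = FALSE)
  out$dataset_ids <- lapply(out$collection_id, function(cid) ds_id[coll == cid])
  rownames(out) <- out$collection_id
  out
}

## ---- file readers -------------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

# Parse a character matrix of numeric cells; empty cells become 0, anything
# non-numeric is reported with its row identifier and column label.
parse_numeric_cells <- function(cells, row_ids, col_labels, path) {
  cells[cells == ""] <- "0"
  suppressWarnings(num <- as.numeric(cells))
  bad <- which(is.na(num) & !is.na(cells))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% length(row_ids)) + 1L
    j <- ((bad[1L] - 1L) %/% length(row_ids)) + 1L
    stop(sprintf("%s: malformed numeric value '%s' (row '%s', column '%s')",
                 path, cells[bad[1L]], row_ids[i], col_labels[j]),
         call. = FALSE)
  }
  matrix(num, nrow = length(row_ids),
         dimnames = list(row_ids, col_labels))
}

#' Read a protein abundance profile table
#'
#' Expects a TSV with a header row of fraction labels, the first column
#' holding protein identifiers (header conventionally `protein`). Empty
#' cells are read as abundance 0.
#'
#' @param path path to the TSV file.
#' @inheritParams profile_dataset
#' @return A [profile_dataset()].
#' @export
load_profile_dataset <- function(path, dataset_id, collection_id, species_id) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 3L)
    stop(path, ": need an identifier column plus at least 2 fractions",
         call. = FALSE)
  prot <- tab[[1L]]
  dup <- unique(prot[duplicated(prot)])
  if (length(dup))
    stop(path, ": duplicate protein identifiers: ",
         paste(dup, collapse = ", "), call. = FALSE)
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  ab <- parse_numeric_cells(cells, prot, colnames(tab)[-1L], path)
  profile_dataset(ab, dataset_id, collection_id, species_id)
}

#' Read a precomputed symmetric interaction score matrix
#'
#' Square TSV with identical row and column identifier sets (columns are
#' reordered to the row order if permuted); asymmetries beyond `tol` are
#' rejected.
#'
#' @inheritParams load_profile_dataset
#' @param tol symmetry tolerance.
#' @return An [interaction_matrix()].
#' @export
load_score_matrix <- function(path, dataset_id, collection_id, species_id,
                              tol = 1e-9) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  prot <- tab[[1L]]
  if (ncol(tab) - 1L != nrow(tab))
    stop(path, sprintf(": matrix is not square (%d rows, %d score columns)",
                       nrow(tab), ncol(tab) - 1L), call. = FALSE)
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  sc <- parse_numeric_cells(cells, prot, colnames(tab)[-1L], path)
  interaction_matrix(sc, dataset_id, collection_id, species_id, tol = tol)
}

#' Read a two-column orthology file
#'
#' Headerless TSV; column 1 holds `species_a` identifiers, column 2
#' `species_b` identifiers. The pairing must be one-to-one.
#'
#' @param path path to the TSV file.
#' @param species_a,species_b species identifiers for the two columns.
#' @return An [orthology_map()].
#' @export
load_orthology <- function(path, species_a, species_b) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L)
    stop(path, ": orthology file needs two tab-separated columns",
         call. = FALSE)
  orthology_map(tab[, 1:2], species_a, species_b)
}

#' Write an orthology map to a two-column TSV
#'
#' @param map an [orthology_map()].
#' @param path output path.
#' @export
write_orthology <- function(map, path) {
  stopifnot(inherits(map, "orthology_map"))
  utils::write.table(data.frame(a = map$a, b = map$b),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference complex file
#'
#' Two formats are accepted, decided per line: a 2-column TSV
#' (`name<TAB>member1;member2;...`) or GMT-style lines with 3+ tab-separated
#' fields (`name<TAB>description<TAB>member1<TAB>member2...`).
#'
#' @param path path to the file.
#' @return A [reference_complexes()] set.
#' @export
load_reference_complexes <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stop(path, ": malformed complex line: ", ln, call. = FALSE)
    nm <- f[1L]
    members <- if (length(f) == 2L) {
      strsplit(f[2L], ";", fixed = TRUE)[[1L]]
    } else {
      f[-(1:2)]  # GMT: field 2 is a description
    }
    members <- members[nzchar(trimws(members))]
    if (nm %in% names(out))
      stop(path, ": duplicate complex name: ", nm, call. = FALSE)
    out[[nm]] <- members
  }
  reference_complexes(out)
}

#' Write a profile dataset to TSV
#'
#' Inverse of [load_profile_dataset()]; first column header is `protein`.
#'
#' @param ds a [profile_dataset()].
#' @param path output path.
#' @export
write_profile_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "profile_dataset"))
  tab <- data.frame(protein = ds$proteins, ds$abundances,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet groups input files into datasets and collections. It is
#' a TSV with header columns `dataset_id`, `collection_id`, `species_id`,
#' `path` and `type` (`profile` or `scores`).
#'
#' @param path path to the sample sheet.
#' @return data frame with one row per dataset.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  need <- c("dataset_id", "collection_id", "species_id", "path", "type")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop(path, ": sample sheet lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !tab$type %in% c("profile", "scores")
  if (any(bad))
    stop(path, ": unknown dataset type(s): ",
         paste(unique(tab$type[bad]), collapse = ", "), call. = FALSE)
  tab
}

#' Load all datasets referenced by a sample sheet
#'
#' @param sheet sample sheet data frame from [read_sample_sheet()] or a path.
#' @param base_dir directory against which relative `path` entries are
#'   resolved; defaults to the sheet's own directory when `sheet` is a path.
#' @return list of [profile_dataset()] / [interaction_matrix()] objects.
#' @export
load_samples <- function(sheet, base_dir = NULL) {
  if (is.character(sheet) && length(sheet) == 1L) {
    if (is.null(base_dir)) base_dir <- dirname(sheet)
    sheet <- read_sample_sheet(sheet)
  }
  if (is.null(base_dir)) base_dir <- "."
  lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, sheet$path[i])
    if (sheet$type[i] == "profile") {
      load_profile_dataset(p, sheet$dataset_id[i], sheet$collection_id[i],
                           sheet$species_id[i])
    } else {
      load_score_matrix(p, sheet$dataset_id[i], sheet$collection_id[i],
                        sheet$species_id[i])
    }
  })
}

#' Write the result tables of a comparative clustering run
#'
#' Produces three TSV files in `out_dir`: `members.tsv` (one row per
#' clustered protein per collection, with FrC score and best-guess flag),
#' `clusters.tsv` (one row per supercluster with match counts, coherence,
#' filter status and annotation) and `network.tsv` (the hypernetwork edge
#' list, node ids encoded `dataset_id::protein`). Rows are ordered by
#' cluster id, then collection, then FrC descending, then identifier.
#'
#' @param result a `profclust` result object.
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_cluster_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "profclust"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mem <- result$members
  mem <- mem[order(mem$supercluster_id, mem$collection_id, -mem$frc,
                   mem$protein), , drop = FALSE]
  p1 <- file.path(out_dir, "members.tsv")
  utils::write.table(mem, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "clusters.tsv")
  utils::write.table(result$cluster_summary, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(out_dir, "network.tsv")
  ed <- result$network$edges
  utils::write.table(ed[order(ed$from, ed$to), , drop = FALSE], p3,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(members = p1, clusters = p2, network = p3))
}
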