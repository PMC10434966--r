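## Synthetic complexome generator: multi-species, multi-replicate
## co-fractionation profile datasets with planted conserved and
## taxon-specific complexes, partial orthology coverage and a known
## ground truth, so every pipeline stage can be exercised without
## external data.

#' Configuration for the synthetic complexome generator
#'
#' Complex subunits comigrate as a shared Gaussian elution peak whose
#' centre is jittered per dataset; profiles carry multiplicative
#' log-normal noise. Background proteins elute at independent positions.
#' Conserved subunits exist in every species and are linked by emitted
#' one-to-one orthology pairs (subject to dropout); a share of each
#' complex is taxon-specific, present in a single species only.
#'
#' @param n_species number of species (one identifier namespace each).
#' @param collections_per_species collections (complexomes) per species;
#'   collections of one species share the identifier namespace.
#' @param datasets_per_collection replicate datasets per collection.
#' @param n_fractions fractions per dataset; default 60, a typical
#'   blue-native gel fractionation depth.
#' @param n_complexes planted complexes; default 10.
#' @param complex_size_range inclusive size range of planted complexes
#'   per species; default c(5, 10).
#' @param taxon_specific_fraction share of each complex's subunits that
#'   are private to one species; default 0.1.
#' @param ortholog_dropout probability that a conserved subunit pair is
#'   omitted from the emitted orthology files; default 0.
#' @param background_proteins proteins per species outside any planted
#'   complex; default 950, so a species' proteome is on the order of a
#'   thousand proteins, as in typical complexome profiles.
#' @param background_margin minimum distance (fractions) between a
#'   background protein's elution position and any complex centre;
#'   default 2. Background proteins comigrating exactly with a complex
#'   would be indistinguishable from members under this profile model,
#'   so the generator keeps them off the planted positions.
#' @param peak_width Gaussian peak standard deviation, in fractions;
#'   default 2.
#' @param peak_jitter maximum per-dataset shift of a peak centre, in
#'   fractions (uniform in +/- jitter); default 1.
#' @param noise_sd standard deviation of the multiplicative log-normal
#'   abundance noise (on the log scale); default 0.1.
#' @param seed integer random seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 2L, collections_per_species = 1L,
                       datasets_per_collection = 2L, n_fractions = 60L,
                       n_complexes = 10L, complex_size_range = c(5L, 10L),
                       taxon_specific_fraction = 0.1,
                       ortholog_dropout = 0,
                       background_proteins = 950L, background_margin = 2,
                       peak_width = 2,
                       peak_jitter = 1, noise_sd = 0.1, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              collections_per_species = as.integer(collections_per_species),
              datasets_per_collection = as.integer(datasets_per_collection),
              n_fractions = as.integer(n_fractions),
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              taxon_specific_fraction = taxon_specific_fraction,
              ortholog_dropout = ortholog_dropout,
              background_proteins = as.integer(background_proteins),
              background_margin = background_margin,
              peak_width = peak_width, peak_jitter = peak_jitter,
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 1, collections_per_species >= 1,
              datasets_per_collection >= 1, n_fractions >= 10,
              n_complexes >= 1, length(complex_size_range) == 2L,
              complex_size_range[1L] >= 2L,
              complex_size_range[2L] >= complex_size_range[1L],
              taxon_specific_fraction >= 0, taxon_specific_fraction <= 1,
              ortholog_dropout >= 0, ortholog_dropout <= 1,
              background_proteins >= 0, background_margin >= 0,
              peak_width > 0, peak_jitter >= 0, noise_sd >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' Generate synthetic complexome profiling collections
#'
#' Draws planted complexes (a conserved core shared by all species plus
#' species-private subunits), assigns each complex a migration position
#' on a shuffled grid across the fractionation range (so distinct
#' complexes occupy distinct apparent masses), and emits replicate
#' profile datasets per collection, pairwise orthology maps, and the
#' ground truth. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `datasets` (list of [profile_dataset()]),
#'   `orthologies` (list of [orthology_map()], one per species pair) and
#'   `truth`: list with `complexes` (per species: complex id -> member
#'   identifiers), `conserved` (per complex: per-species conserved
#'   subunit identifier matrix), `taxon_specific` (per species: complex
#'   id -> private members) and `orthology` (full pre-dropout pair table).
#' @export
generate_collections <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  nsp <- cfg$n_species
  species <- sprintf("sp%d", seq_len(nsp))
  size_choices <- seq(cfg$complex_size_range[1L], cfg$complex_size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), cfg$n_complexes,
                                   replace = TRUE)]
  n_ts <- round(cfg$taxon_specific_fraction * sizes)
  n_ts <- pmin(n_ts, sizes - 1L)  # keep at least one conserved subunit
  n_cons <- sizes - n_ts
  complex_ids <- sprintf("cpx%02d", seq_len(cfg$n_complexes))

  # protein identifiers per species
  cons_ids <- lapply(seq_len(nsp), function(s)
    lapply(seq_len(cfg$n_complexes), function(c)
      sprintf("%s_c%02d_u%02d", species[s], c, seq_len(n_cons[c]))))
  ts_ids <- lapply(seq_len(nsp), function(s)
    lapply(seq_len(cfg$n_complexes), function(c)
      if (n_ts[c] > 0L) sprintf("%s_c%02d_t%02d", species[s], c,
                                seq_len(n_ts[c])) else character()))
  bg_ids <- lapply(seq_len(nsp), function(s)
    sprintf("%s_bg%03d", species[s], seq_len(cfg$background_proteins)))

  # migration positions: complexes on a shuffled grid, backgrounds uniform
  margin <- max(4, 2 * cfg$peak_width)
  grid <- seq(margin, cfg$n_fractions - margin,
              length.out = max(cfg$n_complexes, 2L))
  centers <- sample(grid)[seq_len(cfg$n_complexes)]
  draw_bg_center <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::runif(2L * (n - length(out)), 1, cfg$n_fractions)
      ok <- vapply(x, function(xi)
        all(abs(xi - centers) >= cfg$background_margin), TRUE)
      out <- c(out, x[ok])
    }
    out[seq_len(n)]
  }
  bg_centers <- lapply(seq_len(nsp), function(s)
    draw_bg_center(cfg$background_proteins))

  # per-protein amplitudes, shared across a species' datasets
  amp <- lapply(seq_len(nsp), function(s) {
    ids <- c(unlist(cons_ids[[s]]), unlist(ts_ids[[s]]), bg_ids[[s]])
    stats::setNames(stats::rlnorm(length(ids), meanlog = log(100),
                                  sdlog = 0.5), ids)
  })

  fractions <- seq_len(cfg$n_fractions)
  peak <- function(center) {
    y <- exp(-(fractions - center)^2 / (2 * cfg$peak_width^2))
    y / max(y)
  }
  datasets <- list()
  for (s in seq_len(nsp)) {
    prot_complex <- c(unlist(cons_ids[[s]]), unlist(ts_ids[[s]]))
    prot_cpx <- c(rep(seq_len(cfg$n_complexes), times = n_cons),
                  rep(seq_len(cfg$n_complexes), times = n_ts))
    names(prot_cpx) <- prot_complex
    for (k in seq_len(cfg$collections_per_species)) {
      coll_id <- sprintf("%s_c%d", species[s], k)
      for (r in seq_len(cfg$datasets_per_collection)) {
        ds_id <- sprintf("%s_d%d", coll_id, r)
        jit <- if (cfg$peak_jitter > 0)
          stats::runif(cfg$n_complexes, -cfg$peak_jitter, cfg$peak_jitter)
        else rep(0, cfg$n_complexes)
        ids <- c(prot_complex, bg_ids[[s]])
        ab <- matrix(0, length(ids), cfg$n_fractions,
                     dimnames = list(ids, sprintf("f%02d", fractions)))
        for (p in prot_complex) {
          cx <- prot_cpx[[p]]
          ab[p, ] <- amp[[s]][[p]] * peak(centers[cx] + jit[cx])
        }
        bj <- if (cfg$peak_jitter > 0)
          stats::runif(cfg$background_proteins, -cfg$peak_jitter,
                       cfg$peak_jitter)
        else rep(0, cfg$background_proteins)
        for (b in seq_len(cfg$background_proteins)) {
          p <- bg_ids[[s]][b]
          ab[p, ] <- amp[[s]][[p]] * peak(bg_centers[[s]][b] + bj[b])
        }
        if (cfg$noise_sd > 0) {
          ab <- ab * exp(matrix(stats::rnorm(length(ab), 0, cfg$noise_sd),
                                nrow(ab)))
        }
        datasets[[ds_id]] <- profile_dataset(ab, ds_id, coll_id, species[s])
      }
    }
  }

  # orthology: conserved subunits paired across every species pair
  full_pairs <- list()
  orthologies <- list()
  if (nsp >= 2L) {
    for (s1 in seq_len(nsp - 1L)) {
      for (s2 in seq((s1 + 1L), nsp)) {
        a <- unlist(cons_ids[[s1]])
        b <- unlist(cons_ids[[s2]])
        full_pairs[[paste(species[s1], species[s2], sep = "|")]] <-
          data.frame(a = a, b = b, stringsAsFactors = FALSE)
        keep <- if (cfg$ortholog_dropout > 0)
          stats::runif(length(a)) >= cfg$ortholog_dropout
        else rep(TRUE, length(a))
        orthologies[[length(orthologies) + 1L]] <-
          orthology_map(data.frame(a = a[keep], b = b[keep]),
                        species[s1], species[s2])
      }
    }
  }

  truth <- list(
    complexes = stats::setNames(lapply(seq_len(nsp), function(s) {
      out <- lapply(seq_len(cfg$n_complexes), function(c)
        c(cons_ids[[s]][[c]], ts_ids[[s]][[c]]))
      names(out) <- complex_ids
      out
    }), species),
    taxon_specific = stats::setNames(lapply(seq_len(nsp), function(s) {
      out <- ts_ids[[s]]
      names(out) <- complex_ids
      out
    }), species),
    orthology = full_pairs,
    centers = stats::setNames(centers, complex_ids),
    sizes = stats::setNames(sizes, complex_ids))

  list(datasets = unname(datasets), orthologies = orthologies, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a generated synthetic study to disk
#'
#' Emits the profile TSVs, a sample sheet, two-column orthology files and
#' a ground-truth member table, in the formats the loaders read.
#'
#' @param sim output of [generate_collections()].
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the sample sheet path.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim$datasets, function(d) {
    f <- paste0(d$dataset_id, ".tsv")
    write_profile_dataset(d, file.path(out_dir, f))
    data.frame(dataset_id = d$dataset_id, collection_id = d$collection_id,
               species_id = d$species_id, path = f, type = "profile",
               stringsAsFactors = FALSE)
  })
  sheet <- do.call(rbind, rows)
  sheet_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (m in sim$orthologies) {
    write_orthology(m, file.path(out_dir, sprintf("orthology_%s_%s.tsv",
                                                  m$species_pair[1L],
                                                  m$species_pair[2L])))
  }
  gt <- do.call(rbind, lapply(names(sim$truth$complexes), function(sp) {
    cx <- sim$truth$complexes[[sp]]
    do.call(rbind, lapply(names(cx), function(id)
      data.frame(species = sp, complex = id, protein = cx[[id]],
                 stringsAsFactors = FALSE)))
  }))
  utils::write.table(gt, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sheet_path)
}
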