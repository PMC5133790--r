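#' Mass deviation in parts per million
#'
#' Deviation of an observed mass from a reference mass, in ppm. The first
#' argument is the reference (the master/seed mass in cross-sample matching),
#' which fixes the denominator and keeps the match predicate reproducible.
#'
#' @param ref_mass,mass Masses in Da (vectors recycle); must be positive.
#' @return `abs(mass - ref_mass) / ref_mass * 1e6`.
#' @export
#' @examples
#' ppm_deviation(1000, 1000.05)  # 50
ppm_deviation <- function(ref_mass, mass) {
  if (any(ref_mass <= 0) || any(mass <= 0)) abort("masses must be positive")
  abs(mass - ref_mass) / ref_mass * 1e6
}

#' Pairwise peptide identity rule
#'
#' Two detected features count as the same peptide when the mass deviation is
#' lower than `ppm_tol` ppm and the migration-time gap is lower than
#' `mt_tol_min` minutes — both strict inequalities. The first feature is the
#' reference for the ppm denominator.
#'
#' @param f1,f2 Data frames / named lists with `mass_da` and `mt_min`
#'   (rows recycle against each other).
#' @param ppm_tol Mass tolerance in ppm (default 50).
#' @param mt_tol_min Migration-time tolerance in minutes (default 2).
#' @return Logical vector.
#' @export
features_match <- function(f1, f2, ppm_tol = 50, mt_tol_min = 2) {
  f1 <- as.list(f1); f2 <- as.list(f2)
  ppm_deviation(f1$mass_da, f2$mass_da) < ppm_tol &
    abs(f1$mt_min - f2$mt_min) < mt_tol_min
}

#' Normalize runs against internal standard peptides
#'
#' Scales every intensity in a run by one run-level factor, the median over
#' matched standards of (reference intensity / observed intensity), so the
#' matched standards sit at their declared reference intensities (median
#' ratio 1). With `standards = NULL` the data are taken as pre-normalized and
#' returned unchanged (the synthetic generator emits pre-normalized runs).
#'
#' @param features Feature tibble with `sample_id`, `mass_da`, `mt_min`,
#'   `intensity`.
#' @param standards Tibble with `mass_da`, `mt_min`, `reference_intensity`,
#'   or `NULL` for the identity bypass.
#' @inheritParams features_match
#' @return The feature tibble with scaled intensities; per-run factors in
#'   `attr(, "norm_factors")`.
#' @export
normalize_runs <- function(features, standards = NULL, ppm_tol = 50, mt_tol_min = 2) {
  if (is.null(standards)) {
    attr(features, "norm_factors") <-
      tibble::tibble(sample_id = unique(features$sample_id), factor = 1)
    return(features)
  }
  runs <- split(seq_len(nrow(features)), features$sample_id)
  factors <- purrr::imap_dbl(runs, function(idx, run_id) {
    fm <- features[idx, ]
    ratios <- purrr::pmap_dbl(standards, function(mass_da, mt_min, reference_intensity, ...) {
      hit <- which(features_match(list(mass_da = mass_da, mt_min = mt_min),
                                  fm, ppm_tol, mt_tol_min))
      if (length(hit) == 0) return(NA_real_)
      # closest match by ppm, then by time gap
      dev <- ppm_deviation(mass_da, fm$mass_da[hit])
      dt <- abs(mt_min - fm$mt_min[hit])
      best <- hit[order(dev, dt)][1]
      reference_intensity / fm$intensity[best]
    })
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) == 0) {
      abort(paste0("normalization error: no internal standard matched in run ", run_id))
    }
    median(ratios)
  })
  features$intensity <- features$intensity * unname(factors[features$sample_id])
  attr(features, "norm_factors") <-
    tibble::tibble(sample_id = names(factors), factor = unname(factors))
  features
}

#' Compile runs into a master peptide list and abundance matrix
#'
#' Cross-sample matching by greedy reference-based clustering: features are
#' ranked by descending cross-run occurrence (number of runs holding a
#' matching feature), then descending intensity; each unmatched feature seeds
#' a master peptide and later features join the nearest matching master
#' (smallest ppm deviation from the seed mass, ties by smaller time gap). A
#' master keeps at most one feature per run — the most intense wins, the
#' displaced feature seeds a new master. Consensus mass and migration time
#' are intensity-weighted means over members, and the normalized signal
#' intensity is carried into the matrix as relative abundance (0 = not
#' detected).
#'
#' @param features Normalized feature tibble (`sample_id`, `mass_da`,
#'   `mt_min`, `intensity`; metadata columns `rat_id`, `group`, `week` are
#'   used when `samples` is not given).
#' @param samples Optional samples tibble (`sample_id`, `rat_id`, `group`,
#'   `week`); defaults to the distinct metadata in `features`. Samples listed
#'   here but absent from `features` would yield all-zero rows and are
#'   rejected.
#' @inheritParams features_match
#' @return A [peptidome] object.
#' @export
compile_peptidome <- function(features, samples = NULL, ppm_tol = 50, mt_tol_min = 2) {
  if (is.null(features) || nrow(features) == 0) abort("no runs to compile")
  if (is.null(samples)) {
    samples <- dplyr::distinct(features, .data$sample_id, .data$rat_id,
                               .data$group, .data$week)
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in samples table")
  missing_runs <- setdiff(samples$sample_id, features$sample_id)
  if (length(missing_runs)) {
    abort(paste0("samples without any features (all-zero rows): ",
                 paste(missing_runs, collapse = ", ")))
  }
  features <- dplyr::filter(features, .data$sample_id %in% samples$sample_id)
  run <- match(features$sample_id, samples$sample_id) - 1L
  n_run <- nrow(samples)

  ord_mass <- order(features$mass_da)
  occ <- integer(nrow(features))
  occ[ord_mass] <- .occurrence_counts(features$mass_da[ord_mass],
                                      features$mt_min[ord_mass],
                                      run[ord_mass], n_run,
                                      ppm_tol, mt_tol_min)
  # priority: occurrence desc, intensity desc; deterministic residual ties
  prio <- order(-occ, -features$intensity, features$mass_da,
                features$mt_min, run)
  cl <- .greedy_cluster(features$mass_da, features$mt_min, features$intensity,
                        run, prio - 1L, n_run, ppm_tol, mt_tol_min) + 1L

  w <- features$intensity
  wt_sum <- tapply(w, cl, sum)
  n_members <- tabulate(cl)
  # intensity-weighted consensus; plain mean where all member intensities are 0
  safe_w <- ifelse(wt_sum[cl] > 0, w, 1)
  cons_mass <- tapply(features$mass_da * safe_w, cl, sum) /
    tapply(safe_w, cl, sum)
  cons_mt <- tapply(features$mt_min * safe_w, cl, sum) / tapply(safe_w, cl, sum)

  o <- order(cons_mass, cons_mt)
  new_id <- integer(length(o)); new_id[o] <- seq_along(o)
  peptides <- tibble::tibble(
    peptide_id = seq_along(o),
    mass_da = as.numeric(cons_mass[o]),
    mt_min = as.numeric(cons_mt[o]),
    n_detected = as.integer(n_members[o])
  )
  ab <- matrix(0, n_run, nrow(peptides),
               dimnames = list(samples$sample_id, peptides$peptide_id))
  ab[cbind(run + 1L, new_id[cl])] <- features$intensity
  peptidome(samples, peptides, ab)
}

#' Construct a peptidome (samples x master peptides) object
#'
#' The compiled container of the pipeline: sample metadata, the master
#' peptide list, and a samples-by-peptides matrix of relative abundances in
#' which 0 encodes non-detection.
#'
#' @param samples Tibble with `sample_id`, `rat_id`, `group`, `week`.
#' @param peptides Tibble with `peptide_id`, `mass_da`, `mt_min`.
#' @param abundance Numeric matrix, `nrow(samples)` x `nrow(peptides)`,
#'   non-negative.
#' @return An object of class `peptidome`.
#' @export
peptidome <- function(samples, peptides, abundance) {
  samples <- tibble::as_tibble(samples)
  peptides <- tibble::as_tibble(peptides)
  stopifnot(is.matrix(abundance),
            nrow(abundance) == nrow(samples),
            ncol(abundance) == nrow(peptides))
  if (any(abundance < 0)) abort("abundances must be non-negative")
  if (anyDuplicated(peptides$peptide_id)) abort("peptide_ids must be unique")
  dimnames(abundance) <- list(samples$sample_id, peptides$peptide_id)
  structure(list(samples = samples, peptides = peptides, abundance = abundance),
            class = "peptidome")
}

#' @export
print.peptidome <- function(x, ...) {
  cat(sprintf("<peptidome> %d samples x %d master peptides\n",
              nrow(x$samples), nrow(x$peptides)))
  cat(sprintf("  groups: %s | weeks: %s | zeros: %.1f%%\n",
              paste(sort(unique(x$samples$group)), collapse = "/"),
              paste(sort(unique(x$samples$week)), collapse = ","),
              100 * mean(x$abundance == 0)))
  invisible(x)
}

#' @export
as.matrix.peptidome <- function(x, ...) x$abundance

#' @rdname peptidome
#' @param x A `peptidome`.
#' @param ... Unused.
#' @return `tidy()` returns one row per (sample, peptide) with a detection
#'   flag; `glance()` a one-row summary.
#' @exportS3Method generics::tidy
tidy.peptidome <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = nrow(x$peptides)),
    peptide_id = rep(x$peptides$peptide_id, each = nrow(x$samples)),
    abundance = as.vector(x$abundance)
  )
  long %>%
    dplyr::left_join(x$samples, by = "sample_id") %>%
    dplyr::left_join(x$peptides, by = "peptide_id") %>%
    dplyr::mutate(detected = .data$abundance > 0)
}

#' @rdname peptidome
#' @exportS3Method generics::glance
glance.peptidome <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_peptides = nrow(x$peptides),
    n_rats = dplyr::n_distinct(x$samples$rat_id),
    n_weeks = dplyr::n_distinct(x$samples$week),
    detection_rate = mean(x$abundance > 0),
    total_intensity = sum(x$abundance)
  )
}

#' Restrict a peptidome to selected samples
#'
#' @param x A `peptidome`.
#' @param week Optional week(s) to keep.
#' @param sample_id Optional sample ids to keep.
#' @return A `peptidome` with the same master peptide list.
#' @export
filter_samples <- function(x, week = NULL, sample_id = NULL) {
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(week)) keep <- keep & x$samples$week %in% week
  if (!is.null(sample_id)) keep <- keep & x$samples$sample_id %in% sample_id
  if (!any(keep)) abort("no samples left after filtering")
  peptidome(x$samples[keep, ], x$peptides, x$abundance[keep, , drop = FALSE])
}

#' Write / read the compiled abundance matrix
#'
#' CSV with one row per sample: metadata columns then one column per master
#' peptide (named `pep<id>`); a sister `*_peptides.csv` is not needed because
#' consensus mass/time are stored in the peptide header row order.
#'
#' @param x A `peptidome`.
#' @param path Output CSV path. `read_abundance_matrix()` reads the pair of
#'   files written by `write_abundance_matrix()`.
#' @return Invisibly, the paths written (matrix and peptide table).
#' @export
write_abundance_matrix <- function(x, path) {
  df <- dplyr::bind_cols(
    x$samples,
    tibble::as_tibble(x$abundance, .name_repair = ~ paste0("pep", x$peptides$peptide_id))
  )
  readr::write_csv(df, path, progress = FALSE)
  pep_path <- sub("(\\.csv)?$", "_peptides.csv", path)
  readr::write_csv(x$peptides, pep_path, progress = FALSE)
  invisible(c(path, pep_path))
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), rat_id = readr::col_character(),
    group = readr::col_character(), week = readr::col_integer(),
    .default = readr::col_double()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  pep <- readr::read_csv(sub("(\\.csv)?$", "_peptides.csv", path),
                         col_types = readr::cols(
                           peptide_id = readr::col_integer(),
                           .default = readr::col_double()
                         ), progress = FALSE, show_col_types = FALSE)
  meta <- c("sample_id", "rat_id", "group", "week")
  ab <- as.matrix(df[, setdiff(names(df), meta)])
  peptidome(df[, meta], pep, ab)
}
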