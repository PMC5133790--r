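#' Signed ratio fold change
#'
#' The reporting convention for case-versus-control abundance changes: the
#' ratio of the larger group mean to the smaller, carrying a negative sign
#' when the case group is the smaller (a decrease). Equal positive means
#' give `1`; the fold change is undefined (`NA`, rendered `"na"` in
#' reports) whenever either mean is zero, since a ratio against a
#' non-detected group is not applicable.
#'
#' @param mean_case,mean_control Non-negative group means (vectors recycle).
#' @return Signed fold change (`|fold| >= 1`), `NA` where undefined.
#' @export
#' @examples
#' fold_change(847.2, 1863.1)   # -2.20 (decrease)
#' fold_change(51010.5, 441.3)  # 115.59
#' fold_change(0, 482.2)        # NA ("na")
fold_change <- function(mean_case, mean_control) {
  if (any(mean_case < 0, na.rm = TRUE) || any(mean_control < 0, na.rm = TRUE)) {
    abort("group means must be non-negative")
  }
  r <- mean_case / mean_control
  out <- ifelse(r >= 1, r, -mean_control / mean_case)
  ifelse(mean_case == 0 | mean_control == 0, NA_real_, out)
}

#' Multi-model loading consensus
#'
#' A peptide is named a candidate biomarker when it carries a loading of at
#' least `load_threshold` in absolute value in every one of the screened
#' models (by default the five lowest-error models of a week). By default
#' the maximum over components is used; `per_component` demands the
#' threshold on one and the same component in every model.
#'
#' @param models List of fitted [splsda] models on an identical peptide set.
#' @param load_threshold Minimum absolute loading (default 0.15).
#' @param n_models Required number of models (default 5).
#' @param per_component If `TRUE`, apply the rule per component instead of
#'   to the per-model maximum across components.
#' @return Character vector of selected peptide (column) names.
#' @export
consensus_biomarkers <- function(models, load_threshold = 0.15, n_models = 5,
                                 per_component = FALSE) {
  if (length(models) != n_models) {
    abort(sprintf("expected %d models, got %d", n_models, length(models)))
  }
  pep_names <- rownames(models[[1]]$x_loadings)
  same <- purrr::map_lgl(models, ~ identical(rownames(.x$x_loadings), pep_names))
  if (!all(same)) abort("schema error: models were fitted on different peptide sets")
  if (per_component) {
    ncomp_min <- min(purrr::map_int(models, "ncomp"))
    hit_any <- purrr::reduce(seq_len(ncomp_min), function(acc, h) {
      acc | purrr::reduce(models, function(a, m) a & abs(m$x_loadings[, h]) >= load_threshold,
                          .init = rep(TRUE, length(pep_names)))
    }, .init = rep(FALSE, length(pep_names)))
    return(pep_names[hit_any])
  }
  hits <- purrr::map(models, function(m) {
    apply(abs(m$x_loadings), 1, max) >= load_threshold
  })
  pep_names[purrr::reduce(hits, `&`)]
}

# per-(week, group, peptide) detection frequency (%) and mean relative
# abundance (mean over ALL collected samples, non-detections as 0)
.group_week_summary <- function(pep, scheme = "three_group") {
  long <- tidy(pep)
  long$grp <- as.character(group_labels(long, scheme))
  long %>%
    dplyr::group_by(.data$week, .data$grp, .data$peptide_id) %>%
    dplyr::summarise(
      n_collected = dplyr::n(),
      n_detected = sum(.data$detected),
      freq = 100 * .data$n_detected / .data$n_collected,
      mean_ab = mean(.data$abundance),
      .groups = "drop"
    )
}

#' Detection frequency of a peptide in a group-week
#'
#' Percentage of the samples actually collected in a group-week in which
#' the peptide was detected (abundance above zero). Denominators follow the
#' collected-sample count, not a nominal group size, so missing collections
#' shrink them.
#'
#' @param pep A [peptidome].
#' @param peptide_id Master peptide id.
#' @param group Group under the merged scheme (`"N"`, `"HA"`, `"HL"`) or a
#'   raw arm (`"NA"`, `"NL"`).
#' @param week Week (1–4).
#' @return Frequency in percent.
#' @export
group_frequency <- function(pep, peptide_id, group, week) {
  s <- .peptide_slice(pep, peptide_id, group, week)
  100 * sum(s > 0) / length(s)
}

#' @rdname group_frequency
#' @return `mean_rel_abundance()`: arithmetic mean relative abundance over
#'   all collected samples of the group-week, non-detections contributing 0.
#' @export
mean_rel_abundance <- function(pep, peptide_id, group, week) {
  s <- .peptide_slice(pep, peptide_id, group, week)
  mean(s)
}

.peptide_slice <- function(pep, peptide_id, group, week) {
  gl <- if (group %in% .GROUPS3 && !(group %in% .GROUPS4)) {
    as.character(group_labels(pep$samples, "three_group"))
  } else pep$samples$group
  rows <- gl == group & pep$samples$week == week
  if (!any(rows)) abort(sprintf("no samples collected for group %s in week %d", group, week))
  col <- match(peptide_id, pep$peptides$peptide_id)
  if (is.na(col)) abort(sprintf("unknown peptide_id %s", peptide_id))
  pep$abundance[rows, col]
}

#' Assemble the biomarker panel report
#'
#' Turns per-week consensus selections into the published report layout:
#' one record per (week, peptide) with per-group (N = NA+NL, HA, HL) mean
#' relative abundance and detection frequency and the signed fold changes of
#' HA and HL versus N, after applying the detection-frequency filter (kept
#' only if detected in more than `min_frequency_pct` percent of the samples
#' of at least one group that week). The unique-panel size — distinct
#' peptides across the weekly selections — is attached as attribute
#' `"unique_peptides"` and reported by [panel_summary()].
#'
#' When `pep` is `NULL` the selections are passed through without abundance
#' summaries (no frequency filter can then be applied); this supports
#' counting week-rows and unique peptides for externally supplied panels.
#'
#' @param selections Tibble with `week` and `peptide_id` (one row per
#'   selected week-peptide), e.g. from [consensus_biomarkers()] per week.
#' @param pep A [peptidome], or `NULL`.
#' @param min_frequency_pct Frequency filter threshold in percent
#'   (strict `>`; default 30).
#' @param annotations Optional tibble `peptide_id`, `protein` carried into
#'   the report.
#' @return Tibble of biomarker records ordered by week then peptide, with
#'   attribute `"unique_peptides"`.
#' @export
build_panel <- function(selections, pep = NULL, min_frequency_pct = 30,
                        annotations = NULL) {
  stopifnot(all(c("week", "peptide_id") %in% names(selections)))
  selections <- dplyr::distinct(selections, .data$week, .data$peptide_id)
  if (!is.null(pep)) {
    smry <- .group_week_summary(pep, "three_group")
    wide <- smry %>%
      tidyr::pivot_wider(names_from = "grp",
                         values_from = c("mean_ab", "freq", "n_collected", "n_detected"),
                         names_sep = "_")
    rec <- selections %>%
      dplyr::inner_join(wide, by = c("week", "peptide_id")) %>%
      dplyr::left_join(pep$peptides[, c("peptide_id", "mass_da", "mt_min")],
                       by = "peptide_id") %>%
      dplyr::filter(pmax(.data$freq_N, .data$freq_HA, .data$freq_HL) > min_frequency_pct) %>%
      dplyr::mutate(
        fold_HA = fold_change(.data$mean_ab_HA, .data$mean_ab_N),
        fold_HL = fold_change(.data$mean_ab_HL, .data$mean_ab_N)
      ) %>%
      dplyr::select("week", "peptide_id", "mass_da", "mt_min",
                    "mean_ab_N", "freq_N", "mean_ab_HA", "freq_HA",
                    "mean_ab_HL", "freq_HL", "fold_HA", "fold_HL")
  } else {
    rec <- selections
  }
  if (!is.null(annotations)) {
    rec <- dplyr::left_join(rec, annotations[, c("peptide_id", "protein")],
                            by = "peptide_id")
  }
  rec <- dplyr::arrange(rec, .data$week, .data$peptide_id)
  attr(rec, "unique_peptides") <- dplyr::n_distinct(rec$peptide_id)
  rec
}

#' @rdname build_panel
#' @param records A panel tibble from `build_panel()`.
#' @return `panel_summary()`: one-row tibble with `week_rows` and
#'   `unique_peptides`.
#' @export
panel_summary <- function(records) {
  tibble::tibble(
    week_rows = nrow(records),
    unique_peptides = dplyr::n_distinct(records$peptide_id)
  )
}

#' Screen a compiled peptidome for biomarkers
#'
#' The full weekly screening step: for each requested week, take the five
#' lowest-error three-group models from the search results, refit them on
#' the complete week's data, apply the loading consensus and the
#' detection-frequency filter, and assemble the panel report.
#'
#' @param pep A [peptidome].
#' @param results Search results from [search_models()] (three-group rows
#'   are used).
#' @param weeks Weeks to screen (default 1:4).
#' @param load_threshold,n_models,per_component See [consensus_biomarkers()].
#' @param min_frequency_pct See [build_panel()].
#' @param log1p Passed to the refits.
#' @return Panel records tibble (see [build_panel()]), with the per-week
#'   selections in attribute `"selections"`.
#' @export
screen_biomarkers <- function(pep, results, weeks = 1:4,
                              load_threshold = 0.15, n_models = 5,
                              per_component = FALSE, min_frequency_pct = 30,
                              log1p = FALSE) {
  selections <- purrr::map_dfr(weeks, function(w) {
    best <- select_best(results, grouping = "three_group", week = w, k = n_models)
    models <- purrr::map2(best$ncomp, best$n_peptides,
                          ~ fit_splsda(pep, "three_group", week = w,
                                       ncomp = .x, keep_x = .y, log1p = log1p))
    sel <- consensus_biomarkers(models, load_threshold, length(models), per_component)
    tibble::tibble(week = as.integer(w), peptide_id = pep$peptides$peptide_id[
      match(sel, as.character(pep$peptides$peptide_id))])
  })
  panel <- build_panel(selections, pep, min_frequency_pct = min_frequency_pct)
  attr(panel, "selections") <- selections
  panel
}
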