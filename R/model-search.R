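# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# per-scheme maximum component count = n_groups - 1
.SCHEME_MAX_NCOMP <- c(four_group = 3L, three_group = 2L, sixteen_group = 15L)

#' Enumerate the basic-model search grid
#'
#' All combinations of grouping scheme, week (for the weekly schemes),
#' number of components (1 to n_groups - 1) and number of peptides per
#' component. With the defaults this is the full 1,750-model grid:
#' 600 four-group weekly + 400 three-group weekly + 750 sixteen-group
#' models. Ordering is deterministic: grouping, week, ncomp, n_peptides.
#'
#' @param n_peptides Candidate `keep_x` values (default `1:50`; a thinned
#'   grid such as `seq(5, 50, by = 5)` trades resolution for speed).
#' @param weeks Weeks covered by the weekly schemes.
#' @param schemes Grouping schemes to include.
#' @return Tibble with `grouping`, `week` (`NA` for the all-weeks scheme),
#'   `ncomp`, `n_peptides`.
#' @export
#' @examples
#' nrow(model_grid())  # 1750
model_grid <- function(n_peptides = 1:50, weeks = 1:4,
                       schemes = c("four_group", "three_group", "sixteen_group")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  purrr::map_dfr(schemes, function(s) {
    wk <- if (s == "sixteen_group") NA_integer_ else as.integer(weeks)
    tidyr::expand_grid(
      grouping = s, week = wk,
      ncomp = seq_len(.SCHEME_MAX_NCOMP[[s]]),
      n_peptides = as.integer(n_peptides)
    )
  })
}

#' Stratified rat-level cross-validation folds
#'
#' Partitions rats (never samples) into folds, stratified by class so every
#' fold holds a near-even share of each group; the shuffle is fixed by
#' `seed`. Keeping a rat's samples on one side of each split avoids leakage
#' when a rat contributes several weekly samples.
#'
#' @param rats Tibble with `rat_id` and a stratification `class` column.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed fixing the shuffle.
#' @return Tibble with `rat_id`, `fold`.
#' @export
cv_folds <- function(rats, n_folds = 10, seed = 1) {
  if (nrow(rats) < n_folds) abort("need at least as many rats as folds")
  .with_seed(seed, {
    assigned <- rats %>%
      dplyr::slice_sample(prop = 1) %>%
      dplyr::arrange(.data$class)
    assigned$fold <- rep_len(seq_len(n_folds), nrow(assigned))
  })
  dplyr::select(dplyr::arrange(assigned, .data$rat_id), "rat_id", "fold")
}

# fold table valid iff every training side keeps every class
.folds_valid <- function(folds, samples, y) {
  fold_of <- folds$fold[match(samples$rat_id, folds$rat_id)]
  all(purrr::map_lgl(sort(unique(folds$fold)), function(f) {
    length(unique(y[fold_of != f])) == length(unique(y))
  }))
}

#' Cross-validated error rate of one basic model
#'
#' 10-fold cross-validation at the rat level: nine sub-groups of rats fit
#' the model, the held-out rats' samples are classified by nearest centroid,
#' and misclassification is the error rate, averaged over the folds. Folds
#' are stratified by class and fixed by `seed`; a draw that strands an
#' entire class outside some training fold is redrawn (up to 10 attempts)
#' with a new seed-derived shuffle.
#'
#' @param pep A [peptidome].
#' @param grouping Grouping scheme.
#' @param week Week for the weekly schemes (`NA`/`NULL` for
#'   `"sixteen_group"`).
#' @param ncomp,n_peptides Model complexity (`n_peptides` is `keep_x`).
#' @param n_folds,seed CV settings.
#' @param folds Optional precomputed fold table (from [cv_folds()]), shared
#'   across the models of a slice.
#' @param log1p Passed to [splsda()].
#' @return One-row tibble: the model spec, `error_rate`, and
#'   `per_fold_errors` (list column).
#' @export
cv_error <- function(pep, grouping = "three_group", week = NULL,
                     ncomp = 2, n_peptides = 15,
                     n_folds = 10, seed = 1, folds = NULL, log1p = FALSE) {
  if (grouping != "sixteen_group") {
    if (is.null(week) || is.na(week)) abort("weekly schemes need a week")
    pep <- filter_samples(pep, week = week)
  } else {
    week <- NA_integer_
  }
  y <- droplevels(group_labels(pep$samples, grouping))
  rats <- pep$samples %>%
    dplyr::mutate(class = as.character(group_labels(pep$samples,
      if (grouping == "sixteen_group") "four_group" else grouping))) %>%
    dplyr::distinct(.data$rat_id, .data$class)

  if (is.null(folds) || !.folds_valid(folds, pep$samples, y)) {
    folds <- NULL
    for (attempt in 0:9) {
      cand <- cv_folds(rats, n_folds, seed + 1009L * attempt)
      if (.folds_valid(cand, pep$samples, y)) {
        folds <- cand
        if (attempt > 0) warn(sprintf("fold redraw %d used for seed %d", attempt, seed))
        break
      }
    }
    if (is.null(folds)) {
      abort("unsatisfiable stratification: some class cannot be kept in every training fold")
    }
  }
  fold_of <- folds$fold[match(pep$samples$rat_id, folds$rat_id)]
  per_fold <- purrr::map_dbl(sort(unique(folds$fold)), function(f) {
    tr <- fold_of != f
    fit <- splsda(pep$abundance[tr, , drop = FALSE], y[tr],
                  ncomp = ncomp, keep_x = n_peptides, log1p = log1p)
    pred <- predict(fit, pep$abundance[!tr, , drop = FALSE])
    mean(as.character(pred) != as.character(y[!tr]))
  })
  tibble::tibble(
    grouping = grouping, week = as.integer(week),
    ncomp = as.integer(ncomp), n_peptides = as.integer(n_peptides),
    error_rate = mean(per_fold), per_fold_errors = list(per_fold)
  )
}

#' Cross-validate every model of a grid
#'
#' Runs [cv_error()] for each row of a model grid. One seed-fixed stratified
#' fold partition is drawn per (grouping, week) slice and shared by all of
#' that slice's models, so error rates across the grid differ only through
#' model complexity; set `shared_folds = FALSE` to redraw per model
#' (seeded by the row index).
#'
#' @param pep A [peptidome].
#' @param grid Tibble from [model_grid()].
#' @param n_folds,seed,log1p As in [cv_error()].
#' @param shared_folds Share one fold partition per slice (default TRUE).
#' @return Results tibble: the grid columns plus `error_rate`,
#'   `per_fold_errors`, and `rank` within each (grouping, week) slice.
#' @export
search_models <- function(pep, grid = model_grid(), n_folds = 10, seed = 1,
                          shared_folds = TRUE, log1p = FALSE) {
  grid <- dplyr::mutate(grid, .order = dplyr::row_number())
  slices <- dplyr::group_split(grid, .data$grouping, .data$week)
  res <- purrr::map_dfr(slices, function(sl) {
    folds <- NULL
    purrr::pmap_dfr(
      list(sl$grouping, sl$week, sl$ncomp, sl$n_peptides, sl$.order),
      function(g, w, nc, np, ord) {
        r <- cv_error(pep, g, w, nc, np, n_folds = n_folds,
                      seed = if (shared_folds) seed else seed + ord,
                      folds = folds, log1p = log1p)
        r$.order <- ord
        r
      }
    )
  })
  res %>%
    dplyr::arrange(.data$.order) %>%
    dplyr::group_by(.data$grouping, .data$week) %>%
    dplyr::mutate(rank = rank(.data$error_rate, ties.method = "min")) %>%
    dplyr::ungroup()
}

#' Select the best models of a slice
#'
#' The `k` lowest cross-validated error rates within one (grouping, week)
#' slice; ties resolved toward parsimony — fewer peptides, then fewer
#' components, then enumeration order.
#'
#' @param results Results tibble from [search_models()] (or [cv_error()]
#'   rows bound together).
#' @param grouping,week Optional slice filters.
#' @param k Number of models to keep (default 5, the screening pool size).
#' @return Tibble of `k` rows (fewer, with a warning, when the slice is
#'   smaller than `k`).
#' @export
select_best <- function(results, grouping = NULL, week = NULL, k = 5) {
  if (!is.null(grouping)) results <- dplyr::filter(results, .data$grouping == !!grouping)
  if (!is.null(week)) results <- dplyr::filter(results, .data$week == !!week)
  if (!".order" %in% names(results)) results$.order <- seq_len(nrow(results))
  if (nrow(results) < k) {
    warn(sprintf("only %d model(s) available; returning all", nrow(results)))
  }
  results %>%
    dplyr::arrange(.data$error_rate, .data$n_peptides, .data$ncomp, .data$.order) %>%
    head(k)
}
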