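#' Configuration for the synthetic urinary-peptidome generator
#'
#' Defaults emulate the study design the pipeline targets: 888 master
#' peptides, 24 rats in 4 treatment arms (6 per arm; the two standard-diet
#' arms are statistically identical), 4 weekly collections, zero-inflated
#' log-normal abundances, and 55 planted discriminant peptides whose HL
#' effect sits between N and HA in weeks 1–3 (`hl_lambda`) and converges
#' toward HA at week 4 (`hl_lambda_week4`).
#'
#' @param n_peptides Number of true peptides (default 888).
#' @param rats_per_subgroup Rats per treatment arm (default 6).
#' @param weeks Number of weekly collections (default 4).
#' @param n_planted Number of planted discriminant peptides (default 55).
#' @param effect_lfc HA-versus-N effect on planted peptides, natural-log
#'   units (default 1.5); the sign per peptide is drawn once, seed-fixed.
#' @param hl_lambda HL intermediacy in (0,1) for weeks 1–3 (default 0.5).
#' @param hl_lambda_week4 HL intermediacy at week 4 (default 0.95 — the
#'   intermediate profile vanishes).
#' @param detect_base Target mean detection probability (default 0.6); the
#'   logistic detection model (unit slope in the centered log-mean) is
#'   calibrated so the average detection probability hits this value.
#' @param sigma_log Within-group log-normal SD (default 0.8).
#' @param missing_run_prob Probability a rat-week collection is absent
#'   (default 0.04, echoing the reduced group denominators seen in real
#'   collections).
#' @param mass_range,mt_range Mass (Da) and migration-time (min) supports.
#' @param mass_jitter_ppm,mt_jitter_min Per-run feature jitter bounds.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_peptides = 888, rats_per_subgroup = 6, weeks = 4,
                       n_planted = 55, effect_lfc = 1.5, hl_lambda = 0.5,
                       hl_lambda_week4 = 0.95, detect_base = 0.6,
                       sigma_log = 0.8, missing_run_prob = 0.04,
                       mass_range = c(800, 30000), mt_range = c(19, 47),
                       mass_jitter_ppm = 20, mt_jitter_min = 0.5, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_planted > cfg$n_peptides) abort("n_planted must not exceed n_peptides")
  if (cfg$hl_lambda <= 0 || cfg$hl_lambda >= 1) abort("hl_lambda must lie in (0, 1)")
  for (p in c("detect_base", "missing_run_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must lie in [0, 1]"))
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic CE-MS urinary peptidome study
#'
#' Draws a complete multi-week feeding study with known ground truth. Each
#' peptide gets a baseline log-mean `~ Normal(log 500, 1)`; planted peptides
#' shift the HA arm by `effect_lfc` (random sign) and place HL at
#' `hl_lambda` of the way from N to HA (weeks 1–3) or `hl_lambda_week4`
#' (week 4). Abundance in a run is log-normal around the group log-mean with
#' SD `sigma_log`, observed with a logistic detection probability in the
#' log-mean (calibrated to `detect_base` on average) and zero otherwise.
#' True masses are laid out log-spaced with jitter so any two peptides are
#' separated by far more than the matching tolerances; per-run features
#' jitter by at most `mass_jitter_ppm` ppm and `mt_jitter_min` minutes.
#' Whole rat-week collections go missing with `missing_run_prob`.
#'
#' Intensities are emitted pre-normalized (the internal-standard step is a
#' no-op on them).
#'
#' @param cfg A [sim_config()].
#' @return A `pep_sim` list: `features` (jittered per-run peak rows),
#'   `samples` (metadata of realized collections), `truth` (list with
#'   `peptides` incl. `planted`, and `expected` per peptide-arm-week
#'   log-mean and detection probability), and `config`.
#' @export
simulate_peptidome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_peptides
    span <- log(cfg$mass_range[2] / cfg$mass_range[1])
    # stratified log-spacing: gaps at least 0.4 x stratum width (>> 2 x 50 ppm)
    u <- runif(n, 0.2, 0.8)
    mass <- cfg$mass_range[1] * exp((seq_len(n) - 1 + u) * span / n)
    if (any(diff(log(mass)) <= 2 * 50e-6)) {
      abort("generation error: mass packing violates the matching tolerance")
    }
    mt <- runif(n, cfg$mt_range[1], cfg$mt_range[2])
    planted <- sort(sample.int(n, cfg$n_planted))
    mu <- rnorm(n, log(500), 1)
    eff_sign <- sample(c(-1, 1), cfg$n_planted, replace = TRUE)

    arms <- .GROUPS4
    wk <- seq_len(cfg$weeks)
    lambda_w <- ifelse(wk == 4, cfg$hl_lambda_week4, cfg$hl_lambda)
    # log-mean array: peptide x arm x week
    lm <- array(rep(mu, times = length(arms) * length(wk)),
                dim = c(n, length(arms), length(wk)),
                dimnames = list(NULL, arms, paste0("w", wk)))
    delta <- numeric(n)
    delta[planted] <- eff_sign * cfg$effect_lfc
    for (w in wk) {
      lm[, "HA", w] <- mu + delta
      lm[, "HL", w] <- mu + lambda_w[w] * delta
    }
    # logistic detection in the centered log-mean, calibrated to detect_base
    cen <- as.vector(lm) - mean(mu)
    alpha <- uniroot(function(a) mean(plogis(a + cen)) - cfg$detect_base,
                     c(-30, 30))$root
    pdet <- array(plogis(alpha + cen), dim = dim(lm), dimnames = dimnames(lm))

    rats <- tibble::tibble(
      rat_id = sprintf("R%02d", seq_len(4 * cfg$rats_per_subgroup)),
      group = rep(arms, each = cfg$rats_per_subgroup)
    )
    design <- tidyr::expand_grid(rats, week = wk) %>%
      dplyr::mutate(
        sample_id = sprintf("S_%s_w%d", .data$rat_id, .data$week),
        present = runif(dplyr::n()) >= cfg$missing_run_prob
      )
    samples <- design %>%
      dplyr::filter(.data$present) %>%
      dplyr::select("sample_id", "rat_id", "group", "week")

    features <- purrr::pmap_dfr(samples, function(sample_id, rat_id, group, week) {
      det <- rbinom(n, 1, pdet[, group, week]) == 1
      k <- sum(det)
      if (k == 0) return(NULL)
      jitter_ppm <- runif(k, -cfg$mass_jitter_ppm, cfg$mass_jitter_ppm)
      jitter_mt <- runif(k, -cfg$mt_jitter_min, cfg$mt_jitter_min)
      obs <- rlnorm(k, lm[det, group, week], cfg$sigma_log)
      tibble::tibble(
        sample_id = sample_id, rat_id = rat_id, group = group,
        week = as.integer(week),
        true_id = which(det),
        mass_da = mass[det] * (1 + jitter_ppm * 1e-6),
        mt_min = mt[det] + jitter_mt,
        intensity = obs
      )
    })
    truth <- list(
      peptides = tibble::tibble(
        true_id = seq_len(n), mass_da = mass, mt_min = mt,
        planted = seq_len(n) %in% planted,
        effect = delta
      ),
      expected = tidyr::expand_grid(true_id = seq_len(n), group = arms, week = wk) %>%
        dplyr::mutate(
          log_mean = lm[cbind(.data$true_id, match(.data$group, arms), .data$week)],
          p_detect = pdet[cbind(.data$true_id, match(.data$group, arms), .data$week)]
        )
    )
    structure(list(features = features, samples = samples, truth = truth,
                   config = cfg),
              class = "pep_sim")
  })
}

#' @export
print.pep_sim <- function(x, ...) {
  cat(sprintf("<pep_sim> %d true peptides (%d planted), %d runs, %d feature rows\n",
              nrow(x$truth$peptides), sum(x$truth$peptides$planted),
              nrow(x$samples), nrow(x$features)))
  invisible(x)
}

#' Write a simulated study as per-sample peak-list files
#'
#' Emits one TSV peak list per run (columns `mass_da`, `mt_min`,
#' `intensity`), a `samples.csv` metadata table with a `path` column, and a
#' `truth.json` ground-truth summary — the on-disk form consumed by
#' [read_peaklist()] / [read_sample_table()].
#'
#' @param sim A `pep_sim` from [simulate_peptidome()].
#' @param dir Output directory (created if missing).
#' @return The metadata CSV path, invisibly.
#' @export
write_peaklists <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  by_run <- split(sim$features, sim$features$sample_id)
  paths <- purrr::imap_chr(by_run, function(f, id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    readr::write_tsv(f[, c("mass_da", "mt_min", "intensity")], p, progress = FALSE)
    p
  })
  meta <- dplyr::mutate(sim$samples, path = unname(paths[.data$sample_id]))
  meta_path <- file.path(dir, "samples.csv")
  readr::write_csv(meta, meta_path, progress = FALSE)
  jsonlite::write_json(
    list(n_peptides = nrow(sim$truth$peptides),
         planted_ids = sim$truth$peptides$true_id[sim$truth$peptides$planted],
         config = unclass(sim$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(meta_path)
}

#' Score recovery of planted peptides
#'
#' Matches selected master peptides back to the generator's true peptides
#' (nearest true mass within the matching tolerances) and scores the
#' screening outcome: sensitivity is the fraction of planted peptides
#' recovered by the union of the weekly selections; false selections are
#' selected peptides not matching any planted peptide, counted per week.
#'
#' @param selections Tibble with `week`, `peptide_id` (master ids).
#' @param truth Ground-truth list from [simulate_peptidome()].
#' @param peptides Master peptide table (`pep$peptides`) used to resolve
#'   master ids to masses.
#' @param ppm_tol,mt_tol_min Matching tolerances.
#' @return List with `sensitivity`, `false_by_week` (tibble `week`,
#'   `n_false`), `n_false_total`, `n_recovered`, `n_planted`.
#' @export
evaluate_recovery <- function(selections, truth, peptides,
                              ppm_tol = 50, mt_tol_min = 2) {
  tp <- truth$peptides
  match_true <- function(mass, mt) {
    dev <- ppm_deviation(tp$mass_da, mass)
    ok <- dev < ppm_tol & abs(tp$mt_min - mt) < mt_tol_min
    if (!any(ok)) return(NA_integer_)
    cand <- which(ok)
    cand[which.min(dev[cand])]
  }
  sel <- selections %>%
    dplyr::distinct(.data$week, .data$peptide_id) %>%
    dplyr::left_join(peptides[, c("peptide_id", "mass_da", "mt_min")],
                     by = "peptide_id") %>%
    dplyr::mutate(
      true_id = purrr::map2_int(.data$mass_da, .data$mt_min, match_true),
      is_planted = dplyr::coalesce(tp$planted[.data$true_id], FALSE)
    )
  recovered <- unique(sel$true_id[sel$is_planted])
  false_by_week <- sel %>%
    dplyr::group_by(.data$week) %>%
    dplyr::summarise(n_false = sum(!.data$is_planted), .groups = "drop")
  list(
    sensitivity = length(recovered) / sum(tp$planted),
    false_by_week = false_by_week,
    n_false_total = sum(false_by_week$n_false),
    n_recovered = length(recovered),
    n_planted = sum(tp$planted)
  )
}
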