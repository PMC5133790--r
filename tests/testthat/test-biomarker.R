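test_that("fold change follows the signed-ratio convention", {
  expect_equal(round(fold_change(847.2, 1863.1), 2), -2.20)
  expect_equal(round(fold_change(51010.5, 441.3), 2), 115.59)
  expect_true(is.na(fold_change(0, 482.2)))
  expect_true(is.na(fold_change(482.2, 0)))
  expect_equal(fold_change(7.5, 7.5), 1)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("fold change is antisymmetric with magnitude at least 1", {
  set.seed(31)
  a <- runif(50, 0.1, 1000)
  b <- runif(50, 0.1, 1000)
  f_ab <- fold_change(a, b)
  f_ba <- fold_change(b, a)
  uneq <- a != b
  expect_equal(f_ab[uneq], -f_ba[uneq])
  expect_true(all(abs(f_ab) >= 1))
})

test_that("the loading consensus demands the threshold in every model", {
  make_model <- function(loadings) {
    structure(list(x_loadings = loadings, ncomp = ncol(loadings)),
              class = "splsda")
  }
  L <- matrix(0, 4, 2, dimnames = list(paste0("p", 1:4), NULL))
  L["p1", 2] <- 0.16          # passes on component 2
  L["p2", 1] <- 0.40          # passes strongly
  L["p3", 1] <- 0.10          # never passes
  models <- replicate(5, make_model(L), simplify = FALSE)
  expect_setequal(consensus_biomarkers(models), c("p1", "p2"))
  # one weak model vetoes p2
  L_weak <- L; L_weak["p2", ] <- c(0.10, 0)
  models[[5]] <- make_model(L_weak)
  expect_setequal(consensus_biomarkers(models), "p1")
  # model count and schema checks
  expect_error(consensus_biomarkers(models[1:4]), "expected 5")
  bad <- models
  rownames(bad[[2]]$x_loadings) <- paste0("q", 1:4)
  expect_error(consensus_biomarkers(bad), "schema error")
})

test_that("consensus agrees with brute-force evaluation of the loading tensor", {
  set.seed(17)
  p <- 30
  tensor <- array(rnorm(p * 2 * 5, 0, 0.25), dim = c(p, 2, 5))
  models <- lapply(1:5, function(m) {
    structure(list(x_loadings = matrix(tensor[, , m], p, 2,
                                       dimnames = list(paste0("p", 1:p), NULL)),
                   ncomp = 2), class = "splsda")
  })
  got <- consensus_biomarkers(models, load_threshold = 0.15)
  want <- paste0("p", which(apply(tensor, 1, function(sl) {
    all(apply(abs(matrix(sl, 2, 5)), 2, max) >= 0.15)
  })), recycle0 = TRUE)
  expect_gt(length(want), 0)
  expect_setequal(got, want)
  # monotonicity: raising the threshold never grows the set
  looser <- consensus_biomarkers(models, load_threshold = 0.10)
  expect_true(all(got %in% looser))
})

test_that("group frequency and mean abundance follow the group-week slices", {
  gm <- matrix(c(100, 100, 40, 60), 4, 1,
               dimnames = list(c("NA", "NL", "HA", "HL"), NULL))
  pep <- toy_peptidome(gm, n_rat = 6, sd = 0, seed = 1)
  # knock out detections by hand: 1 of 12 N, all HA, 1 of 6 HL
  pep$abundance[1, 1] <- 0
  pep$abundance[19, 1] <- 0
  expect_equal(round(group_frequency(pep, 1, "N", 2), 1), 91.7)
  expect_equal(round(group_frequency(pep, 1, "HL", 2), 1), 83.3)
  expect_equal(group_frequency(pep, 1, "HA", 2), 100)
  # mean over all collected samples, zeros included
  expect_equal(mean_rel_abundance(pep, 1, "N", 2), 100 * 11 / 12)
  expect_equal(mean_rel_abundance(pep, 1, "HA", 2), 40)
  expect_error(group_frequency(pep, 1, "N", 4), "no samples")
})

test_that("an all-zero group reports frequency 0 and mean 0", {
  gm <- matrix(c(50, 50, 0, 20), 4, 1,
               dimnames = list(c("NA", "NL", "HA", "HL"), NULL))
  pep <- toy_peptidome(gm, sd = 0, seed = 2)
  expect_equal(group_frequency(pep, 1, "HA", 2), 0)
  expect_equal(mean_rel_abundance(pep, 1, "HA", 2), 0)
})

test_that("mean abundance matches brute force on a random fixture", {
  sim <- simulate_peptidome(sim_config(n_peptides = 25, n_planted = 4, seed = 6))
  pep <- compile_peptidome(sim$features)
  long <- tidy(pep)
  for (g in c("N", "HA", "HL")) {
    keep <- (if (g == "N") long$group %in% c("NA", "NL") else long$group == g) &
      long$week == 3 & long$peptide_id == 7
    expect_equal(mean_rel_abundance(pep, 7, g, 3), mean(long$abundance[keep]))
    expect_equal(group_frequency(pep, 7, g, 3), 100 * mean(long$abundance[keep] > 0))
  }
})

test_that("build_panel counts week-rows and unique peptides", {
  sel <- tibble::tibble(week = c(1, 2, 3, 1, 2, 4),
                        peptide_id = c(10, 10, 10, 20, 30, 40))
  panel <- build_panel(sel)
  expect_equal(nrow(panel), 6)
  expect_equal(attr(panel, "unique_peptides"), 4)
  expect_equal(panel_summary(panel)$unique_peptides, 4)
  empty <- build_panel(tibble::tibble(week = integer(), peptide_id = integer()))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "unique_peptides"), 0)
})

test_that("the frequency filter is monotone and uses collected denominators", {
  gm <- matrix(c(10, 10, 200, 100, 0, 0, 50, 30), 4, 2,
               dimnames = list(c("NA", "NL", "HA", "HL"), NULL))
  pep <- toy_peptidome(gm, n_rat = 6, sd = 1, detect_p = 0.4, seed = 5)
  sel <- tibble::tibble(week = 2L, peptide_id = c(1L, 2L))
  loose <- build_panel(sel, pep, min_frequency_pct = 10)
  strict <- build_panel(sel, pep, min_frequency_pct = 60)
  expect_true(all(strict$peptide_id %in% loose$peptide_id))
  expect_lte(nrow(strict), nrow(loose))
  if (nrow(loose)) {
    expect_true(all(pmax(loose$freq_N, loose$freq_HA, loose$freq_HL) > 10))
  }
})

test_that("panel records carry fold changes consistent with their means", {
  gm <- matrix(c(100, 100, 400, 200), 4, 1,
               dimnames = list(c("NA", "NL", "HA", "HL"), NULL))
  pep <- toy_peptidome(gm, sd = 0, seed = 3)
  panel <- build_panel(tibble::tibble(week = 2L, peptide_id = 1L), pep)
  expect_equal(panel$fold_HA, fold_change(panel$mean_ab_HA, panel$mean_ab_N))
  expect_equal(round(panel$fold_HA, 2), 4)
  expect_equal(round(panel$fold_HL, 2), 2)
})

test_that("screening matches a by-hand application of the consensus rule", {
  pep <- separable_peptidome(n_info = 3, n_noise = 20, seed = 8, gap = 15)
  grid <- model_grid(n_peptides = c(3, 5, 10), weeks = 2, schemes = "three_group")
  res <- search_models(pep, grid, seed = 2)
  panel <- screen_biomarkers(pep, res, weeks = 2)
  # the dominant discriminant peptide always survives the consensus
  expect_true(1 %in% panel$peptide_id)
  expect_true(all(c("mean_ab_N", "fold_HA", "fold_HL") %in% names(panel)))
  # selections equal the brute-force rule over the refit five best models
  best <- select_best(res, "three_group", 2, k = 5)
  models <- purrr::map2(best$ncomp, best$n_peptides,
                        ~ fit_splsda(pep, "three_group", week = 2,
                                     ncomp = .x, keep_x = .y))
  pass <- Reduce(`&`, lapply(models, function(m)
    apply(abs(m$x_loadings), 1, max) >= 0.15))
  expect_setequal(as.character(attr(panel, "selections")$peptide_id),
                  names(pass)[pass])
})
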