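test_that("ppm deviation uses the reference mass as denominator", {
  expect_equal(ppm_deviation(1000, 1000.05), 50)
  expect_equal(ppm_deviation(1649.8, 1649.8), 0)
  expect_equal(round(ppm_deviation(1649.8, 1649.9), 1), 60.6)
  expect_error(ppm_deviation(-1, 10), "positive")
})

test_that("the identity rule uses strict tolerances on both axes", {
  f <- function(m, t) list(mass_da = m, mt_min = t)
  expect_true(features_match(f(1000, 37.2), f(1000.04, 38.9)))
  expect_true(features_match(f(1500, 30), f(1500, 30)))
  # 60.6 ppm away: not a match even though time agrees
  expect_false(features_match(f(1649.8, 30), f(1649.9, 30)))
  # time gap exactly 2.0 min: "lower than 2 min" is strict
  expect_false(features_match(f(1000, 37.2), f(1000, 39.2)))
  expect_true(features_match(f(1000, 37.2), f(1000, 39.19)))
})

test_that("internal-standard normalization scales by the median ratio", {
  std <- tibble::tibble(mass_da = c(1000, 2000, 3000), mt_min = c(25, 30, 35),
                        reference_intensity = c(100, 200, 300))
  base <- tibble::tibble(
    sample_id = "S1",
    mass_da = c(1000, 2000, 3000, 1500),
    mt_min = c(25, 30, 35, 28),
    intensity = c(100, 200, 300, 50)
  )
  # all standards at reference: identity
  out <- normalize_runs(base, std)
  expect_equal(out$intensity, base$intensity)
  # all standards at half reference: everything doubled
  half <- dplyr::mutate(base, intensity = intensity / 2)
  out <- normalize_runs(half, std)
  expect_equal(out$intensity, base$intensity)
  # ratios {1.8, 2.0, 2.4} -> median factor 2.0
  skew <- base
  skew$intensity[1:3] <- c(100 / 1.8, 200 / 2.0, 300 / 2.4)
  out <- normalize_runs(skew, std)
  expect_equal(attr(out, "norm_factors")$factor, 2.0)
  expect_equal(out$intensity[4], 100)
})

test_that("a run matching no standard raises a normalization error", {
  std <- tibble::tibble(mass_da = 9000, mt_min = 10, reference_intensity = 1)
  run <- tibble::tibble(sample_id = "S9", mass_da = 1000, mt_min = 30, intensity = 5)
  expect_error(normalize_runs(run, std), "S9")
})

test_that("the identity bypass leaves pre-normalized data untouched", {
  run <- tibble::tibble(sample_id = "S1", mass_da = 1000, mt_min = 30, intensity = 5)
  expect_equal(normalize_runs(run)$intensity, 5)
})

two_run_features <- function(mass2, mt2) {
  tibble::tibble(
    sample_id = c("S1", "S2"), rat_id = c("R1", "R2"),
    group = c("NA", "HA"), week = 1L,
    mass_da = c(1500, mass2), mt_min = c(30, mt2), intensity = c(10, 20)
  )
}

test_that("identical features across two runs compile to one master", {
  pep <- compile_peptidome(two_run_features(1500, 30))
  expect_equal(nrow(pep$peptides), 1)
  expect_equal(as.vector(pep$abundance), c(10, 20))
})

test_that("features exactly 2 minutes apart stay distinct masters", {
  pep <- compile_peptidome(two_run_features(1500, 32))
  expect_equal(nrow(pep$peptides), 2)
})

test_that("jittered features recover the true peptides (brute-force oracle)", {
  set.seed(11)
  true_mass <- c(1000, 1200, 1500, 2500, 9000)
  true_mt <- c(25, 40, 25, 33, 29)
  reps <- 4
  idx <- rep(seq_along(true_mass), each = reps)
  feats <- tibble::tibble(
    sample_id = rep(paste0("S", 1:reps), times = length(true_mass)),
    rat_id = rep(paste0("R", 1:reps), times = length(true_mass)),
    group = "NA", week = 1L,
    mass_da = true_mass[idx] * (1 + runif(20, -25, 25) * 1e-6),
    mt_min = true_mt[idx] + runif(20, -0.5, 0.5),
    intensity = runif(20, 5, 50)
  )
  pep <- compile_peptidome(feats)
  expect_equal(nrow(pep$peptides), 5)
  # membership equals the exhaustive single-linkage components
  oracle <- single_linkage_oracle(feats$mass_da, feats$mt_min)
  expect_equal(length(unique(oracle)), 5)
  # same partition: recompute greedy assignment through the matrix
  expect_true(all(colSums(pep$abundance > 0) == reps))
  expect_equal(sum(pep$abundance), sum(feats$intensity))
})

test_that("greedy clustering matches single linkage on random small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:6, 1)
    true_mass <- sort(runif(k, 900, 20000))
    # enforce separation beyond twice the tolerance
    true_mass <- true_mass * (1 + seq_len(k) * 5e-4)
    true_mt <- runif(k, 20, 45)
    reps <- sample(2:5, 1)
    idx <- rep(seq_len(k), each = reps)
    n <- length(idx)
    feats <- tibble::tibble(
      sample_id = rep(paste0("S", seq_len(reps)), times = k),
      rat_id = rep(paste0("R", seq_len(reps)), times = k),
      group = "NA", week = 1L,
      mass_da = true_mass[idx] * (1 + runif(n, -20, 20) * 1e-6),
      mt_min = true_mt[idx] + runif(n, -0.4, 0.4),
      intensity = runif(n, 1, 100)
    )
    pep <- compile_peptidome(feats)
    oracle_k <- length(unique(single_linkage_oracle(feats$mass_da, feats$mt_min)))
    expect_equal(nrow(pep$peptides), oracle_k)
  }
})

test_that("compilation is idempotent on an already-compiled matrix", {
  sim <- simulate_peptidome(sim_config(n_peptides = 60, n_planted = 6, seed = 3))
  pep <- compile_peptidome(sim$features)
  # one run per sample whose features are the masters themselves
  long <- tidy(pep) %>% dplyr::filter(.data$detected)
  feats2 <- dplyr::transmute(long, sample_id, rat_id, group, week,
                             mass_da, mt_min, intensity = abundance)
  pep2 <- compile_peptidome(feats2)
  expect_equal(nrow(pep2$peptides), nrow(pep$peptides))
  expect_equal(pep2$peptides$mass_da, pep$peptides$mass_da, tolerance = 1e-12)
  expect_equal(sum(pep2$abundance), sum(pep$abundance))
})

test_that("master peptides are mutually distinguishable and conserve intensity", {
  sim <- simulate_peptidome(sim_config(n_peptides = 80, n_planted = 8, seed = 21))
  pep <- compile_peptidome(sim$features)
  m <- pep$peptides$mass_da
  t <- pep$peptides$mt_min
  viol <- 0L
  for (i in seq_along(m)) {
    close_mass <- abs(m - m[i]) / m[i] * 1e6 < 50 & seq_along(m) != i
    viol <- viol + sum(close_mass & abs(t - t[i]) < 2)
  }
  expect_equal(viol, 0L)
  expect_equal(sum(pep$abundance), sum(sim$features$intensity))
  # no all-zero rows
  expect_true(all(rowSums(pep$abundance) > 0))
})

test_that("the abundance matrix round-trips through CSV", {
  sim <- simulate_peptidome(sim_config(n_peptides = 30, n_planted = 3, seed = 2,
                                       rats_per_subgroup = 2, weeks = 2))
  pep <- compile_peptidome(sim$features)
  path <- tempfile(fileext = ".csv")
  write_abundance_matrix(pep, path)
  back <- read_abundance_matrix(path)
  expect_equal(back$samples, pep$samples)
  expect_equal(unname(back$abundance), unname(round(pep$abundance, 10)),
               tolerance = 1e-6)
})

test_that("compiling an empty run list is an input error", {
  expect_error(compile_peptidome(tibble::tibble()), "no runs")
})
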