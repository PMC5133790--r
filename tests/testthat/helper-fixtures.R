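# Shared fixture builders and independent oracles. Everything is generated in
# code; no binary fixtures.

# write a peak-list file from a tibble of rows
write_peak_file <- function(df, delim = "\t", path = tempfile(fileext = ".txt")) {
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  path
}

meta1 <- list(sample_id = "S1", rat_id = "R1", group = "NA", week = 1L)

# hand-built peptidome: n_rat rats per arm, one week, given per-group peptide
# means (matrix groups x peptides), gaussian noise, optional zero inflation
toy_peptidome <- function(group_means, n_rat = 6, week = 2L, sd = 0.05,
                          detect_p = 1, seed = 1) {
  set.seed(seed)
  groups <- rownames(group_means)
  p <- ncol(group_means)
  samples <- tibble::tibble(
    rat_id = sprintf("R%02d", seq_len(n_rat * length(groups))),
    group = rep(groups, each = n_rat),
    week = week
  )
  samples$sample_id <- sprintf("S_%s_w%d", samples$rat_id, samples$week)
  ab <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    mu <- group_means[samples$group[i], ]
    v <- pmax(mu + stats::rnorm(p, 0, sd), 0)
    v * (stats::runif(p) < detect_p)
  }))
  peptides <- tibble::tibble(
    peptide_id = seq_len(p),
    mass_da = seq(1000, by = 50, length.out = p),
    mt_min = seq(20, by = 0.3, length.out = p)
  )
  peptidome(samples[, c("sample_id", "rat_id", "group", "week")], peptides, ab)
}

# well-separated 3-group peptidome: the first `n_info` peptides carry the
# signal. With n_info >= 2 the HA and HL effects live on different peptides so
# the classes span two dimensions; with n_info = 1 all three classes sit on a
# single axis (HL midway).
separable_peptidome <- function(n_info = 5, n_noise = 25, n_rat = 6, seed = 1,
                                week = 2L, gap = 10) {
  p <- n_info + n_noise
  gm <- matrix(5, 4, p, dimnames = list(c("NA", "NL", "HA", "HL"), NULL))
  if (n_info == 1) {
    gm["HA", 1] <- 5 + gap
    gm["HL", 1] <- 5 + gap / 2
  } else {
    ha_set <- seq_len(ceiling(n_info / 2))
    hl_set <- setdiff(seq_len(n_info), ha_set)
    gm["HA", ha_set] <- 5 + gap
    gm["HL", hl_set] <- 5 + gap
  }
  toy_peptidome(gm, n_rat = n_rat, week = week, sd = 0.2, seed = seed)
}

# independent dense PLS2 oracle: per component, the dominant eigenvector of
# (X^T Y)(X^T Y)^T via eigen(), with regression deflation — no NIPALS
dense_pls_oracle <- function(X, y, ncomp) {
  y <- factor(y, levels = unique(as.character(y)))
  n <- nrow(X)
  Y <- matrix(0, n, nlevels(y))
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  Y <- sweep(Y, 2, colMeans(Y))
  sds <- apply(X, 2, stats::sd); sds[sds == 0] <- 1
  Xh <- scale(X, TRUE, sds)
  A <- matrix(0, ncol(X), ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Y)
    a <- eigen(M %*% t(M), symmetric = TRUE)$vectors[, 1]
    j <- which.max(abs(a)); if (a[j] < 0) a <- -a
    A[, h] <- a
    t_h <- Xh %*% a; tt <- sum(t_h^2)
    Xh <- Xh - t_h %*% t(crossprod(Xh, t_h) / tt)
    Y <- Y - t_h %*% t(crossprod(Y, t_h) / tt)
  }
  A
}

# exhaustive single-linkage clustering under the identity rule (tiny n only):
# connected components of the symmetric "features match" graph via union-find
single_linkage_oracle <- function(mass, mt, ppm_tol = 50, mt_tol_min = 2) {
  n <- length(mass)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      match_ij <- (abs(mass[j] - mass[i]) / mass[i] * 1e6 < ppm_tol ||
                   abs(mass[i] - mass[j]) / mass[j] * 1e6 < ppm_tol) &&
        abs(mt[i] - mt[j]) < mt_tol_min
      if (match_ij) parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, integer(1))
}
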