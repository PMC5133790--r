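#' Read a per-sample CE-MS peak list
#'
#' Parses one delimited peak-list file (the triplet of peptide molecular mass
#' in Da, normalized CE migration time in minutes, and normalized signal
#' intensity in ion counts) and attaches the sample's metadata. The delimiter
#' (tab, comma or semicolon) is sniffed from the header line, and column names
#' are matched loosely (`mass_da`/`mass`/`peptide_mass`, `mt_min`/`cetime`/
#' `migration_time`, `intensity`/`signal_intensity`/`abundance`).
#'
#' Rows that cannot be used are not dropped silently: non-numeric cells and
#' values outside the instrument's reporting range (mass 800–30000 Da,
#' positive migration time, non-negative intensity) are collected into a
#' per-row rejection report returned as the `"rejected"` attribute.
#'
#' @param path Path to a delimited text peak list with a header row.
#' @param sample_meta A one-row data frame (or named list) with `sample_id`,
#'   `rat_id`, `group` (one of NA/NL/HA/HL) and `week` (1–4).
#' @return A tibble of features with columns `sample_id`, `rat_id`, `group`,
#'   `week`, `mass_da`, `mt_min`, `intensity`; rejected rows (if any) in
#'   `attr(, "rejected")` as a tibble with `line` and `reason`.
#' @export
read_peaklist <- function(path, sample_meta) {
  sample_meta <- as.list(sample_meta)
  required <- c("sample_id", "rat_id", "group", "week")
  if (!all(required %in% names(sample_meta))) {
    abort(paste0("sample_meta must provide ", paste(required, collapse = ", ")))
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort(paste0("empty peak-list file: ", path))
  delim <- .sniff_delim(header)
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  cols <- .match_peak_columns(names(raw))
  raw <- raw[, unname(cols)]
  names(raw) <- names(cols)

  n <- nrow(raw)
  parsed <- purrr::map(raw, ~ suppressWarnings(as.numeric(.x)))
  reasons <- character(n)
  if (n > 0) {
    bad_num <- purrr::imap(parsed, function(v, nm) is.na(v) & !is.na(raw[[nm]]))
    for (nm in names(bad_num)) {
      hit <- bad_num[[nm]] & reasons == ""
      reasons[hit] <- paste0("non-numeric ", nm)
    }
    with_vals <- reasons == ""
    chk <- function(ok, why) {
      bad <- with_vals & !ok & reasons == ""
      reasons[bad] <<- why
    }
    chk(!is.na(parsed$mass_da) & parsed$mass_da >= 800 & parsed$mass_da <= 30000,
        "mass_da outside [800, 30000] Da")
    chk(!is.na(parsed$mt_min) & parsed$mt_min > 0, "mt_min not positive")
    chk(!is.na(parsed$intensity) & parsed$intensity >= 0, "negative intensity")
  }
  keep <- reasons == ""
  out <- tibble::tibble(
    sample_id = as.character(sample_meta$sample_id),
    rat_id = as.character(sample_meta$rat_id),
    group = as.character(sample_meta$group),
    week = as.integer(sample_meta$week),
    mass_da = parsed$mass_da[keep],
    mt_min = parsed$mt_min[keep],
    intensity = parsed$intensity[keep]
  )
  rejected <- tibble::tibble(line = which(!keep) + 1L, reason = reasons[!keep])
  attr(out, "rejected") <- rejected
  out
}

.sniff_delim <- function(header) {
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              ";"  = lengths(regmatches(header, gregexpr(";", header))),
              ","  = lengths(regmatches(header, gregexpr(",", header))))
  if (all(counts == 0)) return("\t")
  names(counts)[which.max(counts)]
}

.match_peak_columns <- function(nms) {
  norm <- gsub("[^a-z0-9]", "", tolower(nms))
  find <- function(cands, what) {
    i <- which(norm %in% cands)
    if (length(i) == 0) {
      abort(paste0("peak-list format error: no column for ", what,
                   " among: ", paste(nms, collapse = ", ")))
    }
    i[1]
  }
  c(mass_da = find(c("massda", "mass", "peptidemass", "peptidemassda", "molecularmass"),
                   "peptide mass (Da)"),
    mt_min = find(c("mtmin", "mt", "migrationtime", "migrationtimemin", "cetime",
                    "cetimemin", "time", "timemin"), "CE migration time (min)"),
    intensity = find(c("intensity", "signalintensity", "ioncounts", "abundance",
                       "relativeabundance"), "signal intensity"))
}

#' Read a samples metadata table
#'
#' Reads the CSV that maps each sample to its rat, treatment group and
#' collection week. Parsed with no missing-value strings so the group label
#' `"NA"` (standard diet and water) survives as text.
#'
#' @param path CSV with columns `sample_id`, `rat_id`, `group`, `week` (and
#'   optionally `path` pointing at the sample's peak-list file).
#' @return A tibble, `week` as integer.
#' @export
read_sample_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = character(), progress = FALSE, show_col_types = FALSE)
  need <- c("sample_id", "rat_id", "group", "week")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("samples table missing columns: ",
                                 paste(miss, collapse = ", ")))
  x$week <- as.integer(x$week)
  bad <- setdiff(unique(x$group), .GROUPS4)
  if (length(bad)) abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  x
}

#' Bin features into a CE-MS fingerprint grid
#'
#' Builds the classic urinary-peptidome fingerprint: CE migration time (min)
#' against molecular mass (kDa, log10 scale), with each cell holding the mean
#' signal intensity over a set of runs. A feature absent from a run counts as
#' zero, so a cell's value is the summed intensity landing in it divided by
#' the number of runs. Bins are half-open `[lo, hi)`; the top edge is nudged
#' up by a relative 1e-9 so the maximal feature is binned.
#'
#' @param features Feature tibble (`sample_id`, `mass_da`, `mt_min`,
#'   `intensity`), e.g. from [read_peaklist()] rows bound together.
#' @param n_time_bins,n_mass_bins Positive bin counts.
#' @param runs Character vector of run (sample) ids to average over; defaults
#'   to the runs present in `features`. Supplying it lets all-empty runs
#'   contribute to the denominator.
#' @param time_range,logmass_range Optional length-2 ranges (minutes;
#'   log10 kDa). Default to the data range.
#' @return A `fingerprint_grid`: list with `time_edges`, `logmass_edges`,
#'   `values` (time bins x mass bins) and `n_runs`.
#' @export
fingerprint <- function(features, n_time_bins = 40, n_mass_bins = 40,
                        runs = NULL, time_range = NULL, logmass_range = NULL) {
  if (n_time_bins < 1 || n_mass_bins < 1) {
    abort("bin counts must be positive integers")
  }
  if (is.null(runs)) runs <- unique(features$sample_id)
  if (length(runs) == 0) abort("fingerprint needs at least one run")
  features <- dplyr::filter(features, .data$sample_id %in% runs)
  logmass <- log10(features$mass_da / 1000)  # kDa on log10 scale
  edges <- function(r, n) {
    e <- seq(r[1], r[2], length.out = n + 1)
    e[n + 1] <- e[n + 1] + abs(e[n + 1]) * 1e-9 + 1e-12
    e
  }
  if (is.null(time_range)) {
    time_range <- if (nrow(features)) range(features$mt_min) else c(19, 47)
  }
  if (is.null(logmass_range)) {
    logmass_range <- if (nrow(features)) range(logmass) else log10(c(0.8, 30))
  }
  te <- edges(time_range, n_time_bins)
  me <- edges(logmass_range, n_mass_bins)
  ti <- findInterval(features$mt_min, te, rightmost.closed = FALSE)
  mi <- findInterval(logmass, me, rightmost.closed = FALSE)
  ok <- ti >= 1 & ti <= n_time_bins & mi >= 1 & mi <= n_mass_bins
  vals <- matrix(0, n_time_bins, n_mass_bins)
  if (any(ok)) {
    sums <- tapply(features$intensity[ok],
                   list(factor(ti[ok], 1:n_time_bins), factor(mi[ok], 1:n_mass_bins)),
                   sum)
    sums[is.na(sums)] <- 0
    vals <- unclass(sums)
  }
  structure(
    list(time_edges = te, logmass_edges = me,
         values = vals / length(runs), n_runs = length(runs)),
    class = "fingerprint_grid"
  )
}

#' @export
print.fingerprint_grid <- function(x, ...) {
  cat(sprintf("<fingerprint_grid> %d time x %d log-mass bins over %d run(s)\n",
              nrow(x$values), ncol(x$values), x$n_runs))
  cat(sprintf("  time %.1f-%.1f min, mass %.2f-%.2f kDa, total intensity %.1f\n",
              min(x$time_edges), max(x$time_edges),
              10^min(x$logmass_edges), 10^max(x$logmass_edges),
              sum(x$values) * x$n_runs))
  invisible(x)
}

#' @rdname fingerprint
#' @param x A `fingerprint_grid`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fingerprint_grid <- function(x, ...) {
  nt <- nrow(x$values); nm <- ncol(x$values)
  tibble::tibble(
    mt_min = rep((x$time_edges[-(nt + 1)] + x$time_edges[-1]) / 2, times = nm),
    logmass_kda = rep((x$logmass_edges[-(nm + 1)] + x$logmass_edges[-1]) / 2,
                      each = nt),
    mean_intensity = as.vector(x$values)
  )
}

#' @rdname fingerprint
#' @param object A `fingerprint_grid`.
#' @exportS3Method ggplot2::autoplot
autoplot.fingerprint_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mt_min, .data$logmass_kda,
                                   fill = .data$mean_intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mean intensity") +
    ggplot2::labs(x = "CE migration time (min)",
                  y = expression(log[10] ~ "mass (kDa)"))
}

# Table-2-style column order for the biomarker report
.REPORT_COLS <- c("week", "peptide_id", "mass_da", "mt_min", "protein",
                  "mean_ab_N", "freq_N", "mean_ab_HA", "freq_HA",
                  "mean_ab_HL", "freq_HL", "fold_HA", "fold_HL")

#' Write / read the biomarker panel report
#'
#' Renders biomarker records in the published layout: one row per
#' (week, peptide), mass and migration time to 1 decimal, per-group mean
#' relative abundance and detection frequency to 1 decimal, signed fold
#' changes to 2 decimals, and `"na"` where a fold change is undefined because
#' a group mean is zero.
#'
#' @param records Tibble of biomarker records (see [build_panel()]); an
#'   optional `protein` annotation column is carried through.
#' @param path Output CSV path.
#' @return `write_biomarker_report()` returns `path` invisibly;
#'   `read_biomarker_report()` returns the records tibble with numeric fold
#'   columns (`NA` where the file says `"na"`).
#' @export
write_biomarker_report <- function(records, path) {
  if (!"protein" %in% names(records)) records$protein <- ""
  fmt1 <- function(x) formatC(x, format = "f", digits = 1)
  fmt_fold <- function(x) ifelse(is.na(x), "na", formatC(x, format = "f", digits = 2))
  out <- tibble::tibble(
    week = as.integer(records$week),
    peptide_id = records$peptide_id,
    mass_da = fmt1(records$mass_da),
    mt_min = fmt1(records$mt_min),
    protein = records$protein,
    mean_ab_N = fmt1(records$mean_ab_N), freq_N = fmt1(records$freq_N),
    mean_ab_HA = fmt1(records$mean_ab_HA), freq_HA = fmt1(records$freq_HA),
    mean_ab_HL = fmt1(records$mean_ab_HL), freq_HL = fmt1(records$freq_HL),
    fold_HA = fmt_fold(records$fold_HA), fold_HL = fmt_fold(records$fold_HL)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_report
#' @export
read_biomarker_report <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = character(), progress = FALSE, show_col_types = FALSE)
  miss <- setdiff(setdiff(.REPORT_COLS, "protein"), names(x))
  if (length(miss)) abort(paste0("report missing columns: ", paste(miss, collapse = ", ")))
  num <- function(v) as.numeric(v)
  fold <- function(v) suppressWarnings(ifelse(v == "na", NA_real_, as.numeric(v)))
  tibble::tibble(
    week = as.integer(x$week),
    peptide_id = as.integer(x$peptide_id),
    mass_da = num(x$mass_da), mt_min = num(x$mt_min),
    protein = if ("protein" %in% names(x)) x$protein else "",
    mean_ab_N = num(x$mean_ab_N), freq_N = num(x$freq_N),
    mean_ab_HA = num(x$mean_ab_HA), freq_HA = num(x$freq_HA),
    mean_ab_HL = num(x$mean_ab_HL), freq_HL = num(x$freq_HL),
    fold_HA = fold(x$fold_HA), fold_HL = fold(x$fold_HL)
  )
}
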