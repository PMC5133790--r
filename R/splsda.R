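#' Soft-thresholding operator
#'
#' Elementwise `sign(v) * max(|v| - delta, 0)` — the operator that makes a
#' PLS loading sparse. Inside [splsda()], `delta` is chosen per component as
#' the `(keep_x + 1)`-th largest absolute entry, the smallest value leaving
#' at most `keep_x` nonzeros.
#'
#' @param v Numeric vector.
#' @param delta Non-negative threshold.
#' @return Thresholded vector.
#' @export
#' @examples
#' soft_threshold(c(0.5, -0.3, 0.1), 0.2)
soft_threshold <- function(v, delta) {
  if (delta < 0) abort("delta must be non-negative")
  sign(v) * pmax(abs(v) - delta, 0)
}

#' Sparse partial least squares-discriminant analysis
#'
#' From-scratch sPLS-DA: NIPALS partial least squares against a
#' column-centered one-hot class indicator, with per-component
#' soft-thresholding of the X-loading to at most `keep_x` nonzero peptides,
#' and regression-mode deflation of both blocks. Columns of `x` are centered
#' and scaled to unit variance (zero-variance columns keep scale 1, earning
#' zero loadings naturally). Latent scores are mutually orthogonal; each
#' loading column has unit Euclidean norm and its largest-magnitude entry is
#' made positive so loadings are comparable across refits.
#'
#' Classification is by nearest class centroid in latent score space.
#'
#' @param x Numeric matrix, samples x peptides (column names kept).
#' @param y Class labels (factor or character), one per row of `x`; the
#'   level order fixes the deterministic tie-break in prediction.
#' @param ncomp Number of latent components; at most `nlevels(y) - 1`.
#' @param keep_x Number of peptides retained per component (scalar, applied
#'   to every component), in `[1, ncol(x)]`. `keep_x = ncol(x)` recovers
#'   dense PLS-DA.
#' @param log1p Apply `log1p()` to the abundances before scaling.
#' @param max_iter,tol NIPALS iteration cap and convergence tolerance on the
#'   X-loading.
#' @return An object of class `splsda` with elements `x_loadings` (p x
#'   ncomp), `y_loadings` (classes x ncomp regression loadings), `x_scores`
#'   (n x ncomp), `centroids` (classes x ncomp), `proj` (deflation
#'   loadings), `rotation`, `x_center`, `x_scale`, `classes`, `keep_x`,
#'   `ncomp`, `log1p`.
#' @export
splsda <- function(x, y, ncomp = 2, keep_x = ncol(x), log1p = FALSE,
                   max_iter = 500, tol = 1e-9) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  y <- droplevels(y)
  classes <- levels(y)
  n <- nrow(x); p <- ncol(x); K <- length(classes)
  if (length(y) != n) abort("length(y) must match nrow(x)")
  if (K < 2) abort("degenerate input: y has a single class")
  if (ncomp > K - 1) {
    abort(sprintf("parameter error: ncomp (%d) exceeds n_classes - 1 (%d)",
                  ncomp, K - 1))
  }
  if (n <= ncomp) abort("need more samples than components")
  if (keep_x < 1 || keep_x > p) abort("keep_x must lie in [1, ncol(x)]")
  if (log1p) x <- log1p(x)

  x_center <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  x_scale <- ifelse(sds > 0, sds, 1)
  Xh <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  Y <- matrix(0, n, K, dimnames = list(NULL, classes))
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  Yh <- sweep(Y, 2, colMeans(Y))
  X0 <- Xh

  A <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  D <- matrix(0, K, ncomp, dimnames = list(classes, NULL))
  Tm <- matrix(0, n, ncomp)
  iters <- integer(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)
    if (sum(M^2) < .Machine$double.eps) {
      abort(sprintf("no X-Y covariance left at component %d; reduce ncomp", h))
    }
    q <- svd(M, nu = 0, nv = 1)$v[, 1]
    a_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      v <- drop(M %*% q)
      delta <- if (keep_x < p) sort(abs(v), decreasing = TRUE)[keep_x + 1] else 0
      a <- soft_threshold(v, delta)
      a <- a / sqrt(sum(a^2))
      q <- drop(crossprod(M, a))
      q <- q / sqrt(sum(q^2))
      # direction convergence (sign-insensitive)
      if (min(max(abs(a - a_old)), max(abs(a + a_old))) < tol) break
      a_old <- a
    }
    iters[h] <- it
    j <- which.max(abs(a))
    if (a[j] < 0) a <- -a
    t_h <- drop(Xh %*% a)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xh, t_h)) / tt
    d_h <- drop(crossprod(Yh, t_h)) / tt
    Xh <- Xh - tcrossprod(t_h, p_h)
    Yh <- Yh - tcrossprod(t_h, d_h)
    A[, h] <- a; P[, h] <- p_h; D[, h] <- d_h; Tm[, h] <- t_h
  }
  rotation <- A %*% solve(crossprod(P, A))
  centroids <- rowsum(Tm, y) / as.vector(table(y)[classes])
  structure(
    list(x_loadings = A, y_loadings = D, x_scores = Tm, proj = P,
         rotation = rotation, centroids = centroids[classes, , drop = FALSE],
         x_center = x_center, x_scale = x_scale, classes = classes,
         y = y, ncomp = ncomp, keep_x = keep_x, log1p = log1p,
         n_iter = iters),
    class = "splsda"
  )
}

#' @export
print.splsda <- function(x, ...) {
  cat(sprintf("<splsda> %d classes (%s), %d component(s), keep_x = %d\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$ncomp, x$keep_x))
  cat(sprintf("  peptides with a nonzero loading: %d of %d\n",
              length(selected_peptides(x)), nrow(x$x_loadings)))
  invisible(x)
}

#' Peptides carrying any nonzero loading
#'
#' The distinct-variable count of a fitted model: peptides with a nonzero
#' loading on at least one component (the panel-size notion used when a
#' model is described by its "number of peptides").
#'
#' @param model A fitted [splsda] model.
#' @return Character vector of peptide (column) names.
#' @export
selected_peptides <- function(model) {
  rownames(model$x_loadings)[rowSums(model$x_loadings != 0) > 0]
}

#' Predict classes or latent scores for new samples
#'
#' Projects new samples with the training centering/scaling and rotation and
#' assigns each to the class of the nearest centroid (Euclidean distance in
#' score space); exact ties go to the first class in training label order.
#'
#' @param object A fitted [splsda] model.
#' @param newdata Matrix with the training peptide set (columns matched by
#'   name when named).
#' @param type `"class"` (default) or `"scores"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or a score matrix.
#' @export
predict.splsda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(rownames(object$x_loadings), colnames(newdata))
    if (length(miss)) {
      abort(paste0("schema error: newdata lacks training peptides: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    newdata <- newdata[, rownames(object$x_loadings), drop = FALSE]
  } else if (ncol(newdata) != nrow(object$x_loadings)) {
    abort("schema error: newdata has a different peptide count than training")
  }
  if (object$log1p) newdata <- log1p(newdata)
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  scores <- Xs %*% object$rotation
  if (type == "scores") return(scores)
  d2 <- outer(rowSums(scores^2), rowSums(object$centroids^2), "+") -
    2 * scores %*% t(object$centroids)
  # round off float fuzz so exact ties resolve to the first training class
  d2 <- round(d2, 10)
  factor(object$classes[apply(d2, 1, which.min)], levels = object$classes)
}

#' @rdname splsda
#' @param object,... Fitted model (for `tidy`/`glance`) and unused extras.
#' @exportS3Method generics::tidy
tidy.splsda <- function(x, ...) {
  tibble::tibble(
    peptide = rep(rownames(x$x_loadings), times = x$ncomp),
    component = rep(seq_len(x$ncomp), each = nrow(x$x_loadings)),
    loading = as.vector(x$x_loadings)
  )
}

#' @rdname splsda
#' @exportS3Method generics::glance
glance.splsda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    ncomp = x$ncomp,
    keep_x = x$keep_x,
    n_peptides_total = nrow(x$x_loadings),
    n_peptides_selected = length(selected_peptides(x)),
    max_abs_loading = max(abs(x$x_loadings))
  )
}

#' @rdname splsda
#' @exportS3Method ggplot2::autoplot
autoplot.splsda <- function(object, ...) {
  df <- tibble::tibble(
    comp1 = object$x_scores[, 1],
    comp2 = if (object$ncomp >= 2) object$x_scores[, 2] else 0,
    class = object$y
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$comp1, .data$comp2, colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.9, na.rm = TRUE) +
    ggplot2::labs(x = "component 1", y = "component 2", colour = "group")
}

#' Class labels under a grouping scheme
#'
#' The three grouping schemes of the analysis: the four treatment arms
#' (NA/NL/HA/HL), the merged three-group scheme (N = NA+NL vs HA vs HL,
#' motivated by near-identical peptide profiles of the two standard-diet
#' arms), and the sixteen treatment-by-week groups used by the all-weeks
#' model.
#'
#' @param samples Samples tibble (`group`, `week`).
#' @param scheme `"four_group"`, `"three_group"`, or `"sixteen_group"`.
#' @return Factor with a fixed level order (groups, then weeks).
#' @export
group_labels <- function(samples,
                         scheme = c("three_group", "four_group", "sixteen_group")) {
  scheme <- match.arg(scheme)
  g <- samples$group
  if (scheme == "three_group") {
    lab <- ifelse(g %in% c("NA", "NL"), "N", g)
    return(factor(lab, levels = .GROUPS3))
  }
  if (scheme == "four_group") return(factor(g, levels = .GROUPS4))
  lab <- paste0(g, ".w", samples$week)
  lev <- as.vector(outer(.GROUPS4, sort(unique(samples$week)),
                         function(a, b) paste0(a, ".w", b)))
  factor(lab, levels = lev)
}

#' Fit an sPLS-DA model on a peptidome slice
#'
#' Convenience wrapper: restricts the peptidome to a week (for the weekly
#' schemes), derives class labels under the grouping scheme, and fits
#' [splsda()].
#'
#' @param pep A [peptidome].
#' @param scheme Grouping scheme (see [group_labels()]).
#' @param week Week to analyse (required for the weekly schemes, ignored for
#'   `"sixteen_group"`).
#' @inheritParams splsda
#' @return A fitted `splsda` model.
#' @export
fit_splsda <- function(pep, scheme = "three_group", week = NULL,
                       ncomp = 2, keep_x = 15, log1p = FALSE) {
  if (scheme != "sixteen_group") {
    if (is.null(week)) abort("weekly schemes need a week")
    pep <- filter_samples(pep, week = week)
  }
  y <- group_labels(pep$samples, scheme)
  splsda(pep$abundance, y, ncomp = ncomp, keep_x = keep_x, log1p = log1p)
}
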