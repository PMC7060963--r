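#' Count matrix with sample design
#'
#' Entry point of the expression arm: an integer gene x sample count
#' matrix plus a sample-to-group design.
#'
#' @param counts Non-negative integer matrix, genes x samples, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param design Data frame with columns `sample` and `group` covering
#'   every column of `counts`.
#' @param truth Optional generator ground truth.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design, truth = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts needs unique rownames (gene ids)")
  if (is.null(colnames(counts))) stop("counts needs colnames (sample ids)")
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (!all(colnames(counts) %in% design$sample))
    stop("every sample must have a group in the design")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  structure(list(counts = counts, design = design, truth = truth),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$design$group))
  invisible(x)
}

.as_counts <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else counts
}

.groups_of <- function(counts, groups = NULL) {
  if (is.null(groups)) {
    if (inherits(counts, "count_matrix"))
      groups <- stats::setNames(counts$design$group, counts$design$sample)
    else stop("supply `groups` when counts is a bare matrix")
  }
  m <- .as_counts(counts)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m))
    stop("groups must cover every sample column")
  stats::setNames(as.character(groups), colnames(m))
}

#' Median-of-ratios size factors
#'
#' The per-sample normalization factor is the median, over genes with a
#' positive geometric mean across samples, of the ratio of the sample's
#' count to that geometric mean (computed, as is conventional, as the
#' exponential of the median log ratio). Factors are reported unscaled.
#' Within one matrix, a sample whose counts are c times another's gets a
#' factor c times as large, so normalized counts are unaffected by
#' library size.
#'
#' @param counts A [count_matrix()] or bare matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(4, 9), 1, dimnames = list("g1", c("s1", "s2")))
#' size_factors(m)   # 4/6, 9/6
#' @export
size_factors <- function(counts) {
  m <- .as_counts(counts)
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; size factors undefined")
  apply(m[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo[use])))
}

#' Normalized counts
#'
#' @param counts A [count_matrix()] or bare matrix.
#' @param sf Size factors; computed with [size_factors()] if missing.
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  m <- .as_counts(counts)
  sweep(m, 2, sf, "/")
}

#' Log2 fold change of median-normalized means
#'
#' `log2((mean normalized count in treatment + pc) / (mean normalized
#' count in control + pc))` per gene; the pseudocount keeps the estimate
#' finite for genes that drop to zero.
#'
#' @param counts A [count_matrix()] or bare matrix.
#' @param groups Named group vector (taken from the design if `counts` is a
#'   [count_matrix()]).
#' @param contrast Character pair `c(treatment, control)`.
#' @param pseudocount Added to both means (default 1).
#' @param sf Size factors (computed if missing).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2fc_median_norm <- function(counts, groups = NULL, contrast,
                               pseudocount = 1, sf = size_factors(counts)) {
  m <- .as_counts(counts)
  groups <- .groups_of(counts, groups)[colnames(m)]
  if (!all(contrast %in% groups))
    stop("contrast names a group with no samples: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  z <- normalize_counts(m, sf)
  mt <- rowMeans(z[, groups == contrast[1], drop = FALSE])
  mc <- rowMeans(z[, groups == contrast[2], drop = FALSE])
  log2((mt + pseudocount) / (mc + pseudocount))
}

#' Per-gene negative-binomial dispersion by method of moments
#'
#' On normalized counts `z_s = y_s / sf_s`, the squared residual around the
#' gene's group mean has expectation
#' `(1 - 1/n_g) * (mu_g / sf_s + alpha * mu_g^2)` under the NB model
#' (`Var(y) = m + alpha m^2`). Equating the summed squared residuals with
#' this expectation and solving for `alpha` gives
#' `alpha = (RSS - sum w_s mu_g / sf_s) / (sum w_s mu_g^2)` with
#' `w_s = 1 - 1/n_g`.
#'
#' With the few residual degrees of freedom of a typical design the raw
#' per-gene moment estimate is very noisy, and plugging it into a
#' likelihood-ratio test makes the test anticonservative (genes whose
#' dispersion is underestimated by chance get inflated statistics) while
#' simultaneously costing power on genes whose dispersion is
#' overestimated. The estimator therefore applies the standard
#' empirical-Bayes remedy: each gene's raw estimate is shrunk toward the
#' cross-gene center (the median raw estimate) with weights proportional
#' to the residual degrees of freedom `d = n - k` against a prior weight
#' of `prior_df` (default 10), the same moderation idea used throughout
#' the field's DE tools. Set `prior_df = 0` for the unmoderated per-gene
#' estimator. Estimates are floored at `1e-8`.
#'
#' @param y Counts (genes x samples).
#' @param sf Size factors.
#' @param group Group label per sample.
#' @param prior_df Prior degrees of freedom for shrinkage toward the
#'   cross-gene median (default 10; 0 disables moderation).
#' @return Per-gene dispersion vector (>= 1e-8).
#' @export
estimate_dispersion <- function(y, sf, group, prior_df = 10) {
  group <- as.factor(group)
  z <- sweep(y, 2, sf, "/")
  k <- nlevels(group)
  s <- ncol(y)
  if (s - k < 1) stop("need more samples than groups to estimate dispersion")
  gm <- vapply(levels(group), function(g)
    rowMeans(z[, group == g, drop = FALSE]), numeric(nrow(y)))
  gm <- matrix(gm, nrow = nrow(y))
  fitted <- gm[, as.integer(group), drop = FALSE]
  n_g <- as.numeric(table(group))[as.integer(group)]
  w <- 1 - 1 / n_g
  rss <- rowSums((z - fitted)^2)
  pois_part <- rowSums(sweep(fitted, 2, w / sf, "*"))
  quad_part <- rowSums(sweep(fitted^2, 2, w, "*"))
  alpha <- (rss - pois_part) / quad_part
  alpha[!is.finite(alpha)] <- 0
  if (prior_df > 0 && nrow(y) > 1) {
    d <- s - k
    center <- stats::median(alpha)
    alpha <- (d * alpha + prior_df * center) / (d + prior_df)
  }
  pmax(alpha, 1e-8)
}

# Vectorized ML estimate of per-gene NB means with size-factor offsets at
# fixed per-gene dispersion: solves sum_s [y/mu - sf(1+alpha*y)/(1+alpha*sf*mu)] = 0
# by Newton iteration on log(mu).
.nb_fit_mu <- function(y, sf, alpha, iter = 50) {
  rs <- rowSums(y)
  mu <- rs / sum(sf)
  pos <- rs > 0
  if (!any(pos)) return(mu)
  for (it in seq_len(iter)) {
    asf <- outer(alpha * mu, sf)             # alpha_g * mu_g * sf_s
    b <- 1 + asf
    num <- sweep(1 + sweep(y, 1, alpha, "*"), 2, sf, "*")
    g <- rs / mu - rowSums(num / b)
    gp <- -rs / mu^2 + rowSums(num * sweep(1 / b^2, 1, alpha, "*") *
                                 rep(sf, each = nrow(y)))
    step <- g / (gp * mu)                    # Newton step in log(mu)
    step[!is.finite(step) | !pos] <- 0
    step <- pmin(pmax(step, -2), 2)
    mu <- mu * exp(-step)
    if (max(abs(step)) < 1e-12) break
  }
  mu[!pos] <- 0
  mu
}

# NB log likelihood up to per-gene terms that do not depend on mu
# (they cancel in the likelihood ratio because alpha is held fixed).
.nb_partial_ll <- function(y, sf, alpha, mu) {
  m <- outer(mu, sf)
  am <- sweep(m, 1, alpha, "*")
  t1 <- ifelse(y > 0, y * (log(m) - log1p(am)), 0)
  t2 <- sweep(log1p(am), 1, alpha, "/")
  rowSums(t1 - t2)
}

#' Per-gene negative-binomial likelihood-ratio test
#'
#' For each gene: estimate the NB dispersion by method of moments across
#' the contrast's samples, fit the mean under the null (one mean, with
#' size-factor offsets) and the alternative (one mean per group) by
#' maximum likelihood at that fixed dispersion, and refer twice the
#' log-likelihood ratio to chi-square with 1 df. Genes with zero counts in
#' all samples of the contrast get `p = 1` by convention.
#'
#' @inheritParams log2fc_median_norm
#' @param alpha Optional fixed per-gene dispersion vector; estimated if
#'   `NULL`.
#' @return Named numeric vector of per-gene p-values.
#' @export
nb_lrt_test <- function(counts, groups = NULL, contrast,
                        sf = size_factors(counts), alpha = NULL) {
  m <- .as_counts(counts)
  groups <- .groups_of(counts, groups)[colnames(m)]
  keep <- groups %in% contrast
  y <- m[, keep, drop = FALSE]
  g <- factor(groups[keep], levels = contrast)
  if (any(table(g) < 2)) stop("each contrast group needs >= 2 samples")
  sfs <- sf[keep]
  if (is.null(alpha)) alpha <- estimate_dispersion(y, sfs, g)
  mu0 <- .nb_fit_mu(y, sfs, alpha)
  ll0 <- .nb_partial_ll(y, sfs, alpha, mu0)
  ll1 <- numeric(nrow(y))
  for (lev in levels(g)) {
    sel <- g == lev
    mu_g <- .nb_fit_mu(y[, sel, drop = FALSE], sfs[sel], alpha)
    ll1 <- ll1 + .nb_partial_ll(y[, sel, drop = FALSE], sfs[sel], alpha, mu_g)
  }
  lrt <- pmax(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p[rowSums(y) == 0] <- 1
  stats::setNames(p, rownames(y))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity (cumulative minimum from
#' the largest rank); ties share their adjusted value and results are
#' capped at 1. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression table for one contrast
#'
#' The full per-contrast chain: median-of-ratios size factors, base mean of
#' normalized counts, log2 fold change of normalized group means, NB
#' likelihood-ratio p-values and BH q-values. Genes with zero counts in
#' every sample are dropped before testing (their count is recorded in the
#' `n_dropped` attribute).
#'
#' @inheritParams log2fc_median_norm
#' @return A data frame of class `de_table` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `p_value`, `q_value`; attributes `contrast`
#'   and `n_dropped`.
#' @export
de_table <- function(counts, groups = NULL, contrast, pseudocount = 1) {
  m <- .as_counts(counts)
  groups <- .groups_of(counts, groups)[colnames(m)]
  keep_samples <- groups %in% contrast
  nonzero <- rowSums(m[, keep_samples, drop = FALSE]) > 0
  n_dropped <- sum(!nonzero)
  m2 <- m[nonzero, , drop = FALSE]
  sf <- size_factors(m)
  lfc <- log2fc_median_norm(m2, groups, contrast, pseudocount, sf = sf)
  p <- nb_lrt_test(m2, groups, contrast, sf = sf)
  z <- normalize_counts(m2[, keep_samples, drop = FALSE], sf[keep_samples])
  out <- data.frame(gene_id = rownames(m2),
                    base_mean = rowMeans(z),
                    log2fc = unname(lfc),
                    p_value = unname(p),
                    q_value = unname(bh_adjust(p)))
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("de_table", "data.frame")
  out
}

#' Filter differentially expressed genes
#'
#' Keeps records with `|log2fc| > lfc_min` and `q_value < q_max`, labelling
#' the direction of change.
#'
#' @param records A [de_table()] (or any data frame with `log2fc` and
#'   `q_value`).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param q_max Maximum FDR-adjusted p (default 0.05).
#' @return The surviving subset with an added `direction` column
#'   (`"up"` / `"down"`).
#' @export
filter_degs <- function(records, lfc_min = 1, q_max = 0.05) {
  if (lfc_min <= 0 || q_max <= 0) stop("thresholds must be > 0")
  keep <- abs(records$log2fc) > lfc_min & records$q_value < q_max
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Write / read a DE table as TSV
#'
#' @param x A [de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
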