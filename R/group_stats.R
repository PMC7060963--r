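#' Pooled-variance Student's t-test
#'
#' Classic two-sample Student's t with pooled variance and
#' `df = nA + nB - 2`, two-tailed. With zero pooled variance the test is
#' degenerate: equal means give `p = 1` by convention, unequal means are an
#' error (the difference is infinitely many SDs).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' students_t(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = na + nb - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' One-way random-effects (Model II) ANOVA
#'
#' Variance-component estimation for cells nested in batches via expected
#' mean squares: `sigma2_w = MS_within`, `sigma2_b = max(0, (MS_between -
#' MS_within) / n0)` with `n0 = (N - sum(n_i^2) / N) / (k - 1)` the
#' standard unbalanced-design coefficient, and `F = MS_between / MS_within`
#' tested against `F(k - 1, N - k)`.
#'
#' @param values Numeric vector of per-cell values.
#' @param batch Batch labels, same length as `values` (>= 2 distinct).
#' @return A list: `sigma2_b`, `sigma2_w`, `ms_between`, `ms_within`,
#'   `n0`, `F`, `df`, `p`.
#' @export
random_effects_anova <- function(values, batch) {
  values <- as.numeric(values)
  batch <- as.factor(batch)
  if (length(values) != length(batch)) stop("values and batch differ in length")
  k <- nlevels(batch)
  if (k < 2) stop("need >= 2 batches")
  n_i <- as.numeric(table(batch))
  N <- length(values)
  if (N - k < 1) stop("need at least one batch with >= 2 cells")
  grand <- mean(values)
  means <- tapply(values, batch, mean)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((values - means[batch])^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma2_b <- max(0, (ms_between - ms_within) / n0)
  f <- if (ms_within > 0) ms_between / ms_within else NA_real_
  p <- if (is.na(f)) NA_real_ else stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  list(sigma2_b = sigma2_b, sigma2_w = ms_within,
       ms_between = ms_between, ms_within = ms_within, n0 = n0,
       F = f, df = c(k - 1, N - k), p = p)
}

#' Default comparison plan for the four-group study
#'
#' Pairwise contrasts WT vs KO, WT vs WT+helothermine, KO+helothermine vs
#' WT and KO vs KO+helothermine, plus the rescue rule: a metric counts as
#' rescued when the toxin effect is present in the wild type (WT+HELHO vs
#' WT significant) but the treated knockout is indistinguishable from
#' untreated wild type (KO+HELHO vs WT not significant).
#'
#' @param alpha Significance level (default 0.05).
#' @return A plan list for [compare_groups()].
#' @export
default_comparison_plan <- function(alpha = 0.05) {
  list(pairs = list(c("WT", "KO"), c("WT", "WT_HELHO"),
                    c("KO_HELHO", "WT"), c("KO", "KO_HELHO")),
       rescue = list(treated = "KO_HELHO", reference = "WT",
                     positive_control = "WT_HELHO"),
       alpha = alpha)
}

#' Group-level statistics over cell summaries
#'
#' Runs the pooled t-test for every planned group pair and metric
#' (amplitude, rise time, decay-50) on per-cell values, a random-effects
#' ANOVA over differentiation batches within each group, and evaluates the
#' rescue rule of the plan.
#'
#' @param cells A data frame of per-cell summaries with columns `group`,
#'   `diff_batch`, `amplitude`, `rise_time_ms`, `decay50_ms` (e.g. rows
#'   from [analyze_recording()] plus a `group` column).
#' @param plan A plan as from [default_comparison_plan()]; pairs referring
#'   to absent groups are an error.
#' @return An object of class `group_comparison`: `groups` (per-group n,
#'   mean and SD per metric), `comparisons` (one row per pair x metric with
#'   `t`, `df`, `p`, `significant`), `anova` (per group x metric variance
#'   components), `rescue` (named logical per metric, if the plan has a
#'   rescue block), `alpha`.
#' @export
compare_groups <- function(cells, plan = default_comparison_plan()) {
  metrics <- c("amplitude", "rise_time_ms", "decay50_ms")
  stopifnot(all(c("group", metrics) %in% names(cells)))
  alpha <- if (is.null(plan$alpha)) 0.05 else plan$alpha
  present <- unique(cells$group)
  need <- unique(c(unlist(plan$pairs), unlist(plan$rescue)))
  missing <- setdiff(need, present)
  if (length(missing) > 0)
    stop("plan references absent group(s): ", paste(missing, collapse = ", "))
  groups <- do.call(rbind, lapply(split(cells, cells$group), function(g) {
    cbind(data.frame(group = g$group[1], n_cells = nrow(g)),
          as.data.frame(lapply(g[metrics], mean)),
          stats::setNames(as.data.frame(lapply(g[metrics], stats::sd)),
                          paste0("sd_", metrics)))
  }))
  rownames(groups) <- NULL
  comparisons <- do.call(rbind, lapply(plan$pairs, function(pr) {
    do.call(rbind, lapply(metrics, function(m) {
      tt <- students_t(cells[cells$group == pr[1], m],
                       cells[cells$group == pr[2], m])
      data.frame(group_a = pr[1], group_b = pr[2], metric = m,
                 mean_a = tt$mean_a, mean_b = tt$mean_b,
                 t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$p < alpha)
    }))
  }))
  anova <- NULL
  if ("diff_batch" %in% names(cells)) {
    anova <- do.call(rbind, lapply(split(cells, cells$group), function(g) {
      if (length(unique(g$diff_batch)) < 2) return(NULL)
      do.call(rbind, lapply(metrics, function(m) {
        a <- random_effects_anova(g[[m]], g$diff_batch)
        data.frame(group = g$group[1], metric = m, sigma2_b = a$sigma2_b,
                   sigma2_w = a$sigma2_w, F = a$F, p = a$p)
      }))
    }))
    rownames(anova) <- NULL
  }
  rescue <- NULL
  if (!is.null(plan$rescue)) {
    r <- plan$rescue
    rescue <- vapply(metrics, function(m) {
      p_treated <- students_t(cells[cells$group == r$treated, m],
                              cells[cells$group == r$reference, m])$p
      p_pos <- students_t(cells[cells$group == r$positive_control, m],
                          cells[cells$group == r$reference, m])$p
      p_treated >= alpha && p_pos < alpha
    }, logical(1))
  }
  structure(list(groups = groups, comparisons = comparisons, anova = anova,
                 rescue = rescue, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group means (per-cell summaries):\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat("\nPlanned comparisons (pooled t, alpha =", x$alpha, "):\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  if (!is.null(x$rescue)) {
    cat("\nRescue (treated KO vs reference not significant & toxin effect in WT):\n")
    print(x$rescue)
  }
  invisible(x)
}

#' Relative qPCR quantification (ddCt)
#'
#' `dCt = Ct_target - mean(Ct_references)` per condition, `ddCt =
#' dCt_sample - dCt_calibrator`, `fold_change = 2^(-ddCt)`. Adding any
#' constant to every Ct leaves the fold change unchanged.
#'
#' @param ct_target Target-gene Ct in the sample condition.
#' @param ct_refs Reference-gene Ct values in the sample condition
#'   (non-empty; e.g. two housekeeping genes, averaged).
#' @param ct_target_calibrator,ct_refs_calibrator The same for the
#'   calibrator condition.
#' @param sample,target Labels carried into the result.
#' @return An object of class `ddct_result`: `delta_delta_ct`,
#'   `fold_change`, plus the per-condition `delta_ct` values.
#' @examples
#' compute_ddct(20, c(18, 22), 24, c(20, 24))  # ddCt = -2, fold = 4
#' @export
compute_ddct <- function(ct_target, ct_refs, ct_target_calibrator,
                         ct_refs_calibrator, sample = "sample",
                         target = "target") {
  if (length(ct_refs) == 0 || length(ct_refs_calibrator) == 0)
    stop("reference gene list must be non-empty")
  vals <- c(ct_target, ct_refs, ct_target_calibrator, ct_refs_calibrator)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  dct_sample <- ct_target - mean(ct_refs)
  dct_cal <- ct_target_calibrator - mean(ct_refs_calibrator)
  ddct <- dct_sample - dct_cal
  structure(list(sample = sample, target = target,
                 delta_ct_sample = dct_sample, delta_ct_calibrator = dct_cal,
                 delta_delta_ct = ddct, fold_change = 2^(-ddct)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt for %s (%s): ddCt = %.4g cycles, fold change = %.4g\n",
              x$target, x$sample, x$delta_delta_ct, x$fold_change))
  invisible(x)
}
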