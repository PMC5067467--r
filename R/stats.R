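#' Bin the press counts of a training session
#'
#' Partitions the session into `n_bins` equal windows (10 x 2 min for the
#' default 20-min session) and counts the presses whose 0.5 s hold completed
#' inside each window.
#'
#' @param log A `session_log` from [run_session()].
#' @param n_bins Number of equal time bins.
#' @return Integer vector of length `n_bins`; its sum equals the session's
#'   total press count.
#' @export
bin_press_counts <- function(log, n_bins = 10) {
  stopifnot(inherits(log, "session_log"), n_bins >= 1)
  width <- log$duration_s / n_bins
  idx <- pmin(floor(log$presses$time_s / width) + 1, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' One-factor repeated-measures ANOVA over training bins
#'
#' Tests for a learning effect across time bins, treating each
#' replicate-by-manipulandum press-count series as a subject. For the
#' paper-sized design (80 series x 10 bins) the degrees of freedom are
#' (9, 711). No sphericity correction is applied.
#'
#' @param bins Numeric matrix, subjects in rows, bins in columns.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
repeated_anova_bins <- function(bins) {
  bins <- as.matrix(bins)
  stopifnot(nrow(bins) >= 2, ncol(bins) >= 2)
  n_s <- nrow(bins); n_b <- ncol(bins)
  df <- data.frame(y = as.vector(bins),
                   subj = factor(rep(seq_len(n_s), times = n_b)),
                   bin = factor(rep(seq_len(n_b), each = n_s)))
  if (stats::var(df$y) == 0)
    return(list(F = 0, df1 = n_b - 1, df2 = (n_b - 1) * (n_s - 1), p = 1))
  fit <- stats::aov(y ~ bin + Error(subj), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["bin", "F value"], df1 = tab["bin", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["bin", "Pr(>F)"])
}

#' Two-factor mixed ANOVA: lesion (between) x training bin (within)
#'
#' Balanced design required: every condition must contribute the same number
#' of subject series. Reports the two main effects, each with its own error
#' stratum (subjects within lesion for the between factor; bin-by-subject for
#' the within factor).
#'
#' @param bins_by_condition Named list of subject-x-bin matrices, one per
#'   condition, all the same shape.
#' @return List with `F_lesion`, `df_lesion`, `p_lesion`, `F_bins`,
#'   `df_bins`, `p_bins`.
#' @export
mixed_anova <- function(bins_by_condition) {
  shapes <- vapply(bins_by_condition, function(m) dim(as.matrix(m)),
                   numeric(2))
  if (length(unique(shapes[1, ])) != 1 || length(unique(shapes[2, ])) != 1)
    stop("unbalanced design: all conditions must have the same subjects x bins shape",
         call. = FALSE)
  n_s <- shapes[1, 1]; n_b <- shapes[2, 1]
  long <- do.call(rbind, lapply(names(bins_by_condition), function(nm) {
    m <- as.matrix(bins_by_condition[[nm]])
    data.frame(y = as.vector(m), lesion = nm,
               subj = paste0(nm, ".", rep(seq_len(n_s), times = n_b)),
               bin = rep(seq_len(n_b), each = n_s))
  }))
  long$lesion <- factor(long$lesion)
  long$subj <- factor(long$subj)
  long$bin <- factor(long$bin)
  fit <- stats::aov(y ~ lesion * bin + Error(subj), data = long)
  s <- summary(fit)
  between <- s[["Error: subj"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(F_lesion = between["lesion", "F value"],
       df_lesion = c(between["lesion", "Df"], between["Residuals", "Df"]),
       p_lesion = between["lesion", "Pr(>F)"],
       F_bins = within["bin", "F value"],
       df_bins = c(within["bin", "Df"], within["Residuals", "Df"]),
       p_bins = within["bin", "Pr(>F)"])
}

#' Pairwise t-tests with Bonferroni correction
#'
#' All pairwise two-sided t-tests between groups (unpooled variances), with
#' p-values multiplied by the number of comparisons and capped at 1.
#'
#' @param values Numeric vector of per-subject scores (e.g. final-bin press
#'   counts).
#' @param groups Factor or character vector of group labels.
#' @return Symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
bonferroni_pairwise <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2)
  lev <- levels(groups)
  m <- choose(nlevels(groups), 2)
  out <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                dimnames = list(lev, lev))
  for (i in seq_len(nlevels(groups) - 1))
    for (j in seq((i + 1), nlevels(groups))) {
      xi <- values[groups == lev[i]]; xj <- values[groups == lev[j]]
      p <- if (stats::sd(xi) == 0 && stats::sd(xj) == 0 && mean(xi) == mean(xj)) 1
           else stats::t.test(xi, xj)$p.value
      out[i, j] <- out[j, i] <- min(1, p * m)
    }
  out
}

#' Paired two-sided t-test on per-replicate counts
#'
#' The test used for lever preference in the extinction tests: with 40
#' replicates the degrees of freedom are 39. Zero-variance differences with
#' zero mean give `t = 0, p = 1`.
#'
#' @param counts_1,counts_2 Equal-length numeric vectors (per-replicate
#'   press counts for the two actions).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(counts_1, counts_2) {
  stopifnot(length(counts_1) == length(counts_2), length(counts_1) >= 2)
  d <- counts_1 - counts_2
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0))
  }
  ht <- stats::t.test(counts_1, counts_2, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Devaluation-effect decision rule
#'
#' The effect is considered present when the lever preference is *not*
#' significant in the non-devalued test and *is* significant in the devalued
#' test.
#'
#' @param outcome_ND,outcome_D Results of [paired_t()] for the two tests (or
#'   any lists with a `p` field).
#' @param alpha Significance level.
#' @return List of class `ide_verdict` with `present`, `p_ND`, `p_D`,
#'   `alpha`.
#' @export
assess_ide <- function(outcome_ND, outcome_D, alpha = 0.05) {
  v <- list(present = outcome_ND$p >= alpha && outcome_D$p < alpha,
            p_ND = outcome_ND$p, p_D = outcome_D$p, alpha = alpha)
  class(v) <- "ide_verdict"
  v
}

#' @export
print.ide_verdict <- function(x, ...) {
  cat(sprintf("devaluation effect %s (p_ND = %.3g, p_D = %.3g, alpha = %g)\n",
              if (x$present) "PRESENT" else "absent", x$p_ND, x$p_D, x$alpha))
  invisible(x)
}
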