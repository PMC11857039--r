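#' Shapiro-Wilk normality gate
#'
#' Applies the Shapiro-Wilk test to each group and reports whether the
#' analysis pipeline should route to its nonparametric branch (it does as
#' soon as any group tests non-normal at `alpha`). Constant samples cannot
#' be tested and are flagged non-normal; groups with n < 3 are skipped with
#' a warning.
#'
#' @param samples named list of numeric vectors (one per group).
#' @param alpha gate level (default 0.05).
#' @return List with `table` (group, n, W, p, normal) and `nonparametric`
#'   (logical: use the nonparametric branch).
#' @export
shapiro_gate <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]][!is.na(samples[[g]])]
    n <- length(x)
    if (n < 3L) {
      warning(sprintf("group '%s' has n = %d < 3: skipped", g, n))
      return(data.frame(group = g, n = n, W = NA_real_, p = NA_real_,
                        normal = NA))
    }
    if (sd(x) == 0)
      return(data.frame(group = g, n = n, W = NA_real_, p = 0,
                        normal = FALSE))
    sw <- shapiro.test(x)
    data.frame(group = g, n = n, W = unname(sw$statistic),
               p = sw$p.value, normal = sw$p.value > alpha)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       nonparametric = any(tab$p <= alpha, na.rm = TRUE))
}

# Friedman chi-square from within-block midranks, with the standard tie
# correction. `mat` is blocks x conditions, complete.
friedman_statistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  rk <- t(apply(mat, 1L, rank))
  Rj <- colSums(rk)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(mat, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C > 0) stat <- stat / C
  list(statistic = stat, df = k - 1, mean_ranks = colMeans(rk),
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Friedman test with Bonferroni-corrected post hoc comparisons
#'
#' Repeated-measures comparison of surface conditions across animal blocks:
#' the Friedman chi-square is computed from within-block midranks (tie
#' corrected); pairwise post hoc comparisons use Dunn-type z tests on mean
#' ranks (SE `sqrt(k(k+1)/(6n))`), Bonferroni-adjusted by the number of
#' pairs compared, or — with `posthoc = "wilcoxon"` — paired Wilcoxon
#' signed-rank tests with the same correction. Blocks with any missing
#' condition are dropped listwise (with a message).
#'
#' @param mat numeric matrix, blocks (animals) x conditions; column names
#'   are condition labels.
#' @param alpha significance level for the reported decisions (default
#'   0.05).
#' @param posthoc `"dunn"` (default) or `"wilcoxon"`.
#' @param comparisons `"all"` pairwise (default) or `"vs_control"`.
#' @param control control condition name (first column by default), used
#'   when `comparisons = "vs_control"`.
#' @return List of class `friedman_report`: `statistic`, `df`, `p`,
#'   `n_blocks`, `mean_ranks`, `posthoc` (data frame with raw and adjusted
#'   p), `dropped_blocks`.
#' @export
friedman_bonferroni <- function(mat, alpha = 0.05,
                                posthoc = c("dunn", "wilcoxon"),
                                comparisons = c("all", "vs_control"),
                                control = NULL) {
  posthoc <- match.arg(posthoc)
  comparisons <- match.arg(comparisons)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("cond", seq_len(ncol(mat)))
  complete <- stats::complete.cases(mat)
  dropped <- which(!complete)
  if (length(dropped))
    message(sprintf("dropping %d incomplete block(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  mat <- mat[complete, , drop = FALSE]
  k <- ncol(mat); n <- nrow(mat)
  if (k < 2L || n < 2L) {
    warning("fewer than 2 complete blocks or 2 conditions: test not run")
    return(structure(list(statistic = NA_real_, df = NA_integer_,
                          p = NA_real_, n_blocks = n, mean_ranks = NULL,
                          posthoc = NULL, dropped_blocks = dropped),
                     class = "friedman_report"))
  }
  fr <- friedman_statistic(mat)
  if (is.null(control)) control <- colnames(mat)[1]
  pairs <- if (comparisons == "all") {
    utils::combn(colnames(mat), 2L, simplify = FALSE)
  } else {
    lapply(setdiff(colnames(mat), control), function(b) c(control, b))
  }
  npairs <- length(pairs)
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    if (posthoc == "dunn") {
      se <- sqrt(k * (k + 1) / (6 * n))
      z <- (fr$mean_ranks[pr[1]] - fr$mean_ranks[pr[2]]) / se
      praw <- 2 * pnorm(-abs(z))
      data.frame(a = pr[1], b = pr[2], statistic = unname(z),
                 p_raw = unname(praw))
    } else {
      wt <- suppressWarnings(wilcox.test(mat[, pr[1]], mat[, pr[2]],
                                         paired = TRUE, exact = FALSE))
      data.frame(a = pr[1], b = pr[2], statistic = unname(wt$statistic),
                 p_raw = wt$p.value)
    }
  }))
  ph$p_adj <- pmin(1, ph$p_raw * npairs)
  ph$significant <- !is.na(ph$p_adj) & ph$p_adj <= alpha
  structure(list(statistic = fr$statistic, df = fr$df, p = fr$p,
                 n_blocks = n, mean_ranks = fr$mean_ranks, posthoc = ph,
                 n_comparisons = npairs, alpha = alpha,
                 dropped_blocks = dropped),
            class = "friedman_report")
}

#' @export
print.friedman_report <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4g, df = %s, p = %.4g (n = %d blocks)\n",
              x$statistic, x$df, x$p, x$n_blocks))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
    cat(sprintf("post hoc: %d comparisons, %d significant at alpha = %g\n",
                nrow(x$posthoc), nrow(sig), x$alpha))
  }
  invisible(x)
}

#' Mann-Whitney comparison of the two healing intervals
#'
#' Two-sided Mann-Whitney U comparing per-disc values at 4 and 13 weeks:
#' exact when both samples have n <= 8 (and ties permit), otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x4,x13 numeric vectors (per-disc values at the two timepoints).
#' @return Data frame with `U`, `p`, `n4`, `n13`, `method`.
#' @export
mannwhitney_timepoints <- function(x4, x13) {
  x4 <- x4[!is.na(x4)]; x13 <- x13[!is.na(x13)]
  if (!length(x4) || !length(x13)) {
    warning("empty sample: comparison reported as missing")
    return(data.frame(U = NA_real_, p = NA_real_, n4 = length(x4),
                      n13 = length(x13), method = NA_character_))
  }
  use_exact <- length(x4) <= 8L && length(x13) <= 8L
  wt <- suppressWarnings(
    wilcox.test(x4, x13, exact = use_exact, correct = TRUE))
  data.frame(U = unname(wt$statistic), p = wt$p.value,
             n4 = length(x4), n13 = length(x13),
             method = if (grepl("continuity", wt$method)) "approx" else
               if (use_exact && !any(duplicated(c(x4, x13)))) "exact"
               else "approx")
}

#' Spearman correlation grid
#'
#' Spearman rank correlations (midranks, two-sided p) between metric pairs,
#' computed per condition and timepoint — the layout of a per-condition
#' correlation table (BF vs BIC, BF vs CD31, ...).
#'
#' @param data data frame with columns `condition`, `timepoint`, plus one
#'   column per metric; one row per disc.
#' @param pairs list of 2-element character vectors naming metric columns.
#' @return Data frame: `condition`, `timepoint`, `pair`, `n`, `rho`, `p`.
#'   Pairs with fewer than 3 complete observations or zero variance report
#'   `NA`.
#' @export
spearman_grid <- function(data, pairs) {
  stopifnot(all(c("condition", "timepoint") %in% names(data)))
  combos <- unique(data[, c("condition", "timepoint")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- data[data$condition == combos$condition[i] &
                  data$timepoint == combos$timepoint[i], , drop = FALSE]
    for (pr in pairs) {
      x <- sub[[pr[1]]]; y <- sub[[pr[2]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = combos$condition[i], timepoint = combos$timepoint[i],
        pair = paste(pr, collapse = "~"), n = n, rho = rho, p = p)
    }
  }
  do.call(rbind, out)
}

#' Spearman rho for one paired sample
#'
#' Midrank-based Spearman correlation with its two-sided p value.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @examples
#' spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-comparison alpha from a family-wise error rate
#'
#' Bonferroni division of a family-wise error rate over the planned number
#' of comparisons (the study design's alpha arithmetic: 5% over 14 planned
#' comparisons gives 0.36% per comparison).
#'
#' @param fwer family-wise error rate, in `(0, 1)`.
#' @param n_comparisons number of planned comparisons (>= 1).
#' @return Per-comparison significance level (same scale as `fwer`).
#' @examples
#' round(100 * bonferroni_alpha(0.05, 14), 2)  # 0.36 (percent)
#' @export
bonferroni_alpha <- function(fwer, n_comparisons) {
  stopifnot_scalar_number(fwer, "fwer", min = 1e-12, max = 1 - 1e-12)
  if (!is.numeric(n_comparisons) || length(n_comparisons) != 1L ||
      n_comparisons < 1)
    stop("`n_comparisons` must be a positive count", call. = FALSE)
  fwer / n_comparisons
}

#' Group descriptives (mean +/- SD)
#'
#' @param samples named list of numeric vectors.
#' @return Data frame `group`, `n`, `mean`, `sd`.
#' @export
describe_groups <- function(samples) {
  do.call(rbind, lapply(names(samples), function(g) {
    x <- samples[[g]][!is.na(samples[[g]])]
    data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x))
  }))
}
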