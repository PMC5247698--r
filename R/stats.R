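#' mFPA bracket categorisation
#'
#' Partitions `[0, 100]` into the standard steatosis brackets
#' `<5`, `5-9.9`, `10-19.9` and `>=20` percent fat. Boundary values (5, 10,
#' 20 exactly) are assigned upward, so 5% mFPA counts as steatotic.
#'
#' @param mfpa_pct Numeric vector in `[0, 100]`.
#' @return An ordered factor with levels `"<5" < "5-9.9" < "10-19.9" <
#'   ">=20"`.
#' @export
mfpa_brackets <- function() c("<5", "5-9.9", "10-19.9", ">=20")

#' @rdname mfpa_brackets
#' @export
categorize_mfpa <- function(mfpa_pct) {
  if (any(!is.finite(mfpa_pct)) || any(mfpa_pct < 0 | mfpa_pct > 100))
    stop_input("mfpa_pct must lie in [0, 100]")
  cut(mfpa_pct, breaks = c(0, 5, 10, 20, 100), labels = mfpa_brackets(),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, on pairwise-complete
#' observations. The two-sided p-value is exact (permutation distribution)
#' for n <= 9 without ties and uses the t approximation otherwise, as in
#' [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `rs`, `p` and `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_input("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_input("undefined correlation: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rs = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test reported as the U statistic for group `a`
#' (smaller U means `a` ranks lower). For small samples
#' (`length(a) + length(b) <= exact_limit`, default 14) the p-value is exact
#' by full enumeration of all group assignments of the observed values,
#' which handles ties naturally; larger samples use the normal approximation
#' with tie and continuity corrections via [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_limit Combined size at or below which enumeration is used.
#' @return List with `U`, `p`, `method` (`"exact"` or `"asymptotic"`).
#' @export
mann_whitney <- function(a, b, exact_limit = 14L) {
  if (!length(a) || !length(b)) stop_input("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_limit) {
    # exact null: U recomputed for every C(na+nb, na) assignment of the
    # pooled values to group a; two-sided p by symmetric deviation from mn/2
    idx <- utils::combn(na + nb, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    dev <- abs(Us - na * nb / 2)
    p <- mean(dev >= abs(U - na * nb / 2) - 1e-9)
    list(U = U, p = p, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(U = U, p = wt$p.value, method = "asymptotic")
  }
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction and a chi-square p-value on k-1 degrees
#' of freedom (via [stats::kruskal.test()]). For small samples a seeded
#' Monte-Carlo permutation p-value is available.
#'
#' @param groups List of >= 3 non-empty numeric vectors.
#' @param exact `"none"` (default) for the chi-square p, or `"montecarlo"`
#'   for a permutation p over `n_perm` seeded label shuffles.
#' @param n_perm,seed Monte-Carlo settings.
#' @return List with `H`, `df`, `p`, and `p_montecarlo` when requested.
#' @export
kruskal_wallis <- function(groups, exact = c("none", "montecarlo"),
                           n_perm = 2000L, seed = 1L) {
  exact <- match.arg(exact)
  if (!is.list(groups) || length(groups) < 3)
    stop_input("need >= 3 groups; use mann_whitney() for two")
  if (any(!lengths(groups))) stop_input("all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    # fully tied data: no rank variation at all, so H is 0 by convention
    # (kruskal.test's tie correction degenerates to 0/0 here)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
  if (exact == "montecarlo") {
    set.seed(seed)
    r <- rank(x); N <- length(x)
    Hs <- replicate(n_perm, {
      rp <- sample(r)
      sums <- tapply(rp, g, sum)
      12 / (N * (N + 1)) * sum(sums^2 / lengths(groups)) - 3 * (N + 1)
    })
    ties <- table(x); ties <- ties[ties > 1]
    tc <- 1 - (if (length(ties)) sum(ties^3 - ties) else 0) / (N^3 - N)
    Hs <- Hs / tc
    out$p_montecarlo <- (sum(Hs >= out$H - 1e-12) + 1) / (n_perm + 1)
  }
  out
}

#' ROC curve and AUROC
#'
#' Sweeps every unique score (plus +/- infinity) as a "positive if score >=
#' threshold" cut-off, recording sensitivity and specificity, and computes
#' the area under the curve by the trapezoidal rule. With ties this equals
#' the concordance probability `P(score+ > score-) + 0.5 P(score+ ==
#' score-)`.
#'
#' @param scores Numeric predictor (higher predicts positive).
#' @param labels Binary outcome (logical, or 0/1).
#' @return An object of class `"roc_curve"`: data.frame `points`
#'   (`threshold`, `sensitivity`, `specificity`), `auroc`, `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_input("both label classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg, numeric(1))
  fpr <- 1 - spec
  auroc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auroc = auroc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUROC %.3f (%d positive / %d negative)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity at a fixed cut-off
#'
#' Positive call when `score >= cutoff` (so a cut-off at the upper limit of
#' normal flags values at or above it). Sensitivity is TP/(TP+FN) on the
#' positive class, specificity TN/(TN+FP) on the negative.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome.
#' @param cutoff Decision threshold.
#' @return List with `sensitivity`, `specificity`, and the 2x2 counts.
#' @export
sensitivity_specificity <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop_input("both label classes must be present")
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  tn <- sum(!call_pos & !labels); fp <- sum(call_pos & !labels)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}
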