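#' Full cohort analysis report
#'
#' Reproduces the standard analysis bundle for a steatosis cohort:
#' \enumerate{
#'   \item summary medians and interquartile ranges - overall, by sex, and
#'     split at 5% mFPA (the conventional steatosis cut-off);
#'   \item Spearman correlations of mFPA with ALT, AST, HA, LR and HpL,
#'     pooled and stratified by sex (stratified and pooled coefficients are
#'     labelled explicitly - they can differ appreciably);
#'   \item mFPA bracket medians (`<5`, `5-9.9`, `10-19.9`, `>=20`),
#'     adjacent-bracket Mann-Whitney p-values and an overall
#'     Kruskal-Wallis test per variable;
#'   \item ROC analysis of ALT and AST against the 5% and 20% mFPA labels,
#'     with sensitivity/specificity at the configured clinical cut-offs.
#' }
#' Pairwise p-values are reported raw (no multiple-testing adjustment) by
#' default, with an optional Holm correction. Missing biochemistry is
#' handled by pairwise-complete deletion per analysis. The bundle embeds
#' the package version so reports are traceable.
#'
#' @param records Cohort data.frame in the [generate_cohort()] schema; at
#'   least 10 rows with non-missing `mfpa_pct`.
#' @param cutoffs_u_l Transaminase cut-offs (U/L) at which sensitivity and
#'   specificity are tabulated. Defaults are the 31/33 U/L upper normal
#'   limits plus 41, 67 and 75 U/L.
#' @param holm Apply Holm adjustment across each variable's pairwise
#'   bracket comparisons.
#' @return An object of class `"cohort_report"`, a list of data.frames:
#'   `summary`, `correlations`, `brackets`, `bracket_tests`, `roc_auc`,
#'   `roc_points`, `cutoffs`, plus `meta`.
#' @export
cohort_report <- function(records, cutoffs_u_l = c(31, 33, 41, 67, 75),
                          holm = FALSE) {
  need <- c("mfpa_pct", "sex", "alt_u_l", "ast_u_l", "ha_um2", "lr_um", "hpl")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_input("records are missing required columns: ", paste(miss, collapse = ", "))
  records <- records[!is.na(records$mfpa_pct), , drop = FALSE]
  if (nrow(records) < 10) stop_input("need at least 10 records with mFPA")

  num_vars <- intersect(c("age", "mfpa_pct", "alt_u_l", "ast_u_l", "ggt_u_l",
                          "bilirubin_mmol_l", "albumin_g_l", "alp_u_l",
                          "ha_um2", "lr_um", "hpl"), names(records))
  med_iqr <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(stats::median(x), stats::quantile(x, 0.25, names = FALSE),
      stats::quantile(x, 0.75, names = FALSE), length(x))
  }
  strata <- list(all = rep(TRUE, nrow(records)),
                 male = records$sex == "male",
                 female = records$sex == "female",
                 mfpa_lt5 = records$mfpa_pct < 5,
                 mfpa_ge5 = records$mfpa_pct >= 5)
  summary_tab <- do.call(rbind, lapply(names(strata), function(s) {
    sub <- records[strata[[s]], , drop = FALSE]
    do.call(rbind, lapply(num_vars, function(v) {
      m <- med_iqr(sub[[v]])
      data.frame(stratum = s, variable = v, median = m[1], q1 = m[2],
                 q3 = m[3], n = m[4], stringsAsFactors = FALSE)
    }))
  }))

  cor_vars <- c(alt_u_l = "ALT", ast_u_l = "AST", ha_um2 = "HA",
                lr_um = "LR", hpl = "HpL")
  cor_strata <- list(together = rep(TRUE, nrow(records)),
                     male = records$sex == "male",
                     female = records$sex == "female")
  correlations <- do.call(rbind, lapply(names(cor_strata), function(s) {
    sub <- records[cor_strata[[s]], , drop = FALSE]
    do.call(rbind, lapply(names(cor_vars), function(v) {
      res <- tryCatch(spearman(sub$mfpa_pct, sub[[v]]),
                      error = function(e) list(rs = NA_real_, p = NA_real_, n = 0))
      data.frame(stratum = s, variable = cor_vars[[v]], rs = res$rs,
                 p = res$p, n = res$n, stringsAsFactors = FALSE)
    }))
  }))

  bracket <- categorize_mfpa(records$mfpa_pct)
  occupancy <- table(bracket)
  brackets_tab <- do.call(rbind, lapply(levels(bracket), function(b) {
    sub <- records[bracket == b, , drop = FALSE]
    do.call(rbind, lapply(names(cor_vars), function(v) {
      m <- med_iqr(sub[[v]])
      data.frame(bracket = b, variable = cor_vars[[v]], median = m[1],
                 q1 = m[2], q3 = m[3], n = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))

  lv <- levels(bracket)
  bracket_tests <- do.call(rbind, lapply(names(cor_vars), function(v) {
    vals <- records[[v]]
    occupied <- lv[vapply(lv, function(b) sum(bracket == b & is.finite(vals)) > 0, logical(1))]
    kw <- if (length(occupied) >= 3) {
      gl <- lapply(occupied, function(b) vals[bracket == b & is.finite(vals)])
      kruskal_wallis(gl)
    } else list(H = NA_real_, p = NA_real_)
    pw <- do.call(rbind, lapply(seq_len(length(lv) - 1), function(i) {
      a <- vals[bracket == lv[i] & is.finite(vals)]
      b <- vals[bracket == lv[i + 1] & is.finite(vals)]
      if (!length(a) || !length(b))
        return(data.frame(variable = cor_vars[[v]], comparison =
                            paste(lv[i], "vs", lv[i + 1]), test = "mann_whitney",
                          statistic = NA_real_, p = NA_real_,
                          skipped = TRUE, stringsAsFactors = FALSE))
      mw <- mann_whitney(a, b)
      data.frame(variable = cor_vars[[v]],
                 comparison = paste(lv[i], "vs", lv[i + 1]),
                 test = "mann_whitney", statistic = mw$U, p = mw$p,
                 skipped = FALSE, stringsAsFactors = FALSE)
    }))
    if (holm) pw$p[!pw$skipped] <- stats::p.adjust(pw$p[!pw$skipped], "holm")
    rbind(data.frame(variable = cor_vars[[v]], comparison = "all brackets",
                     test = "kruskal_wallis", statistic = kw$H, p = kw$p,
                     skipped = is.na(kw$p), stringsAsFactors = FALSE),
          pw)
  }))

  roc_auc <- NULL; roc_points <- NULL; cutoff_tab <- NULL
  for (marker in c("alt_u_l", "ast_u_l")) {
    for (thr in c(5, 20)) {
      lab <- records$mfpa_pct >= thr
      sc <- records[[marker]]
      ok <- is.finite(sc)
      if (length(unique(lab[ok])) < 2) next
      rc <- roc(sc[ok], lab[ok])
      mk <- toupper(sub("_u_l", "", marker))
      roc_auc <- rbind(roc_auc, data.frame(
        marker = mk, mfpa_cutoff_pct = thr, auroc = rc$auroc,
        n_pos = rc$n_pos, n_neg = rc$n_neg, stringsAsFactors = FALSE))
      roc_points <- rbind(roc_points, cbind(
        data.frame(marker = mk, mfpa_cutoff_pct = thr), rc$points))
      cutoff_tab <- rbind(cutoff_tab, do.call(rbind, lapply(cutoffs_u_l, function(co) {
        ss <- sensitivity_specificity(sc[ok], lab[ok], co)
        data.frame(marker = mk, mfpa_cutoff_pct = thr, cutoff_u_l = co,
                   sensitivity = ss$sensitivity, specificity = ss$specificity,
                   stringsAsFactors = FALSE)
      })))
    }
  }

  structure(list(summary = summary_tab, correlations = correlations,
                 brackets = brackets_tab, bracket_tests = bracket_tests,
                 roc_auc = roc_auc, roc_points = roc_points,
                 cutoffs = cutoff_tab,
                 meta = list(n = nrow(records),
                             occupancy = as.list(occupancy),
                             cutoffs_u_l = cutoffs_u_l, holm = holm,
                             package_version =
                               as.character(utils::packageVersion("steatomorph")))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n = %d patients\n", x$meta$n))
  occ <- unlist(x$meta$occupancy)
  cat("  bracket occupancy:", paste(names(occ), occ, sep = "=", collapse = "  "), "\n")
  if (!is.null(x$roc_auc)) {
    for (i in seq_len(nrow(x$roc_auc)))
      cat(sprintf("  AUROC %s vs %g%% mFPA: %.3f\n", x$roc_auc$marker[i],
                  x$roc_auc$mfpa_cutoff_pct[i], x$roc_auc$auroc[i]))
  }
  invisible(x)
}

#' Serialise a cohort report
#'
#' Writes the report bundle as one JSON file plus one CSV per table.
#' Output is deterministic: the same report always produces byte-identical
#' files.
#'
#' @param report A [cohort_report()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  if (!inherits(report, "cohort_report")) stop_input("not a cohort_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("summary", "correlations", "brackets", "bracket_tests",
            "roc_auc", "roc_points", "cutoffs")
  for (t in tabs)
    if (!is.null(report[[t]]))
      utils::write.csv(report[[t]], file.path(dir, paste0(t, ".csv")),
                       row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
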