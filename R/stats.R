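# Subject- and group-level screening statistics.

#' Intracellular retention statistic
#'
#' Permeabilised minus non-permeabilised percent positive for the same
#' subject: detergent permeabilisation lets the antibody reach retained
#' intracellular collagen VI, so the difference estimates intracellular
#' accumulation. Negative values are physically implausible (they indicate
#' staining or acquisition problems) and are flagged with a warning.
#'
#' @param pct_perm,pct_nonperm Percent positive in \[0, 100\]; vectorised.
#' @return `pct_perm - pct_nonperm` in percentage points.
#' @examples
#' retention(95.3, 65.3)  # 30
#' @export
retention <- function(pct_perm, pct_nonperm) {
  check_pct(pct_perm, "pct_perm")
  check_pct(pct_nonperm, "pct_nonperm")
  out <- pct_perm - pct_nonperm
  if (any(out < 0)) {
    warning("negative retention value(s): permeabilised staining below surface staining",
            call. = FALSE)
  }
  out
}

check_pct <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 100)) {
    stop("`", name, "` must be percentages in [0, 100]", call. = FALSE)
  }
  invisible(x)
}

#' Group summary (mean +/- SD, range)
#'
#' @param subjects Data frame of subject-level results.
#' @param condition Group to summarise.
#' @param measure Column to summarise (e.g. `"pct_nonperm"`, `"pct_perm"`,
#'   `"retention"`).
#' @param group_col Column holding the group labels.
#' @return One-row data frame: `condition`, `n`, `mean_pct`, `sd_pct`
#'   (sample SD, n-1 denominator; `NA` with a warning for n = 1),
#'   `min_pct`, `max_pct`.
#' @export
group_summary <- function(subjects, condition, measure = "pct_nonperm",
                          group_col = "condition") {
  stopifnot(is.data.frame(subjects), measure %in% names(subjects))
  x <- subjects[[measure]][subjects[[group_col]] == condition]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no subjects in group '", condition, "'", call. = FALSE)
  if (length(x) < 2L) {
    warning("group '", condition, "' has a single subject; SD undefined",
            call. = FALSE)
  }
  data.frame(condition = condition, n = length(x),
             mean_pct = mean(x),
             sd_pct = if (length(x) >= 2L) stats::sd(x) else NA_real_,
             min_pct = min(x), max_pct = max(x),
             stringsAsFactors = FALSE)
}

#' Least-squares comparison of patient groups against controls
#'
#' Ordinary least squares of the chosen measure on group indicator
#' variables with the control group as reference — the regression analogue
#' of one-way ANOVA with treatment contrasts, so each coefficient is
#' exactly that group's mean difference from the control mean (percentage
#' points), with a two-sided t test per coefficient.
#'
#' @param subjects Data frame of subject-level results.
#' @param measure Response column.
#' @param group_col Grouping column.
#' @param reference Reference group label (default `"control"`).
#' @return Object of class `group_comparison`: `table` (group, estimate,
#'   std_error, t_value, p_value), `residual_df`, `sigma`, `degenerate`
#'   (TRUE when the fit has zero residual variance, in which case p values
#'   are reported as exact 0), `flagged_groups` (groups of size 1).
#' @export
group_comparison <- function(subjects, measure = "pct_nonperm",
                             group_col = "condition", reference = "control") {
  stopifnot(is.data.frame(subjects), measure %in% names(subjects))
  keep <- !is.na(subjects[[measure]]) & subjects[[group_col]] != "negative_control"
  df <- subjects[keep, , drop = FALSE]
  groups <- unique(df[[group_col]])
  if (!reference %in% groups) {
    stop("reference group '", reference, "' absent from the data", call. = FALSE)
  }
  if (length(groups) < 2L) stop("need at least two groups to compare", call. = FALSE)
  sizes <- table(df[[group_col]])
  flagged <- names(sizes)[sizes == 1L]
  if (length(flagged)) {
    warning("group(s) with a single subject: ", paste(flagged, collapse = ", "),
            call. = FALSE)
  }
  df$.group <- stats::relevel(factor(df[[group_col]]), ref = reference)
  fit <- stats::lm(stats::reformulate(".group", response = measure), data = df)
  # zero-residual fits are an advertised degenerate path; keep summary.lm's
  # "essentially perfect fit" warning out of the way, we flag it ourselves
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  idx <- grep("^\\.group", rownames(co))
  tab <- data.frame(group = sub("^\\.group", "", rownames(co)[idx]),
                    estimate = co[idx, 1], std_error = co[idx, 2],
                    t_value = co[idx, 3], p_value = co[idx, 4],
                    stringsAsFactors = FALSE)
  degenerate <- sm$sigma < sqrt(.Machine$double.eps)
  if (degenerate) {
    tab$p_value <- ifelse(abs(tab$estimate) > 0, 0, NA_real_)
    tab$t_value <- ifelse(abs(tab$estimate) > 0, Inf, NA_real_)
  }
  rownames(tab) <- NULL
  structure(list(table = tab, residual_df = fit$df.residual,
                 sigma = sm$sigma, degenerate = degenerate,
                 flagged_groups = flagged, reference = reference),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison vs '%s' (OLS on group indicators, %d residual df%s)\n",
              x$reference, x$residual_df,
              if (x$degenerate) "; zero residual variance" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Deficiency ratio of case to control expression
#'
#' Ratio of a case group's mean surface percent positive to the control
#' group's; UCMD fibroblasts typically express less than one third of
#' control levels.
#'
#' @param group_mean_case,group_mean_control Group mean percent positive.
#' @return Proportion `group_mean_case / group_mean_control`.
#' @examples
#' deficiency_ratio(19.6, 65.3)  # < 1/3
#' @export
deficiency_ratio <- function(group_mean_case, group_mean_control) {
  check_pct(group_mean_case, "group_mean_case")
  check_pct(group_mean_control, "group_mean_control")
  if (any(group_mean_control == 0)) {
    stop("control group mean must be > 0", call. = FALSE)
  }
  group_mean_case / group_mean_control
}

#' Severity bands recognised by the classifier
#' @export
BANDS <- c("UCMD_range", "indeterminate", "BM_or_control_range")

#' Classify a subject's surface expression into a severity band
#'
#' In the published cohort the two diagnostic categories separated cleanly:
#' every UCMD surface (non-permeabilised) value fell below 37% and every BM
#' value above 44%. The classifier keeps that observed gap explicit — values
#' between the cuts are `indeterminate` rather than forced into a band.
#' BM and control ranges overlap, so the upper band deliberately does not
#' distinguish them.
#'
#' @param pct_nonperm Surface percent positive in \[0, 100\]; vectorised.
#' @param low_cut Below this: `UCMD_range`. Default 37.
#' @param high_cut Above this: `BM_or_control_range`. Default 44.
#' @return Factor with levels `UCMD_range`, `indeterminate`,
#'   `BM_or_control_range`.
#' @examples
#' classify_sample(c(16, 40, 56.9))
#' @export
classify_sample <- function(pct_nonperm, low_cut = 37, high_cut = 44) {
  check_pct(pct_nonperm, "pct_nonperm")
  if (!(low_cut < high_cut)) stop("`low_cut` must be below `high_cut`", call. = FALSE)
  band <- ifelse(pct_nonperm < low_cut, "UCMD_range",
                 ifelse(pct_nonperm > high_cut, "BM_or_control_range",
                        "indeterminate"))
  factor(band, levels = BANDS)
}
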