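#' Two-population fluorescence model
#'
#' Generative model for one stained fibroblast sample: antigen-negative and
#' antigen-positive events each draw their fluorescence from a log-normal
#' (normal on the log10 axis, the scale cytometers display), and side scatter
#' from a common normal truncated at zero. Defaults give a cleanly bimodal
#' PE distribution: populations two decades apart, each ~0.35 decades wide,
#' i.e. separation > 4 SD, matching gate-based percent-positive counting.
#'
#' @param neg_log_mean,neg_log_sd Mean and SD of log10 fluorescence for the
#'   antigen-negative population (dimensionless decades).
#' @param pos_log_mean,pos_log_sd Same for the antigen-positive population.
#' @param ssc_mean,ssc_sd Side-scatter mean and SD in arbitrary linear units.
#' @return An object of class `fluorescence_model`.
#' @export
fluorescence_model <- function(neg_log_mean = 1.0, neg_log_sd = 0.35,
                               pos_log_mean = 3.0, pos_log_sd = 0.35,
                               ssc_mean = 450, ssc_sd = 90) {
  stopifnot(is.numeric(neg_log_mean), is.numeric(pos_log_mean))
  if (neg_log_sd <= 0 || pos_log_sd <= 0 || ssc_sd <= 0) {
    stop("all standard deviations must be > 0", call. = FALSE)
  }
  if (pos_log_mean <= neg_log_mean) {
    stop("positive population must sit above the negative population", call. = FALSE)
  }
  sep <- pos_log_mean - neg_log_mean
  if (sep < 4 * max(neg_log_sd, pos_log_sd)) {
    warning("populations separated by < 4 SD; gate-based counting will blur",
            call. = FALSE)
  }
  structure(list(neg_log_mean = neg_log_mean, neg_log_sd = neg_log_sd,
                 pos_log_mean = pos_log_mean, pos_log_sd = pos_log_sd,
                 ssc_mean = ssc_mean, ssc_sd = ssc_sd),
            class = "fluorescence_model")
}

#' Conditions recognised in sample manifests
#' @export
CONDITIONS <- c("control", "BM", "UCMD", "negative_control")

#' Plan for one simulated sample
#'
#' @param sample_id,subject_id Identifiers.
#' @param condition One of `"control"`, `"BM"`, `"UCMD"`, `"negative_control"`.
#' @param permeabilised Logical; detergent-permeabilised staining (antibody
#'   reaches intracellular antigen) versus surface-only.
#' @param true_positive_fraction True proportion of antigen-positive events
#'   in \[0, 1\]. Forced to 0 for `negative_control`.
#' @param n_events Events to acquire; the assay standard is 15,000.
#' @param seed Integer seed making this one sample reproducible in isolation.
#' @return An object of class `sample_plan`.
#' @export
sample_plan <- function(sample_id, subject_id = sample_id,
                        condition = "control", permeabilised = FALSE,
                        true_positive_fraction = 0, n_events = 15000L,
                        seed = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is.numeric(true_positive_fraction) || length(true_positive_fraction) != 1L ||
      is.na(true_positive_fraction) ||
      true_positive_fraction < 0 || true_positive_fraction > 1) {
    stop("`true_positive_fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  if (condition == "negative_control" && true_positive_fraction != 0) {
    stop("a negative control has true_positive_fraction = 0 by definition", call. = FALSE)
  }
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L) {
    stop("`n_events` must be at least 1", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 subject_id = as.character(subject_id),
                 condition = condition,
                 permeabilised = isTRUE(permeabilised),
                 true_positive_fraction = true_positive_fraction,
                 n_events = n_events, seed = as.integer(seed)),
            class = "sample_plan")
}

#' Cohort-level generative configuration
#'
#' Group parameters (mean, SD, range of percent positive, and subject count)
#' per condition and permeabilisation status. The defaults reproduce the
#' published screening cohort: five controls, five Bethlem myopathy (BM) and
#' eight Ullrich congenital muscular dystrophy (UCMD) subjects, with surface
#' (non-permeabilised) percent-positive distributions of 65.4 +/- 10.7
#' (range 50.0-76.9), 54.1 +/- 8.0 (44.8-66.2) and 19.6 +/- 10.0 (9.7-36.8)
#' respectively, and permeabilised staining above 90% in every group
#' (controls 95.3 +/- 2.2). The permeabilised BM/UCMD means are back-derived
#' from the group intracellular-retention means (42.0 and 70.9 points), the
#' only constraint the source statistics give.
#'
#' @param groups Data frame with columns `condition`, `permeabilised`,
#'   `mean_pct`, `sd_pct`, `low_pct`, `high_pct`, `n_subjects`.
#' @param base_seed Integer; master seed from which per-sample seeds derive.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_cohort_groups(), base_seed = 1L) {
  req <- c("condition", "permeabilised", "mean_pct", "sd_pct",
           "low_pct", "high_pct", "n_subjects")
  if (!is.data.frame(groups) || !all(req %in% names(groups))) {
    stop("`groups` must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  with(groups, {
    if (any(sd_pct < 0)) stop("group SDs must be >= 0", call. = FALSE)
    if (any(low_pct < 0 | high_pct > 100 | low_pct > mean_pct | mean_pct > high_pct)) {
      stop("each group needs 0 <= low <= mean <= high <= 100", call. = FALSE)
    }
    if (any(n_subjects < 1)) stop("each group needs at least one subject", call. = FALSE)
  })
  if (anyDuplicated(groups[c("condition", "permeabilised")])) {
    stop("one row per condition x permeabilisation status", call. = FALSE)
  }
  structure(list(groups = groups, base_seed = as.integer(base_seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_groups <- function() {
  data.frame(
    condition     = rep(c("control", "BM", "UCMD"), times = 2),
    permeabilised = rep(c(FALSE, TRUE), each = 3),
    mean_pct      = c(65.4, 54.1, 19.6, 95.3, 96.1, 90.5),
    sd_pct        = c(10.7,  8.0, 10.0,  2.2,  2.2,  2.2),
    low_pct       = c(50.0, 44.8,  9.7, 90.0, 90.0, 90.0),
    high_pct      = c(76.9, 66.2, 36.8, 100,  100,  100),
    n_subjects    = c(5L, 5L, 8L, 5L, 5L, 8L),
    stringsAsFactors = FALSE
  )
}

cohort_group_row <- function(config, condition, permeabilised) {
  g <- config$groups
  row <- g[g$condition == condition & g$permeabilised == permeabilised, ]
  if (nrow(row) != 1L) {
    stop(sprintf("no group parameters for condition '%s' (permeabilised = %s)",
                 condition, permeabilised), call. = FALSE)
  }
  row
}
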