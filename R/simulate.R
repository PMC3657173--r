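# Synthetic event-level cytometry.
#
# Each event is independently antigen-positive with the sample's true
# fraction; fluorescence is then log-normal for its population and side
# scatter normal (floored at zero). Per-event population labels are kept
# as an attribute so tests can tally ground truth; they are never written
# to FCS/CSV output.

# evaluate `code` under `seed` without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one stained sample
#'
#' Generates `plan$n_events` events: each is antigen-positive with
#' probability `plan$true_positive_fraction`, fluorescence is drawn from the
#' corresponding log10-normal population of `model`, and side scatter from
#' the model's scatter distribution. Deterministic for a fixed `plan$seed`.
#'
#' @param plan A [sample_plan()].
#' @param model A [fluorescence_model()].
#' @return An [event_table()] with channels `SSC` and `PE`, carrying the
#'   per-event population labels in `attr(, "population")` (1 = positive).
#' @examples
#' et <- generate_sample(sample_plan("s1", true_positive_fraction = 0.65,
#'                                   n_events = 1000, seed = 7))
#' mean(attr(et, "population"))
#' @export
generate_sample <- function(plan, model = fluorescence_model()) {
  stopifnot(inherits(plan, "sample_plan"), inherits(model, "fluorescence_model"))
  n <- plan$n_events
  p <- plan$true_positive_fraction
  with_seed(plan$seed, {
    positive <- stats::runif(n) < p
    log_mu <- ifelse(positive, model$pos_log_mean, model$neg_log_mean)
    log_sd <- ifelse(positive, model$pos_log_sd, model$neg_log_sd)
    pe <- 10^stats::rnorm(n, log_mu, log_sd)
    ssc <- pmax(stats::rnorm(n, model$ssc_mean, model$ssc_sd), 0)
    out <- event_table(cbind(SSC = ssc, PE = pe))
    attr(out, "population") <- as.integer(positive)
    attr(out, "sample_id") <- plan$sample_id
    out
  })
}

#' Simulate a no-primary-antibody negative control
#'
#' Pure background sample (true positive fraction 0), used downstream to set
#' the positivity gate.
#'
#' @param n_events Number of events (default 15,000, the assay standard).
#' @param model A [fluorescence_model()].
#' @param seed Integer seed.
#' @return An [event_table()].
#' @export
generate_negative_control <- function(n_events = 15000L,
                                      model = fluorescence_model(),
                                      seed = 1L) {
  plan <- sample_plan("negative_control", condition = "negative_control",
                      true_positive_fraction = 0, n_events = n_events,
                      seed = seed)
  generate_sample(plan, model)
}

#' Simulate a whole screening cohort
#'
#' For every subject of every condition in `config`, draws a true surface
#' (non-permeabilised) positive fraction from the group's mean-calibrated
#' truncated normal and a paired permeabilised fraction from the
#' permeabilised group distribution, enforcing permeabilised >= surface
#' (intracellular staining can only add positives). Emits one paired sample
#' set per subject plus exactly one batch negative control. Fully
#' reproducible from `config$base_seed`; per-sample seeds are recorded in
#' the manifest so any sample regenerates in isolation.
#'
#' @param config A [cohort_config()].
#' @param model A [fluorescence_model()].
#' @param n_events Events per sample.
#' @return A list with `samples` (named list of [event_table()]s),
#'   `manifest` (data frame: sample_id, subject_id, condition, permeabilised,
#'   true_fraction, seed — true_fraction retained for test oracles only),
#'   `negative_control_id`, `config`, `model`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            model = fluorescence_model(),
                            n_events = 15000L) {
  stopifnot(inherits(config, "cohort_config"))
  nonperm <- config$groups[!config$groups$permeabilised, ]
  conditions <- nonperm$condition

  draws <- with_seed(config$base_seed, {
    frac <- lapply(seq_len(nrow(nonperm)), function(i) {
      cond <- nonperm$condition[i]
      n <- nonperm$n_subjects[i]
      np_row <- cohort_group_row(config, cond, FALSE)
      pm_row <- cohort_group_row(config, cond, TRUE)
      np_mu <- calibrate_truncnorm(np_row$mean_pct, np_row$sd_pct,
                                   np_row$low_pct, np_row$high_pct)
      pm_mu <- calibrate_truncnorm(pm_row$mean_pct, pm_row$sd_pct,
                                   pm_row$low_pct, pm_row$high_pct)
      np <- rtruncnorm(n, np_mu, np_row$sd_pct, np_row$low_pct, np_row$high_pct) / 100
      pm <- rtruncnorm(n, pm_mu, pm_row$sd_pct, pm_row$low_pct, pm_row$high_pct) / 100
      list(nonperm = np, perm = pmax(pm, np))
    })
    names(frac) <- conditions
    n_total <- 2L * sum(nonperm$n_subjects) + 1L
    list(fractions = frac, seeds = sample.int(.Machine$integer.max - 1L, n_total))
  })

  manifest <- do.call(rbind, lapply(conditions, function(cond) {
    n <- nonperm$n_subjects[nonperm$condition == cond]
    subj <- sprintf("%s_%02d", cond, seq_len(n))
    data.frame(
      sample_id = c(paste0(subj, "_surf"), paste0(subj, "_perm")),
      subject_id = rep(subj, 2),
      condition = cond,
      permeabilised = rep(c(FALSE, TRUE), each = n),
      true_fraction = c(draws$fractions[[cond]]$nonperm,
                        draws$fractions[[cond]]$perm),
      stringsAsFactors = FALSE
    )
  }))
  nc_id <- "negative_control_01"
  manifest <- rbind(manifest,
                    data.frame(sample_id = nc_id, subject_id = nc_id,
                               condition = "negative_control",
                               permeabilised = FALSE, true_fraction = 0,
                               stringsAsFactors = FALSE))
  manifest$seed <- draws$seeds
  rownames(manifest) <- NULL

  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    generate_sample(sample_plan(m$sample_id, m$subject_id, m$condition,
                                m$permeabilised, m$true_fraction,
                                n_events, m$seed),
                    model)
  })
  names(samples) <- manifest$sample_id

  list(samples = samples, manifest = manifest, negative_control_id = nc_id,
       config = config, model = model)
}
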