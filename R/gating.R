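# Negative-control-calibrated positivity gating.
#
# The batch's no-primary-antibody control defines background fluorescence;
# the gate threshold is a high empirical quantile of that background and
# the same gate is applied to every sample of the batch.

#' Derive the positivity gate from a negative control
#'
#' The threshold is the empirical `quantile` of the negative control's
#' fluorescence channel (inverted-CDF / type-1 definition, so it is always
#' an observed value and at most `ceiling((1 - quantile) * n) + 1` control
#' events exceed it under the strict `>` rule). An optional side-scatter
#' window restricts which control events inform the threshold and which
#' sample events are counted.
#'
#' @param negative_control [event_table()] of the batch's no-primary control.
#' @param quantile Background quantile defining the threshold; must lie in
#'   (0.5, 1). Default 0.99, the conventional 1% false-positive gate.
#' @param ssc_window Optional `c(low, high)` side-scatter window, linear units.
#' @param fluor_channel,ssc_channel Channel names carrying the antibody
#'   fluorescence (PE) and side-scatter roles.
#' @param control_id Identifier of the control sample, recorded for audit.
#' @return An object of class `col6_gate` with fields `fluor_threshold`,
#'   `quantile_used`, `ssc_window`, `fluor_channel`, `ssc_channel`,
#'   `derived_from`.
#' @export
derive_positive_gate <- function(negative_control, quantile = 0.99,
                                 ssc_window = NULL,
                                 fluor_channel = "PE", ssc_channel = "SSC",
                                 control_id = attr(negative_control, "sample_id")) {
  stopifnot(inherits(negative_control, "event_table"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0.5 || quantile >= 1) {
    stop("`quantile` must lie strictly between 0.5 and 1", call. = FALSE)
  }
  fl <- channel_values(negative_control, fluor_channel)
  if (!is.null(ssc_window)) {
    stopifnot(length(ssc_window) == 2L, ssc_window[1] <= ssc_window[2])
    ssc <- channel_values(negative_control, ssc_channel)
    keep <- ssc >= ssc_window[1] & ssc <= ssc_window[2]
    if (!any(keep)) stop("SSC window excludes every control event", call. = FALSE)
    fl <- fl[keep]
  }
  if (length(fl) < 100L) {
    warning(sprintf("negative control has only %d events; threshold will be noisy",
                    length(fl)), call. = FALSE)
  }
  structure(list(
    fluor_threshold = stats::quantile(fl, quantile, type = 1, names = FALSE),
    quantile_used = quantile,
    ssc_window = ssc_window,
    fluor_channel = fluor_channel,
    ssc_channel = ssc_channel,
    derived_from = if (is.null(control_id)) NA_character_ else control_id
  ), class = "col6_gate")
}

#' @export
print.col6_gate <- function(x, ...) {
  cat(sprintf("<col6_gate: %s > %.4g (q = %.3g from '%s')%s>\n",
              x$fluor_channel, x$fluor_threshold, x$quantile_used,
              x$derived_from,
              if (is.null(x$ssc_window)) "" else
                sprintf(", %s in [%g, %g]", x$ssc_channel,
                        x$ssc_window[1], x$ssc_window[2])))
  invisible(x)
}

#' Apply a gate to one sample
#'
#' An event counts as antigen-positive iff its fluorescence strictly exceeds
#' the gate threshold (ties go negative — conservative for a deficiency
#' screen) and, when the gate carries a side-scatter window, its SSC falls
#' inside it. Percent positive is taken over the gated (windowed) events.
#'
#' @param table An [event_table()].
#' @param gate A gate from [derive_positive_gate()].
#' @return List with `n_events_total`, `n_events_gated`, `n_positive`,
#'   `pct_positive`.
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(table, "event_table"), inherits(gate, "col6_gate"))
  fl <- channel_values(table, gate$fluor_channel)
  if (is.null(gate$ssc_window)) {
    gated <- rep(TRUE, length(fl))
  } else {
    ssc <- channel_values(table, gate$ssc_channel)
    gated <- ssc >= gate$ssc_window[1] & ssc <= gate$ssc_window[2]
  }
  n_gated <- sum(gated)
  if (n_gated == 0L) stop("no events inside the SSC window", call. = FALSE)
  n_pos <- sum(fl[gated] > gate$fluor_threshold)
  list(n_events_total = length(fl),
       n_events_gated = n_gated,
       n_positive = n_pos,
       pct_positive = 100 * n_pos / n_gated)
}

#' Gate every sample of a batch with one shared gate
#'
#' Applies the identical threshold to all samples. Elements may be
#' in-memory [event_table()]s or file paths (`.fcs` or `.csv`); a sample
#' whose file cannot be read is recorded as failed and the batch continues.
#'
#' @param samples Named list of [event_table()]s and/or file paths.
#' @param gate A `col6_gate`.
#' @return Data frame keyed by `sample_id` with the [apply_gate()] counts,
#'   an `ok` flag and an error `message` for failed samples; the number of
#'   failures is in `attr(, "n_failed")`.
#' @export
gate_batch <- function(samples, gate) {
  stopifnot(inherits(gate, "col6_gate"))
  ids <- names(samples)
  if (is.null(ids) || any(ids == "")) stop("`samples` must be a named list", call. = FALSE)
  rows <- lapply(ids, function(id) {
    res <- tryCatch({
      s <- samples[[id]]
      if (is.character(s)) s <- read_events(s)
      c(apply_gate(s, gate), list(ok = TRUE, message = NA_character_))
    }, error = function(e) {
      list(n_events_total = NA_integer_, n_events_gated = NA_integer_,
           n_positive = NA_integer_, pct_positive = NA_real_,
           ok = FALSE, message = conditionMessage(e))
    })
    data.frame(sample_id = id, n_events_total = res$n_events_total,
               n_events_gated = res$n_events_gated, n_positive = res$n_positive,
               pct_positive = res$pct_positive, ok = res$ok,
               message = res$message, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(!out$ok)
  out
}

#' Read sample events by file extension
#'
#' Dispatches to [read_fcs()] or [read_csv_events()] on extension.
#'
#' @param path `.fcs` or `.csv` file.
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         fcs = read_fcs(path),
         csv = read_csv_events(path),
         stop("unrecognised event file extension: .", ext, call. = FALSE))
}

#' Serialise / restore a gate as JSON
#'
#' Keeps a batch's gate auditable and reusable across runs.
#'
#' @param gate A `col6_gate`.
#' @param path JSON file path.
#' @return `write_gate()` returns `path` invisibly; `read_gate()` a gate.
#' @export
write_gate <- function(gate, path) {
  stopifnot(inherits(gate, "col6_gate"))
  rec <- unclass(gate)
  rec$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fluor_threshold = rec$fluor_threshold,
                 quantile_used = rec$quantile_used,
                 ssc_window = if (length(rec$ssc_window)) rec$ssc_window else NULL,
                 fluor_channel = rec$fluor_channel,
                 ssc_channel = rec$ssc_channel,
                 derived_from = rec$derived_from),
            class = "col6_gate")
}
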