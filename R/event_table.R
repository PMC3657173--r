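#' Event-level cytometry table
#'
#' Container for one acquired sample: one row per event, one column per
#' channel, all values on a linear scale. The screening assay needs at least
#' a side-scatter channel (`"SSC"`, linear) and an antibody fluorescence
#' channel (`"PE"`, linear storage; log10 is a display convention only).
#'
#' @param values Numeric matrix or data frame, events in rows, channels in
#'   columns. All values must be finite and non-negative.
#' @param channels Character vector of channel names; defaults to the column
#'   names of `values`.
#' @return A data frame of class `event_table`.
#' @examples
#' et <- event_table(cbind(SSC = c(420, 431), PE = c(12.1, 980.4)))
#' n_events(et)
#' @export
event_table <- function(values, channels = colnames(values)) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(values) < 1L) stop("an event table needs at least one event", call. = FALSE)
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  channels <- as.character(channels)
  if (length(channels) != ncol(values) || anyDuplicated(channels)) {
    stop("`channels` must uniquely name every column", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("event values must be finite (no missing values)", call. = FALSE)
  }
  if (any(values < 0)) stop("event values must be non-negative", call. = FALSE)
  out <- as.data.frame(values)
  names(out) <- channels
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' @rdname event_table
#' @param x An `event_table`.
#' @export
n_events <- function(x) nrow(x)

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %d events x %d channels [%s]>\n",
              nrow(x), ncol(x), paste(names(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("# ... with %d more events\n", nrow(x) - 5L))
  invisible(x)
}

# channel lookup with an error that names the missing channel
channel_values <- function(table, channel) {
  if (!channel %in% names(table)) {
    stop(sprintf("channel '%s' not present in event table (has: %s)",
                 channel, paste(names(table), collapse = ", ")), call. = FALSE)
  }
  table[[channel]]
}
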