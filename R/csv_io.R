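# CSV fallback for event tables, and the batch sample manifest.

#' Write / read event tables as CSV
#'
#' One row per event, header row naming the channels. A plain-text
#' alternative to FCS for pipelines and fixtures.
#'
#' @param table An [event_table()].
#' @param path CSV file path.
#' @return `write_csv_events()` returns `path` invisibly;
#'   `read_csv_events()` returns an [event_table()].
#' @export
write_csv_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_csv_events
#' @export
read_csv_events <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  event_table(df)
}

MANIFEST_CONDITIONS <- c("control", "BM", "UCMD", "negative_control", "unknown")

#' Read a batch sample manifest
#'
#' A manifest lists every acquired sample of a staining batch: columns
#' `sample_id`, `subject_id`, `condition`, `permeabilised`, and optionally
#' `file` (path to the sample's FCS/CSV events), `true_fraction` and `seed`
#' (simulation provenance). Sample ids must be unique and conditions must be
#' one of `control`, `BM`, `UCMD`, `negative_control`, `unknown`.
#'
#' @param path Manifest CSV path.
#' @return Data frame with validated columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "condition", "permeabilised")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$condition), MANIFEST_CONDITIONS)
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(MANIFEST_CONDITIONS, collapse = ", "),
         call. = FALSE)
  }
  df$permeabilised <- as.logical(df$permeabilised)
  if (anyNA(df$permeabilised)) {
    stop("`permeabilised` must be TRUE/FALSE for every sample", call. = FALSE)
  }
  df
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
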