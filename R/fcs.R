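# Minimal FCS 3.1 list-mode I/O.
#
# Writing targets the universally supported modern dialect: a single
# dataset, $MODE=L, $DATATYPE=F (float32), little-endian, no ANALYSIS
# segment. Reading additionally accepts FCS 3.0 and integer data
# ($DATATYPE=I, uniform 16- or 32-bit widths). Spillover matrices,
# multi-dataset files and the doubled-delimiter escape inside keyword
# values are out of scope.

FCS_HEADER_LEN <- 58L

#' Write an event table as an FCS 3.1 file
#'
#' Emits HEADER + TEXT + DATA segments with the required keywords
#' (`$TOT`, `$PAR`, `$PnN`, `$PnB`, `$PnE`, `$PnR`, `$DATATYPE=F`,
#' `$MODE=L`, `$BYTEORD=1,2,3,4`); events are stored row-major as
#' little-endian float32.
#'
#' @param table An [event_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  n <- nrow(table)
  p <- ncol(table)
  data_len <- 4L * n * p
  d <- "/"

  pnr <- vapply(table, function(v) {
    r <- max(1, ceiling(max(v)))
    format(2^ceiling(log2(r + 1)), scientific = FALSE)
  }, character(1))

  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "%010d", "$ENDDATA" = "%010d",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(p), "$TOT" = as.character(n))
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- names(table)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- pnr[i]
  }
  text_template <- paste0(d, paste0(names(kw), d, unname(kw), d, collapse = ""))

  text_start <- FCS_HEADER_LEN
  text_len <- nchar(text_template, type = "bytes") +
    2L * (10L - nchar("%010d"))       # each %010d placeholder expands to 10
  data_start <- text_start + text_len
  data_end <- data_start + data_len - 1L
  text <- sprintf(text_template, data_start, data_end)
  stopifnot(nchar(text, type = "bytes") == text_len)

  if (data_end > 99999999L) {
    # offsets too wide for the 8-char header fields: header carries zeros,
    # the TEXT $BEGINDATA/$ENDDATA keywords remain authoritative
    hdr_data <- c(0L, 0L)
  } else {
    hdr_data <- c(data_start, data_end)
  }
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    hdr_data[1], hdr_data[2], 0L, 0L)
  stopifnot(nchar(header) == FCS_HEADER_LEN)

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(as.matrix(table))), con, size = 4L, endian = "little")
  invisible(path)
}

# split a raw TEXT segment into a named keyword vector; the first byte is
# the delimiter (any single byte, not just '/')
parse_fcs_text <- function(text_raw) {
  if (length(text_raw) < 2L) stop("FCS TEXT segment is empty", call. = FALSE)
  delim <- rawToChar(text_raw[1L])
  body <- rawToChar(text_raw[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) && parts[1] == "") parts <- parts[-1]  # leading delimiter
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  if (length(parts) < 2L) stop("FCS TEXT segment has no keywords", call. = FALSE)
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  names(vals) <- trimws(toupper(keys))
  vals
}

fcs_keyword <- function(kw, name, required = TRUE) {
  if (!name %in% names(kw)) {
    if (required) stop(sprintf("corrupt FCS file: required keyword %s missing", name),
                       call. = FALSE)
    return(NA_character_)
  }
  unname(kw[[name]])
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Supports `$DATATYPE` `F` (float32) and `I` (uniform 16-bit unsigned or
#' 32-bit integer widths), `$MODE=L` only. Channel names come from `$PnN`.
#'
#' @param path FCS file path.
#' @return An [event_table()].
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) < FCS_HEADER_LEN) stop("corrupt FCS file: truncated header", call. = FALSE)
  version <- rawToChar(bytes[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS dialect: version '", version, "'", call. = FALSE)
  }
  off <- function(i) {   # i-th 8-byte ASCII offset field after byte 10
    s <- trimws(rawToChar(bytes[(11L + 8L * (i - 1L)):(10L + 8L * i)]))
    if (s == "") 0L else as.integer(s)
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  if (text_end > length(bytes) || text_start >= text_end) {
    stop("corrupt FCS file: bad TEXT offsets", call. = FALSE)
  }
  kw <- parse_fcs_text(bytes[(text_start + 1L):(text_end + 1L)])

  mode <- fcs_keyword(kw, "$MODE")
  if (mode != "L") stop("unsupported FCS dialect: $MODE=", mode, call. = FALSE)
  dtype <- fcs_keyword(kw, "$DATATYPE")
  if (!dtype %in% c("F", "I")) {
    stop("unsupported FCS dialect: $DATATYPE=", dtype, call. = FALSE)
  }
  tot <- as.integer(fcs_keyword(kw, "$TOT"))
  par <- as.integer(fcs_keyword(kw, "$PAR"))
  byteord <- fcs_keyword(kw, "$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported FCS dialect: $BYTEORD=", byteord, call. = FALSE))
  if (data_start == 0L) data_start <- as.integer(fcs_keyword(kw, "$BEGINDATA"))
  if (data_end == 0L) data_end <- as.integer(fcs_keyword(kw, "$ENDDATA"))

  widths <- if (dtype == "F") rep(32L, par) else {
    vapply(seq_len(par),
           function(i) as.integer(fcs_keyword(kw, sprintf("$P%dB", i))),
           integer(1))
  }
  if (dtype == "I" && length(unique(widths)) != 1L) {
    stop("unsupported FCS dialect: mixed integer channel widths", call. = FALSE)
  }
  size <- widths[1] / 8L
  if (dtype == "I" && !size %in% c(2L, 4L)) {
    stop("unsupported FCS dialect: $PnB=", widths[1], call. = FALSE)
  }
  need <- as.numeric(size) * tot * par
  if (data_end - data_start + 1L < need || data_end + 1L > length(bytes)) {
    stop("corrupt FCS file: DATA segment truncated", call. = FALSE)
  }
  data_raw <- bytes[(data_start + 1L):(data_start + need)]
  values <- if (dtype == "F") {
    readBin(data_raw, what = "numeric", n = tot * par, size = 4L, endian = endian)
  } else {
    readBin(data_raw, what = "integer", n = tot * par, size = size,
            signed = size > 2L, endian = endian)
  }
  channels <- vapply(seq_len(par),
                     function(i) fcs_keyword(kw, sprintf("$P%dN", i)),
                     character(1))
  mat <- matrix(values, nrow = tot, ncol = par, byrow = TRUE)
  event_table(mat, channels = channels)
}

#' Read the TEXT keywords of an FCS file
#'
#' Exposes the raw keyword/value pairs (e.g. `$TOT`, `$PnN`) without
#' touching the DATA segment; useful for gate audits.
#'
#' @param path FCS file path.
#' @return Named character vector of keywords.
#' @export
read_fcs_keywords <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  text_start <- as.integer(trimws(rawToChar(bytes[11:18])))
  text_end <- as.integer(trimws(rawToChar(bytes[19:26])))
  parse_fcs_text(bytes[(text_start + 1L):(text_end + 1L)])
}
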