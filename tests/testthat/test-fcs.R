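# FCS 3.1 / CSV event I/O.

test_that("FCS write/read round-trips within float32 rounding, preserving order", {
  et <- quick_sample(0.4, n = 500, seed = 17)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(et, path)
  back <- read_fcs(path)
  expect_named(back, c("SSC", "PE"))
  # float32 carries ~7 significant digits
  expect_equal(as.matrix(back), as.matrix(et), tolerance = 1e-6)
  # order preserved: per-event agreement, not just distributional
  expect_lt(max(abs(back$PE - et$PE) / pmax(et$PE, 1)), 1e-6)
})

test_that("required TEXT keywords describe a default acquisition", {
  et <- generate_sample(sample_plan("s", true_positive_fraction = 0.6, seed = 2))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(et, path)
  kw <- read_fcs_keywords(path)
  expect_identical(kw[["$TOT"]], "15000")   # the assay's standard event count
  expect_identical(kw[["$PAR"]], "2")
  expect_identical(kw[["$DATATYPE"]], "F")
  expect_identical(kw[["$MODE"]], "L")
  expect_identical(kw[["$P1N"]], "SSC")
  expect_identical(kw[["$P2N"]], "PE")
})

test_that("byte offsets are arithmetically consistent: 1 event x 2 channels = 8 bytes", {
  et <- event_table(cbind(SSC = 400, PE = 12.5))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(et, path)
  bytes <- readBin(path, "raw", file.size(path))
  hdr <- rawToChar(bytes[1:58])
  expect_match(hdr, "^FCS3\\.1")
  off <- function(i) as.integer(trimws(substr(hdr, 11 + 8 * (i - 1), 10 + 8 * i)))
  data_start <- off(3); data_end <- off(4)
  expect_identical(data_end - data_start + 1L, 8L)       # 2 x float32
  expect_identical(length(bytes), data_end + 1L)         # file ends with DATA
  kw <- read_fcs_keywords(path)
  expect_identical(kw[["$PAR"]], "2")
  expect_identical(kw[["$TOT"]], "1")
  expect_identical(as.integer(kw[["$BEGINDATA"]]), data_start)
  expect_identical(as.integer(kw[["$ENDDATA"]]), data_end)
})

# hand-build a small FCS file so reader error paths and foreign dialects
# can be exercised byte by byte
craft_fcs <- function(path, keywords, data_raw, delim = "/", version = "FCS3.1") {
  text <- paste0(delim, paste0(names(keywords), delim, unname(keywords), delim,
                               collapse = ""))
  text_start <- 58L
  text_end <- text_start + nchar(text, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + length(data_raw) - 1L
  header <- sprintf("%-10s%8d%8d%8d%8d%8d%8d", version, text_start, text_end,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (length(data_raw)) writeBin(data_raw, con)
  invisible(path)
}

base_keywords <- function(tot, par = 2L, dtype = "F") {
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0", "$BEGINSTEXT" = "0",
          "$ENDSTEXT" = "0", "$BYTEORD" = "1,2,3,4", "$DATATYPE" = dtype,
          "$MODE" = "L", "$NEXTDATA" = "0", "$PAR" = as.character(par),
          "$TOT" = as.character(tot))
  for (i in seq_len(par)) {
    kw[sprintf("$P%dN", i)] <- c("SSC", "PE")[i]
    kw[sprintf("$P%dB", i)] <- if (dtype == "F") "32" else "16"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "1024"
  }
  kw
}

test_that("non-default TEXT delimiters parse identically to a brute-force split oracle", {
  for (delim in c("|", "\\", "!")) {
    path <- withr::local_tempfile(fileext = ".fcs")
    kw <- base_keywords(1L)
    craft_fcs(path, kw, writeBin(c(400, 25), raw(), size = 4, endian = "little"),
              delim = delim)
    parsed <- read_fcs_keywords(path)
    # oracle: independent split of the crafted TEXT bytes
    bytes <- readBin(path, "raw", file.size(path))
    hdr <- rawToChar(bytes[1:58])
    text_end <- as.integer(trimws(substr(hdr, 19, 26)))
    expect_identical(rawToChar(bytes[59]), delim)
    toks <- strsplit(rawToChar(bytes[60:(text_end + 1L)]), delim, fixed = TRUE)[[1]]
    oracle <- toks[seq(2, 2 * length(kw), by = 2)]
    names(oracle) <- toupper(toks[seq(1, 2 * length(kw) - 1, by = 2)])
    expect_identical(parsed[names(kw)], oracle[names(kw)])
    # and the events themselves decode
    et <- read_fcs(path)
    expect_equal(unname(as.matrix(et)[1, ]), c(400, 25))
  }
})

test_that("integer list-mode files (16-bit unsigned) are readable", {
  path <- withr::local_tempfile(fileext = ".fcs")
  vals <- c(400L, 25L, 380L, 900L)  # 2 events x 2 channels, row-major
  craft_fcs(path, base_keywords(2L, dtype = "I"),
            writeBin(vals, raw(), size = 2, endian = "little"))
  et <- read_fcs(path)
  expect_equal(as.vector(t(as.matrix(et))), vals)
})

test_that("corrupt or unsupported files give explicit errors", {
  # missing $TOT
  path <- withr::local_tempfile(fileext = ".fcs")
  kw <- base_keywords(1L)
  craft_fcs(path, kw[names(kw) != "$TOT"],
            writeBin(c(1, 2), raw(), size = 4, endian = "little"))
  expect_error(read_fcs(path), "\\$TOT")

  # truncated DATA segment
  path2 <- withr::local_tempfile(fileext = ".fcs")
  craft_fcs(path2, base_keywords(10L),
            writeBin(c(1, 2), raw(), size = 4, endian = "little"))
  expect_error(read_fcs(path2), "truncated")

  # unsupported histogram mode and datatype
  path3 <- withr::local_tempfile(fileext = ".fcs")
  kw3 <- base_keywords(1L); kw3[["$MODE"]] <- "U"
  craft_fcs(path3, kw3, writeBin(c(1, 2), raw(), size = 4, endian = "little"))
  expect_error(read_fcs(path3), "unsupported FCS dialect")

  path4 <- withr::local_tempfile(fileext = ".fcs")
  kw4 <- base_keywords(1L); kw4[["$DATATYPE"]] <- "A"
  craft_fcs(path4, kw4, writeBin(c(1, 2), raw(), size = 4, endian = "little"))
  expect_error(read_fcs(path4), "\\$DATATYPE")

  # FCS 2.0 container
  path5 <- withr::local_tempfile(fileext = ".fcs")
  craft_fcs(path5, base_keywords(1L),
            writeBin(c(1, 2), raw(), size = 4, endian = "little"),
            version = "FCS2.0")
  expect_error(read_fcs(path5), "version")
})

test_that("CSV event tables round-trip exactly", {
  et <- quick_sample(0.3, n = 200, seed = 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_events(et, path)
  back <- read_csv_events(path)
  expect_equal(as.matrix(back), as.matrix(et))
  expect_named(back, names(et))
})

test_that("manifest validation enforces schema, uniqueness and known conditions", {
  man <- data.frame(
    sample_id = c(paste0("P", 1:13), paste0("C", 1:5)),
    subject_id = c(paste0("P", 1:13), paste0("C", 1:5)),
    condition = c(rep("UCMD", 8), rep("BM", 5), rep("control", 5)),
    permeabilised = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  loaded <- read_manifest(path)
  expect_identical(nrow(loaded), 18L)  # 13 patients + 5 controls
  expect_identical(length(unique(loaded$subject_id)), 18L)

  dup <- man; dup$sample_id[2] <- dup$sample_id[1]
  write_manifest(dup, path)
  expect_error(read_manifest(path), "duplicate sample_id")

  bad <- man; bad$condition[1] <- "UCDM"
  write_manifest(bad, path)
  expect_error(read_manifest(path), "unknown condition")

  incomplete <- man[, c("sample_id", "condition")]
  write_manifest(incomplete, path)
  expect_error(read_manifest(path), "missing columns")
})
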