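# BrainVision file triplet (.vhdr/.vmrk/.eeg) reader and writer for the
# documented subset: multiplexed binary data, IEEE float32 or int16 with
# per-channel resolution, stimulus markers with sample positions.

parse_vhdr_sections <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character(0)
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      sections[[current]][key] <- val
    }
  }
  sections
}

#' Read a BrainVision recording
#'
#' Supports multiplexed binary data in IEEE_FLOAT_32 or INT_16 (scaled by
#' the per-channel resolution), with `Stimulus` markers parsed into events.
#'
#' @param header_path Path to the `.vhdr` header; the data and marker files
#'   it names must sit alongside it.
#' @return An `eeg_recording` (data in uV). Stimulus descriptions become the
#'   `stimulus_id` column; a `condition` column is filled from the
#'   description when it is encoded as `id/condition`.
#' @export
read_brainvision <- function(header_path) {
  stop_if_not(file.exists(header_path), "header not found: %s", header_path)
  dir <- dirname(header_path)
  sec <- parse_vhdr_sections(readLines(header_path, warn = FALSE))
  ci <- sec[["Common Infos"]]
  stop_if_not(!is.null(ci), "no [Common Infos] section in header")
  stop_if_not(identical(toupper(ci[["DataFormat"]]), "BINARY"),
              "unsupported DataFormat '%s' (only BINARY)", ci[["DataFormat"]])
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  stop_if_not(orientation == "MULTIPLEXED",
              "unsupported DataOrientation '%s' (only MULTIPLEXED)", orientation)
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  bin_fmt <- toupper(sec[["Binary Infos"]][["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  stop_if_not(bin_fmt %in% c("IEEE_FLOAT_32", "INT_16"),
              "unsupported BinaryFormat '%s'", bin_fmt)
  chinfo <- sec[["Channel Infos"]]
  stop_if_not(length(chinfo) == n_ch, "channel info does not match channel count")
  parts <- strsplit(unname(chinfo), ",")
  ch_names <- vapply(parts, `[`, character(1), 1)
  resolution <- vapply(parts, function(p) {
    r <- if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
    if (is.na(r)) 1 else r
  }, numeric(1))

  data_path <- file.path(dir, ci[["DataFile"]])
  stop_if_not(file.exists(data_path), "data file not found: %s", data_path)
  size <- file.info(data_path)$size
  con <- file(data_path, "rb")
  raw <- if (bin_fmt == "IEEE_FLOAT_32") {
    readBin(con, numeric(), n = size / 4, size = 4, endian = "little")
  } else {
    readBin(con, integer(), n = size / 2, size = 2, endian = "little")
  }
  close(con)
  n_samples <- length(raw) %/% n_ch
  data <- matrix(raw[seq_len(n_ch * n_samples)], nrow = n_ch)
  if (bin_fmt == "INT_16") data <- data * resolution
  events <- data.frame(sample = integer(), stimulus_id = character(),
                       condition = character(), stringsAsFactors = FALSE)
  marker_file <- ci[["MarkerFile"]]
  if (!is.null(marker_file) && file.exists(file.path(dir, marker_file))) {
    msec <- parse_vhdr_sections(readLines(file.path(dir, marker_file), warn = FALSE))
    mk <- msec[["Marker Infos"]]
    if (length(mk)) {
      mparts <- strsplit(unname(mk), ",")
      types <- vapply(mparts, `[`, character(1), 1)
      keep <- types == "Stimulus"
      if (any(keep)) {
        desc <- vapply(mparts[keep], `[`, character(1), 2)
        pos <- as.integer(vapply(mparts[keep], `[`, character(1), 3))
        id <- sub("/.*$", "", desc)
        cond <- ifelse(grepl("/", desc), sub("^[^/]*/", "", desc), NA_character_)
        events <- data.frame(sample = pos, stimulus_id = id, condition = cond,
                             stringsAsFactors = FALSE)
        events <- events[order(events$sample), , drop = FALSE]
      }
    }
  }
  eeg_recording(data, sfreq, ch_names, events)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `base_path`.vhdr/.vmrk/.eeg with multiplexed IEEE float32 data and
#' `Stimulus` markers encoded as `stimulus_id/condition`.
#'
#' @param rec An `eeg_recording`.
#' @param base_path Output path without extension.
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(rec, base_path) {
  base <- basename(base_path)
  vhdr <- paste0(base_path, ".vhdr")
  vmrk <- paste0(base_path, ".vmrk")
  eegf <- paste0(base_path, ".eeg")
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$sfreq, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$ch_names)
  )
  writeLines(header, vhdr, useBytes = TRUE)
  markers <- c(
    "Brain Vision Data Exchange Marker File Version 1.0",
    "", "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec$events)) {
    desc <- rec$events$stimulus_id
    if (!is.null(rec$events$condition)) {
      has_cond <- !is.na(rec$events$condition)
      desc[has_cond] <- paste0(desc[has_cond], "/", rec$events$condition[has_cond])
    }
    markers <- c(markers, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                                  seq_len(nrow(rec$events)) + 1L,
                                  desc, rec$events$sample))
  }
  writeLines(markers, vmrk, useBytes = TRUE)
  con <- file(eegf, "wb")
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}
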