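#' Write a recording as BrainVision files
#'
#' Produces the standard `.vhdr` / `.vmrk` / `.eeg` triplet: text headers
#' plus multiplexed IEEE float32 samples in uV. Block events are stored as
#' stimulus markers named `block/<condition>/<id>` whose position and length
#' are in data points.
#'
#' @param rec An `sbc_recording`.
#' @param basepath Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basepath) {
  base <- basename(basepath)
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg <- paste0(basepath, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$labels))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (!is.null(rec$events) && nrow(rec$events) > 0) {
    pos <- round(rec$events$onset_s * rec$rate) + 1L
    len <- round((rec$events$offset_s - rec$events$onset_s) * rec$rate)
    mk <- c(mk, sprintf("Mk%d=Stimulus,block/%s/%d,%d,%d,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$condition, rec$events$block_id, pos, len))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

bv_section <- function(lines, name) {
  starts <- grep("^\\[", lines)
  s <- grep(paste0("^\\[", name, "\\]"), lines)
  if (length(s) == 0) return(character(0))
  nxt <- starts[starts > s[1]]
  end <- if (length(nxt) == 0) length(lines) else nxt[1] - 1L
  lines[(s[1] + 1L):end]
}

#' Read a BrainVision recording
#'
#' Supports multiplexed IEEE float32 binary data with the marker convention
#' of [write_brainvision()]; stimulus markers named
#' `block/<condition>/<id>` are decoded into the events table.
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @return An `sbc_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  common <- bv_section(lines, "Common Infos")
  get <- function(key, from = common) {
    m <- grep(paste0("^", key, "="), from, value = TRUE)
    if (length(m) == 0) stop("missing ", key, " in ", vhdr_path)
    sub(paste0("^", key, "="), "", m[1])
  }
  if (get("DataOrientation") != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation supported")
  binfmt <- get("BinaryFormat", bv_section(lines, "Binary Infos"))
  if (binfmt != "IEEE_FLOAT_32") stop("only IEEE_FLOAT_32 supported")
  nch <- as.integer(get("NumberOfChannels"))
  rate <- 1e6 / as.numeric(get("SamplingInterval"))
  chs <- bv_section(lines, "Channel Infos")
  chs <- grep("^Ch[0-9]+=", chs, value = TRUE)
  labels <- vapply(chs, function(l)
    strsplit(sub("^Ch[0-9]+=", "", l), ",")[[1]][1], character(1),
    USE.NAMES = FALSE)

  dir <- dirname(vhdr_path)
  con <- file(file.path(dir, get("DataFile")), "rb")
  vals <- readBin(con, numeric(), n = file.size(file.path(dir, get("DataFile"))) / 4,
                  size = 4, endian = "little")
  close(con)
  data <- matrix(vals, nrow = nch, dimnames = list(labels, NULL))

  mlines <- readLines(file.path(dir, get("MarkerFile")), warn = FALSE)
  mk <- grep("^Mk[0-9]+=Stimulus,block/", bv_section(mlines, "Marker Infos"),
             value = TRUE)
  events <- data.frame(block_id = integer(0), onset_s = numeric(0),
                       offset_s = numeric(0), condition = character(0))
  if (length(mk) > 0) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    desc <- strsplit(vapply(parts, `[[`, character(1), 2), "/")
    pos <- as.numeric(vapply(parts, `[[`, character(1), 3))
    len <- as.numeric(vapply(parts, `[[`, character(1), 4))
    events <- data.frame(
      block_id = as.integer(vapply(desc, `[[`, character(1), 3)),
      onset_s = (pos - 1) / rate,
      offset_s = (pos - 1 + len) / rate,
      condition = vapply(desc, `[[`, character(1), 2),
      stringsAsFactors = FALSE)
  }
  structure(list(data = data, labels = labels,
                 types = channel_types(labels), rate = rate,
                 events = events),
            class = "sbc_recording")
}
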