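#' Read an EEG recording from disk
#'
#' Supported formats, dispatched on the file extension:
#' \describe{
#'   \item{`.edf`}{European Data Format (16-bit); amplitudes are rescaled to
#'     microvolts from the header's physical range.}
#'   \item{`.tsv`, `.csv`, `.txt`}{Delimited numeric matrix, one column per
#'     channel, with a header row of channel labels. Sampling rate and
#'     metadata come from a JSON sidecar `<path>.json` (fields `fs`,
#'     `lesion_side`, `reference`).}
#' }
#'
#' @param path file path.
#' @param lesion_side,reference overrides for metadata absent from the file.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, lesion_side = NULL, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("edf")) {
    rec <- read_edf(path)
  } else if (ext %in% c("tsv", "csv", "txt")) {
    rec <- read_eeg_delim(path)
  } else {
    stop("unsupported EEG format '.", ext,
         "'; supported: .edf, .tsv, .csv, .txt")
  }
  if (!is.null(lesion_side)) rec$lesion_side <- match.arg(lesion_side, c("left", "right"))
  if (!is.null(reference)) rec$reference <- reference
  rec
}

#' Write an EEG recording to disk
#'
#' Formats as in [read_eeg()]. The delimited writer also emits a JSON sidecar
#' `<path>.json` carrying the sampling rate, lesion side and reference tag.
#'
#' @param rec an [eeg_recording].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    write_edf(rec, path)
  } else if (ext %in% c("tsv", "csv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    mat <- t(rec$samples)
    colnames(mat) <- rec$channels
    utils::write.table(mat, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    meta <- list(fs = rec$fs, lesion_side = rec$lesion_side,
                 reference = rec$reference)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    stop("unsupported EEG format '.", ext,
         "'; supported: .edf, .tsv, .csv, .txt")
  }
  invisible(path)
}

read_eeg_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext == "csv") "," else "\t"
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty or truncated EEG file: ", path)
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!nrow(dat) || !all(vapply(dat, is.numeric, TRUE))) {
    stop("malformed delimited EEG matrix in ", path)
  }
  side <- paste0(path, ".json")
  meta <- list(fs = 512, lesion_side = "left", reference = "unknown")
  if (file.exists(side)) {
    got <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  eeg_recording(t(as.matrix(dat)), fs = meta$fs, channels = colnames(dat),
                lesion_side = meta$lesion_side, reference = meta$reference)
}

# --- minimal EDF (16-bit European Data Format) support -----------------------
# Continuous recordings are stored as a single data record whose duration is
# n_samples / fs. Physical range spans the observed data; digital range is
# the full signed 16-bit range, so quantisation error is (max-min)/65535.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- length(rec$channels)
  n <- ncol(rec$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad(paste("Startdate X X X X lesion", rec$lesion_side), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8),            # header bytes
    edf_pad("", 44),
    edf_pad(1, 8),                         # number of data records
    edf_pad(format(n / rec$fs, digits = 7), 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  pmin_ <- apply(rec$samples, 1, min)
  pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep(paste("AgAgCl ref", rec$reference), ns), 80)
  field(rep("uV", ns), 8)
  field(format(pmin_, digits = 7), 8)
  field(format(pmax_, digits = 7), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(n, ns), 8)
  field(rep("", ns), 32)
  for (j in seq_len(ns)) {
    dig <- round((rec$samples[j, ] - pmin_[j]) / (pmax_[j] - pmin_[j]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    if (nchar(out, type = "bytes") < width) {
      stop("truncated EDF header in ", path)
    }
    trimws(out)
  }
  rd(8)
  rd(80)
  rec_info <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0) stop("truncated or malformed EDF header in ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  chunks <- vector("list", ns)
  for (j in seq_len(ns)) chunks[[j]] <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[j], size = 2,
                     signed = TRUE, endian = "little")
      if (length(dig) < nsamp[j]) stop("truncated EDF data in ", path)
      phys <- pmin_[j] + (dig - dmin_[j]) / (dmax_[j] - dmin_[j]) *
        (pmax_[j] - pmin_[j])
      chunks[[j]] <- c(chunks[[j]], phys)
    }
  }
  samples <- do.call(rbind, chunks)
  fs <- nsamp[1] / dur
  side <- if (grepl("lesion right", rec_info)) "right" else "left"
  eeg_recording(samples, fs = round(fs, 6), channels = labels,
                lesion_side = side)
}

# --- trial logs --------------------------------------------------------------

#' Write / read a trial log as JSON lines
#'
#' One trial per line; per-step posterior traces are carried inline so that
#' contingency analysis can be re-run from the serialized log alone.
#'
#' @param log a `trial_log` data frame (see [gen_therapy_course()]).
#' @param path output path.
#' @return `path` (writer) or a `trial_log` (reader).
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- list(
      schema = "bcifes-trial/1", run = log$run[i], trial = log$trial[i],
      true_class = log$true_class[i], arm = attr(log, "arm"),
      t_fes = log$t_fes[i], decision = log$decision[i],
      decision_time = log$decision_time[i],
      step_times = log$step_times[[i]], posterior = log$posterior[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  log <- data.frame(
    run = vapply(rows, function(r) as.integer(r$run), 1L),
    trial = vapply(rows, function(r) as.integer(r$trial), 1L),
    true_class = vapply(rows, function(r) as.character(r$true_class), ""),
    t_fes = vapply(rows, function(r) if (is.null(r$t_fes)) NA_real_ else as.numeric(r$t_fes), 1),
    decision = vapply(rows, function(r) as.character(r$decision), ""),
    decision_time = vapply(rows, function(r) if (is.null(r$decision_time)) NA_real_ else as.numeric(r$decision_time), 1)
  )
  log$step_times <- I(lapply(rows, function(r) as.numeric(r$step_times)))
  log$posterior <- I(lapply(rows, function(r) as.numeric(r$posterior)))
  class(log) <- c("trial_log", class(log))
  attr(log, "arm") <- rows[[1]]$arm
  log
}
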