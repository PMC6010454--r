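#' EEG recording container
#'
#' A minimal channels-by-time container for multichannel EEG. Amplitudes are
#' in microvolts, channel labels follow the 10/20 convention (stored
#' upper-case), and the lesion side is carried along so that downstream
#' montage flipping can align all subjects on a common hemisphere.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling frequency in Hz.
#' @param channels character vector of 10/20 channel labels, one per row of
#'   `samples`; must be unique.
#' @param lesion_side `"left"` or `"right"`.
#' @param reference free-text tag describing the reference (e.g. `"mastoid"`,
#'   `"CAR"`, `"laplacian"`).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channels,
                          lesion_side = c("left", "right"),
                          reference = "unknown") {
  samples <- as.matrix(samples)
  lesion_side <- match.arg(lesion_side)
  channels <- toupper(as.character(channels))
  if (nrow(samples) != length(channels)) {
    stop("`samples` must have one row per channel label (",
         nrow(samples), " rows vs ", length(channels), " labels)")
  }
  if (anyDuplicated(channels)) {
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }
  if (anyNA(samples)) stop("`samples` contains NA values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  rownames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         lesion_side = lesion_side, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  cat("  lesion side:", x$lesion_side, " reference:", x$reference, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)

#' Homologous left/right channel pairs of a montage
#'
#' Lateral 10/20 labels carry an odd (left) or even (right) final digit;
#' midline labels end in `z`. Pairs are matched by swapping the digit parity
#' (C3 <-> C4, FC1 <-> FC2, CP5 <-> CP6, ...).
#'
#' @param channels character vector of 10/20 labels.
#' @return data frame with columns `left` and `right`.
#' @keywords internal
homologous_pairs <- function(channels) {
  channels <- toupper(channels)
  m <- regmatches(channels, regexec("^([A-Z]+)([0-9]+)$", channels))
  lateral <- vapply(m, length, 1L) == 3L
  out <- list(left = character(), right = character())
  for (ch in channels[lateral]) {
    parts <- regmatches(ch, regexec("^([A-Z]+)([0-9]+)$", ch))[[1]]
    num <- as.integer(parts[3])
    if (num %% 2L == 1L) {
      partner <- paste0(parts[2], num + 1L)
      if (!(partner %in% channels)) {
        stop("unpaired lateral channel: ", ch, " (no ", partner, ")")
      }
      out$left <- c(out$left, ch)
      out$right <- c(out$right, partner)
    } else {
      partner <- paste0(parts[2], num - 1L)
      if (!(partner %in% channels)) {
        stop("unpaired lateral channel: ", ch, " (no ", partner, ")")
      }
    }
  }
  data.frame(left = out$left, right = out$right)
}
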