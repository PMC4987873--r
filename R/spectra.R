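# Centroided MS2 spectrum container.

#' Construct an MS2 spectrum
#'
#' Peaks are stored as a two-column matrix (`mz`, `intensity`), sorted
#' ascending by m/z. Exact duplicate m/z values are collapsed to the most
#' intense peak.
#'
#' @param title Spectrum identifier.
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Positive integer precursor charge.
#' @param peaks Two-column numeric matrix or data.frame (`mz`, `intensity`).
#' @param rt Retention time in seconds, or `NA`.
#' @return A `glyco_spectrum` object.
#' @export
new_spectrum <- function(title, precursor_mz, precursor_charge, peaks,
                         rt = NA_real_) {
  stopifnot(is.character(title), length(title) == 1L,
            is.numeric(precursor_mz), precursor_mz > 0,
            precursor_charge >= 1)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)", call. = FALSE)
  colnames(peaks) <- c("mz", "intensity")
  storage.mode(peaks) <- "double"
  if (nrow(peaks)) {
    if (any(peaks[, "mz"] <= 0)) stop("peak m/z must be positive", call. = FALSE)
    if (any(peaks[, "intensity"] < 0)) stop("peak intensity must be >= 0", call. = FALSE)
    peaks <- peaks[order(peaks[, "mz"], -peaks[, "intensity"]), , drop = FALSE]
    dup <- duplicated(peaks[, "mz"])
    if (any(dup)) peaks <- peaks[!dup, , drop = FALSE]
  }
  structure(
    list(title = title, precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge),
         rt = rt, peaks = peaks),
    class = "glyco_spectrum"
  )
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("<glyco_spectrum> %s\n  precursor %.4f Th (%d+)%s, %d peaks\n",
              x$title, x$precursor_mz, x$precursor_charge,
              if (is.na(x$rt)) "" else sprintf(", RT %.1f s", x$rt),
              nrow(x$peaks)))
  invisible(x)
}

# Indices of peaks within `tol` of each target m/z; returns an integer vector
# (NA where no peak matches). Peaks are assumed sorted; nearest peak wins.
.nearest_peak <- function(peaks, targets, tol) {
  if (!nrow(peaks) || !length(targets)) return(rep(NA_integer_, length(targets)))
  mz <- peaks[, "mz"]
  idx <- findInterval(targets, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(mz[lo] - targets)
  d_hi <- abs(mz[hi] - targets)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  out <- ifelse(d <= tol, best, NA_integer_)
  as.integer(out)
}

# All peak indices within tol of a single target m/z.
.peaks_within <- function(peaks, target, tol) {
  if (!nrow(peaks)) return(integer())
  mz <- peaks[, "mz"]
  lo <- findInterval(target - tol, mz) + 1L
  hi <- findInterval(target + tol, mz)
  if (hi < lo) integer() else lo:hi
}
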