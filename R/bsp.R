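#' Body-surface potential map
#'
#' An M-electrodes x T-samples potential matrix with sampling metadata.
#' The standard ectopic-beat input covers the first 30 ms of the beat at
#' 1 kHz (T = 30).  Maps are referenced to a zero-mean common reference
#' per sample before any fitting (see [dipole_lsq()]).
#'
#' @param potentials numeric matrix (M x T).
#' @param sample_rate sampling rate in Hz.
#' @param electrode_labels optional length-M labels.
#' @return object of class `bsp_map`.
#' @export
bsp_map <- function(potentials, sample_rate = 1000,
                    electrode_labels = NULL) {
  potentials <- as.matrix(potentials)
  if (ncol(potentials) < 1L) stop("map must have at least one sample")
  if (any(!is.finite(potentials))) stop("non-finite map entries")
  if (!is.null(electrode_labels) &&
      length(electrode_labels) != nrow(potentials))
    stop("electrode_labels length must match electrode count")
  structure(list(potentials = potentials,
                 sample_rate = as.numeric(sample_rate),
                 electrode_labels = electrode_labels),
            class = "bsp_map")
}

#' @export
print.bsp_map <- function(x, ...) {
  cat(sprintf("bsp_map: %d electrodes x %d samples @ %g Hz\n",
              nrow(x$potentials), ncol(x$potentials), x$sample_rate))
  invisible(x)
}

#' @export
dim.bsp_map <- function(x) dim(x$potentials)

## zero-mean common reference per sample (columns)
rereference <- function(potentials) {
  sweep(potentials, 2L, colMeans(potentials), `-`)
}

#' Read / write a BSP map as CSV
#'
#' Rows are electrodes; the header holds sample times in ms derived from
#' the sampling rate.
#'
#' @param map a [bsp_map()].
#' @param path CSV file path.
#' @param sample_rate sampling rate assumed on read if the header does
#'   not encode times (Hz).
#' @return `path` (write) or a [bsp_map()] (read).
#' @export
write_bsp <- function(map, path) {
  tms <- (seq_len(ncol(map$potentials)) - 1L) / map$sample_rate * 1000
  d <- as.data.frame(map$potentials)
  names(d) <- sprintf("t%.6g", tms)
  d <- cbind(electrode = if (is.null(map$electrode_labels))
    as.character(seq_len(nrow(d))) else map$electrode_labels, d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bsp
#' @export
read_bsp <- function(path, sample_rate = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(d[[1L]])
  pot <- as.matrix(d[, -1L, drop = FALSE])
  tms <- suppressWarnings(as.numeric(sub("^t", "", colnames(pot))))
  if (is.null(sample_rate)) {
    sample_rate <- if (length(tms) > 1L && !anyNA(tms))
      1000 / stats::median(diff(tms)) else 1000
  }
  bsp_map(unname(pot), sample_rate = sample_rate, electrode_labels = labels)
}

#' Per-electrode signal power
#'
#' Power of each electrode's signal computed as the square of its root
#' mean square value, used to contrast signal power against
#' transfer-matrix electrode significance.
#'
#' @param signals numeric matrix (M x T) or a [bsp_map()].
#' @return numeric vector of length M.
#' @export
electrode_power <- function(signals) {
  if (inherits(signals, "bsp_map")) signals <- signals$potentials
  signals <- as.matrix(signals)
  rowMeans(signals^2)
}
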