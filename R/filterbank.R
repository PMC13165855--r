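#' Define a frequency band
#'
#' A band is a named passband with lower and upper edges in Hz. Edges must
#' satisfy `0 < low < high`; whether they fit under the Nyquist frequency is
#' checked when the band is applied to a signal of known sampling rate.
#'
#' @param name Band label (e.g. `"theta"`).
#' @param low,high Passband edges in Hz.
#' @return A `band_definition` object.
#' @export
#' @examples
#' band_definition("theta", 4, 8)
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("band '", name, "': edges must satisfy 0 < low < high (got ",
         low, ", ", high, ")")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Filter-bank specification
#'
#' An ordered list of passbands plus the Butterworth design parameters used
#' to realize them. The default is the nine-band fatigue decomposition:
#' delta (0.5-4), theta (4-8), alpha1 (8-10), alpha2 (10-13), beta1 (13-20),
#' beta2 (20-30), gamma1 (30-36), gamma2 (36-42) and broadband (0.5-45) Hz,
#' in that order. Band axis index 1 is delta, index 9 is broadband.
#'
#' @param bands List of [band_definition()] objects, in band-axis order.
#' @param order Butterworth design order (applied forward and backward, so
#'   the effective magnitude response is of twice this order).
#' @param zero_phase Apply the filter forward and backward (zero phase
#'   distortion). The bank is only defined for zero-phase operation; the
#'   flag is retained so single-pass filtering can be requested explicitly.
#' @return A `filter_bank_spec` object.
#' @export
filter_bank_spec <- function(bands = default_bands(), order = 4L,
                             zero_phase = TRUE) {
  stopifnot(is.list(bands), length(bands) >= 1L)
  for (b in bands) {
    if (!inherits(b, "band_definition")) {
      stop("all elements of 'bands' must be band_definition objects")
    }
  }
  nm <- vapply(bands, function(b) b$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate band names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(bands = bands, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank_spec")
}

#' @rdname filter_bank_spec
#' @export
default_bands <- function() {
  list(
    band_definition("delta",     0.5,  4),
    band_definition("theta",     4,    8),
    band_definition("alpha1",    8,   10),
    band_definition("alpha2",   10,   13),
    band_definition("beta1",    13,   20),
    band_definition("beta2",    20,   30),
    band_definition("gamma1",   30,   36),
    band_definition("gamma2",   36,   42),
    band_definition("broadband", 0.5, 45)
  )
}

#' @rdname filter_bank_spec
#' @export
default_filter_bank <- function() filter_bank_spec()

#' @export
print.filter_bank_spec <- function(x, ...) {
  cat("Filter bank:", length(x$bands), "bands, Butterworth order",
      x$order, if (x$zero_phase) "(zero phase)\n" else "(single pass)\n")
  for (i in seq_along(x$bands)) {
    b <- x$bands[[i]]
    cat(sprintf("  [%d] %-9s %5.1f-%5.1f Hz\n", i, b$name, b$low, b$high))
  }
  invisible(x)
}

band_names <- function(spec) vapply(spec$bands, `[[`, character(1), "name")

#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass filter of the given order and applies it
#' forward and backward along time (zero phase distortion; effective
#' magnitude order is twice the design order). Edge transients are bounded
#' by odd-reflection padding of length 3x the effective filter order before
#' filtering; the padding is removed afterwards.
#'
#' @param x Numeric matrix, channels x time, or a numeric vector (treated as
#'   one channel).
#' @param fs Sampling rate in Hz.
#' @param low,high Passband edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#'
#' @details The reflection padding is sized from the filter's slowest pole
#' (about six time constants, at least 3x the effective order, capped at
#' the signal length minus one) and each pass starts from the steady state
#' of its first padded sample, so constant (DC) input is suppressed
#' exactly and pass-band sinusoids emerge with the designed magnitude away
#' from the signal edges. Very short signals relative to the low-edge time
#' constant retain some edge transient; a low edge of 0.5 Hz is fully
#' settled for epochs of a few seconds.
#' @return Filtered matrix with the same shape as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' x <- rbind(sin(2 * pi * 10 * t))        # 10 Hz lies inside 0.5-45 Hz
#' y <- apply_zero_phase_bandpass(x, 200, 0.5, 45)
apply_zero_phase_bandpass <- function(x, fs, low, high, order = 4L) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, nrow = 1L)
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low ||
      high >= fs / 2) {
    stop("invalid band edges [", low, ", ", high, "] Hz for fs = ", fs,
         " Hz (need 0 < low < high < fs/2)")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  nmin <- 3L * (length(bf$b) - 1L)   # 3 x effective order
  if (ncol(x) <= nmin) {
    stop("signal too short for stable filtering: ", ncol(x),
         " samples, need more than ", nmin)
  }
  # pad long enough for the slowest pole's transient to decay (~r^npad
  # below 2.5e-3), capped by the available signal
  r <- max(Mod(polyroot(rev(bf$a))))
  npad <- min(ncol(x) - 1L,
              max(nmin, ceiling(6 / max(1e-9, 1 - r))))
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- filtfilt_reflect(bf$b, bf$a, x[ch, ], npad)
  }
  if (vec_in) out <- drop(out)
  out
}

# forward-backward filtering with odd-reflection padding at both ends;
# each pass starts from the steady state of its first sample, so constant
# inputs map exactly to H(1) * x and edge transients stay bounded
filtfilt_reflect <- function(b, a, x, npad) {
  n <- length(x)
  pre  <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(pre, x, post)
  h1 <- sum(b) / sum(a)
  pass <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], length(b) - 1L),
                              init.y = rep(v[1] * h1, length(a) - 1L)))
  }
  y <- pass(xp)
  y <- rev(pass(rev(y)))
  y[npad + seq_len(n)]
}

#' Decompose an epoch into its multi-band tensor
#'
#' Passes one preprocessed epoch through the filter bank, producing the
#' `Nb x C x T` multi-band tensor the network consumes: slice `b` along the
#' first axis is the band-`b` filtered copy of the epoch.
#'
#' @param epoch An [eeg_epoch()] object, or a channels x time matrix (in
#'   which case `fs` must be supplied).
#' @param spec A [filter_bank_spec()]; default is the nine-band bank.
#' @param fs Sampling rate in Hz, only used when `epoch` is a bare matrix.
#' @return A `multiband_tensor`: numeric array `(Nb, C, T)` with attributes
#'   `band_spec` and `band_names`.
#' @export
filter_bank_decompose <- function(epoch, spec = default_filter_bank(),
                                  fs = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples
    fs <- epoch$fs
  } else {
    x <- epoch
    if (is.null(fs)) stop("'fs' is required when 'epoch' is a bare matrix")
  }
  stopifnot(is.matrix(x))
  for (b in spec$bands) {
    if (b$high >= fs / 2) {
      stop("band '", b$name, "' upper edge ", b$high,
           " Hz reaches the Nyquist frequency (fs/2 = ", fs / 2, " Hz)")
    }
  }
  nb <- length(spec$bands)
  out <- array(0, dim = c(nb, nrow(x), ncol(x)))
  for (i in seq_len(nb)) {
    out[i, , ] <- apply_zero_phase_bandpass(x, fs, spec$bands[[i]]$low,
                                            spec$bands[[i]]$high, spec$order)
  }
  structure(out, band_spec = spec, band_names = band_names(spec),
            class = c("multiband_tensor", "array"))
}

#' Zero all but a chosen subset of bands
#'
#' Used by the single-band masking analysis: the masked tensor keeps the
#' selected band slices bit-identical and sets every other slice to exactly
#' zero, so a trained network can be probed band-by-band without retraining.
#'
#' @param xfb A multi-band tensor `(Nb, C, T)`.
#' @param keep Integer indices (1-based along the band axis) or band names
#'   to retain.
#' @return Tensor of the same shape with non-kept slices zeroed.
#' @export
mask_bands <- function(xfb, keep) {
  stopifnot(length(dim(xfb)) == 3L)
  nb <- dim(xfb)[1]
  if (is.character(keep)) {
    nm <- attr(xfb, "band_names")
    if (is.null(nm)) stop("band names unavailable; use integer indices")
    miss <- setdiff(keep, nm)
    if (length(miss)) stop("unknown band name(s): ",
                           paste(miss, collapse = ", "))
    keep <- match(keep, nm)
  }
  keep <- as.integer(keep)
  if (length(keep) == 0L) stop("'keep' must select at least one band")
  if (any(keep < 1L | keep > nb)) stop("band index out of range 1..", nb)
  out <- xfb
  out[setdiff(seq_len(nb), keep), , ] <- 0
  out
}
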