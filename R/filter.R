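#' Band-pass filter specification
#'
#' Defaults follow the conditioning used for resting-state laminar fMRI:
#' a second-order Butterworth band-pass, 0.01–0.1 Hz, applied forward and
#' backward (zero net phase). "Second-order" is the design order before the
#' forward–backward doubling.
#'
#' @param highpass_hz high-pass corner (Hz).
#' @param lowpass_hz low-pass corner (Hz); must exceed `highpass_hz` and be
#'   below the Nyquist frequency of the series it is applied to.
#' @param order Butterworth design order.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.01, lowpass_hz = 0.1, order = 2L) {
  if (highpass_hz <= 0 || lowpass_hz <= highpass_hz) {
    stop_invalid("invalid-argument: need 0 < highpass_hz < lowpass_hz")
  }
  if (order < 1) stop_invalid("invalid-argument: order must be >= 1")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Concatenate runs of laminar time series
#'
#' Row-binds segments in the given order. All segments must agree on channel
#' labels and sampling interval.
#'
#' @param segments list of [laminar_ts()] objects.
#' @return A single [laminar_ts()] with `T = sum of segment lengths`.
#' @export
concatenate_runs <- function(segments) {
  if (length(segments) == 0) stop_invalid("invalid-argument: no segments")
  first <- segments[[1L]]
  for (s in segments[-1L]) {
    if (!identical(colnames(s$data), colnames(first$data))) {
      stop_invalid("incompatible-input: segments have different channel sets")
    }
    if (!isTRUE(all.equal(s$tr_seconds, first$tr_seconds))) {
      stop_invalid("incompatible-input: segments have different TR")
    }
  }
  laminar_ts(first$participant_id,
             do.call(rbind, lapply(segments, `[[`, "data")),
             first$channels, first$tr_seconds)
}

#' Linear detrend and zero-phase Butterworth band-pass
#'
#' Each channel is linearly detrended, then band-pass filtered forward and
#' backward with a Butterworth design of the given order, for zero net phase
#' (the amplitude response is applied twice). Edge transients are bounded by
#' odd-reflection padding of three filter lengths at both ends before the
#' two passes.
#'
#' @param ts a [laminar_ts()].
#' @param spec a [filter_spec()].
#' @return A [laminar_ts()] of the same shape.
#' @export
detrend_bandpass <- function(ts, spec = filter_spec()) {
  fs <- 1 / ts$tr_seconds
  nyquist <- fs / 2
  if (nyquist <= spec$lowpass_hz) {
    stop_invalid("invalid-argument: Nyquist (%.4g Hz) must exceed lowpass_hz (%.4g Hz)",
                 nyquist, spec$lowpass_hz)
  }
  bf <- signal::butter(spec$order,
                       c(spec$highpass_hz, spec$lowpass_hz) / nyquist,
                       type = "pass")
  npad <- 3L * (length(bf$a) - 1L)
  if (nrow(ts$data) <= 2L * npad) {
    stop_invalid("invalid-argument: need more than %d time points for stable zero-phase filtering",
                 2L * npad)
  }
  x <- detrend_linear(ts$data)
  y <- apply(x, 2L, filtfilt_reflect, b = bf$b, a = bf$a, npad = npad)
  laminar_ts(ts$participant_id, y, ts$channels, ts$tr_seconds)
}

detrend_linear <- function(x) {
  tt <- seq_len(nrow(x))
  design <- cbind(1, tt)
  fit <- lm.fit(design, x)
  as.matrix(fit$residuals)
}

# zero-phase IIR application: odd-reflection pad, filter, reverse, filter,
# reverse, strip the padding
filtfilt_reflect <- function(x, b, a, npad) {
  n <- length(x)
  front <- 2 * x[1L] - x[(npad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(front, x, back)
  yp <- signal::filter(b, a, xp)
  yp <- rev(signal::filter(b, a, rev(yp)))
  as.numeric(yp[(npad + 1L):(npad + n)])
}
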