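# Respiratory-belt signal conditioning: low-pass filtering, quadratic drift
# removal, and amplitude binning into motion states.

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase, no group
#' delay), so the filtered trace stays aligned with the k-space timestamps.
#'
#' @param sig a [resp_signal()].
#' @param cutoff_hz cutoff frequency in Hz (default 3).
#' @return The filtered [resp_signal()] (same length and sampling).
#' @export
lowpass_filter <- function(sig, cutoff_hz = 3.0) {
  stopifnot(inherits(sig, "resp_signal"))
  nyq <- sig$sample_rate / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyq))
  bw <- signal::butter(4, cutoff_hz / nyq, type = "low")
  # reflection padding: the forward-backward pass otherwise leaves start-up
  # transients of the filter's time-constant length at both ends
  v <- sig$values
  n <- length(v)
  npad <- min(n - 1, ceiling(10 * sig$sample_rate / cutoff_hz))
  padded <- c(2 * v[1] - rev(v[2:(npad + 1)]), v,
              2 * v[n] - rev(v[(n - npad):(n - 1)]))
  out <- signal::filtfilt(bw, padded)[(npad + 1):(npad + n)]
  resp_signal(out, sig$sample_rate, sig$t0)
}

#' Remove quadratic baseline drift
#'
#' Belt drift (typically from slow air leaks) is modeled as a quadratic
#' function of time; the least-squares fit is subtracted from the signal.
#'
#' @param sig a [resp_signal()].
#' @return The drift-corrected [resp_signal()].
#' @export
correct_drift <- function(sig) {
  stopifnot(inherits(sig, "resp_signal"))
  v <- sig$values
  if (length(v) < 3) stop("drift correction needs at least 3 samples")
  t <- resp_times(sig)
  t <- t - mean(t)  # centered for conditioning; same fitted values
  fit <- stats::lm.fit(cbind(1, t, t^2), v)
  resp_signal(v - fit$fitted.values, sig$sample_rate, sig$t0)
}

#' Bin a conditioned signal into motion states
#'
#' Equal-width amplitude bins between robust bounds (1st and 99th
#' percentiles); samples outside the bounds are clamped into the end bins.
#' Each state's representative value is the bin midpoint. Labels are 0-based.
#'
#' @param sig a filtered, drift-corrected [resp_signal()].
#' @param n_states number of motion states \code{Ns} (default 12).
#' @return The [resp_signal()] with \code{state_labels} and
#'   \code{state_values} filled; empty states (no samples) are listed in the
#'   \code{"empty_states"} attribute.
#' @export
bin_motion_states <- function(sig, n_states = 12L) {
  stopifnot(inherits(sig, "resp_signal"))
  n_states <- as.integer(n_states)
  if (n_states < 1) stop("n_states must be >= 1")
  v <- sig$values
  if (n_states == 1L) {
    out <- resp_signal(v, sig$sample_rate, sig$t0,
                       state_labels = rep(0L, length(v)),
                       state_values = mean(range(v)))
    attr(out, "empty_states") <- integer(0)
    return(out)
  }
  lo <- stats::quantile(v, 0.01, names = FALSE)
  hi <- stats::quantile(v, 0.99, names = FALSE)
  if (hi - lo <= 1e-12 * max(1, abs(hi)))
    stop("degenerate amplitude range: cannot bin a constant signal into ",
         n_states, " states")
  edges <- seq(lo, hi, length.out = n_states + 1)
  lab <- findInterval(v, edges, rightmost.closed = TRUE)
  lab <- pmin(pmax(lab, 1L), n_states) - 1L  # clamp outliers, 0-based
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  out <- resp_signal(v, sig$sample_rate, sig$t0,
                     state_labels = as.integer(lab), state_values = mids)
  attr(out, "empty_states") <- setdiff(seq_len(n_states) - 1L, unique(lab))
  out
}

#' Motion state of an acquisition timestamp
#'
#' Returns the state label of the signal sample nearest in time; at an exact
#' midpoint between two samples the earlier sample wins.
#'
#' @param sig a binned [resp_signal()] (see [bin_motion_states()]).
#' @param timestamp acquisition time(s) in seconds (vectorized).
#' @return Integer 0-based state label(s).
#' @export
state_for_line <- function(sig, timestamp) {
  if (is.null(sig$state_labels)) stop("signal has no motion-state labels")
  t <- resp_times(sig)
  tol <- 1 / sig$sample_rate
  if (any(timestamp < t[1] - tol | timestamp > t[length(t)] + tol))
    stop("timestamp outside the signal span (beyond one sample period)")
  # nearest sample; on ties round() floors the half-index -> earlier wins
  idx <- floor((timestamp - sig$t0) * sig$sample_rate + 0.5)
  # floor(x + 0.5) rounds half-up in index space, i.e. midpoint goes to the
  # LATER sample; shift exact midpoints down to honor the earlier-wins rule
  frac <- (timestamp - sig$t0) * sig$sample_rate
  mid <- abs(frac - floor(frac) - 0.5) < 1e-12
  idx[mid] <- floor(frac[mid])
  idx <- pmin(pmax(idx, 0), length(t) - 1) + 1
  sig$state_labels[idx]
}

#' Full signal conditioning pipeline
#'
#' Low-pass filter (if the sampling rate permits), quadratic drift removal,
#' then motion-state binning. A degenerate (constant) signal collapses to a
#' single state rather than erroring, which is the correct limit for a
#' motionless acquisition.
#'
#' @param sig a raw [resp_signal()].
#' @param n_states requested number of motion states.
#' @param cutoff_hz low-pass cutoff (Hz); skipped if at/above Nyquist.
#' @return A binned [resp_signal()].
#' @export
condition_resp <- function(sig, n_states = 12L, cutoff_hz = 3.0) {
  if (sig$sample_rate > 2 * cutoff_hz) sig <- lowpass_filter(sig, cutoff_hz)
  sig <- correct_drift(sig)
  rng <- diff(range(sig$values))
  if (n_states > 1 && rng <= 1e-9 * max(1, max(abs(sig$values)))) {
    n_states <- 1L
  }
  bin_motion_states(sig, n_states)
}
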