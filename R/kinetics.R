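# Force-plate processing: zero-phase filtering, threshold touchdown
# detection, and the normalized fore-aft collision impulse.

#' Zero-phase low-pass filter force channels
#'
#' Applies a Butterworth low-pass forward and backward (zero phase). The
#' designed order is applied twice, so the default 4th-order design yields
#' an 8th-order effective magnitude response with the squared -3 dB point at
#' the cutoff (gain 0.5 at 270 Hz).
#'
#' @param trace a [force_trace()]
#' @param cutoff cutoff frequency (Hz)
#' @param order filter order of the single-pass design
#' @return the filtered `force_trace`
#' @export
filter_forces <- function(trace, cutoff = 270, order = 4L) {
  nyq <- trace$rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("cutoff %.0f Hz must be below the Nyquist frequency %.0f Hz",
                 cutoff, nyq))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  out <- trace
  for (ch in c("Fx", "Fy", "Fz")) {
    out[[ch]] <- as.numeric(signal::filtfilt(bf, trace[[ch]]))
  }
  out
}

#' Detect touchdown and liftoff on the force plate
#'
#' Touchdown is the first crossing of the vertical force above the unloaded
#' baseline mean plus four baseline standard deviations, sustained for at
#' least `min_dur`; liftoff is the symmetric falling crossing.
#'
#' @param trace a [force_trace()] with a `baseline_idx` interval
#' @param min_dur minimum sustained loading (s)
#' @return data.frame with columns `t_td`, `t_lo`, `threshold`
#' @export
detect_force_touchdown <- function(trace, min_dur = 0.005) {
  if (is.null(trace$baseline_idx) || length(trace$baseline_idx) < 2L) {
    stop("force trace lacks an unloaded baseline interval")
  }
  base <- trace$Fz[trace$baseline_idx]
  thr <- mean(base) + 4 * sd(base)
  above <- trace$Fz > thr
  above[trace$baseline_idx] <- FALSE
  runs <- true_runs(above)
  if (nrow(runs) == 0L) {
    return(data.frame(t_td = numeric(), t_lo = numeric(),
                      threshold = numeric()))
  }
  min_n <- max(2L, ceiling(min_dur * trace$rate))
  runs <- runs[runs[, 2L] - runs[, 1L] + 1L >= min_n, , drop = FALSE]
  data.frame(
    t_td = trace$t[runs[, 1L]],
    t_lo = trace$t[runs[, 2L]],
    threshold = rep(thr, nrow(runs))
  )
}

#' Normalized fore-aft collision impulse
#'
#' For each stance, integrates the fore-aft force (expressed in the
#' direction-of-travel frame, braking negative) cumulatively from touchdown
#' and takes the largest magnitude of the decelerating (negative) excursion
#' as the fore-aft collision impulse, normalized by the aerial-phase forward
#' momentum `mass * vy`.
#'
#' @param trace a [force_trace()]
#' @param events data.frame with `t_td`, `t_lo` (s), one row per stance
#' @param vy aerial-phase forward CoM speed per stance (m/s), recycled
#' @param mass body mass (kg)
#' @param direction direction of travel per stance (+1/-1 along the y
#'   axis), recycled; the fore-aft channel is rotated into this frame
#' @param vy_fallback used where `vy` is not finite (e.g. no flight phase
#'   found); such steps are flagged
#' @return data.frame of class `impulse_records`: one row per stance with
#'   `Jy_star` (N s), `momentum` (N s), `normalized_impulse`, and a
#'   `fallback_vy` flag
#' @export
fore_aft_impulse <- function(trace, events, vy, mass, direction = 1,
                             vy_fallback = NULL) {
  n <- nrow(events)
  vy <- rep_len(vy, n)
  direction <- rep_len(direction, n)
  fallback <- !is.finite(vy)
  if (any(fallback)) {
    if (is.null(vy_fallback)) {
      stop("non-finite aerial speed and no fallback supplied")
    }
    vy[fallback] <- rep_len(vy_fallback, n)[fallback]
  }
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- which(trace$t >= events$t_td[k] & trace$t <= events$t_lo[k])
    if (length(sel) < 3L) {
      rows[[k]] <- data.frame(step = k, Jy_star = NA_real_,
                              momentum = NA_real_,
                              normalized_impulse = NA_real_,
                              fallback_vy = fallback[k])
      next
    }
    fy <- direction[k] * trace$Fy[sel]
    cumj <- as.numeric(pracma::cumtrapz(trace$t[sel], fy))
    jy <- max(0, -min(cumj))
    mv <- mass * vy[k]
    rows[[k]] <- data.frame(step = k, Jy_star = jy, momentum = mv,
                            normalized_impulse = jy / mv,
                            fallback_vy = fallback[k])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("impulse_records", "data.frame")
  out
}
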