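#' Instantaneous pH from a free proton count
#'
#' `pH = -log10(N_H / (N_A V))`.  A count of zero maps to `Inf`, a typed
#' sentinel that downstream summary statistics mask explicitly.
#'
#' @param N_H free proton count (>= 0), vectorized.
#' @param volume vesicle volume, L.
#' @param constants a [physical_constants()] object.
#' @return pH value(s).
#' @export
#' @examples
#' ph_instant(1, make_geometry(58)$volume)  # ~5.7
#' ph_instant(2, make_geometry(58)$volume)  # ~5.4
ph_instant <- function(N_H, volume, constants = physical_constants()) {
  if (any(N_H < 0)) stop("N_H must be >= 0")
  out <- rep(Inf, length(N_H))
  pos <- N_H > 0
  out[pos] <- -log10(N_H[pos] / (constants$avogadro * volume))
  out
}

#' Expected free proton count at a given pH
#'
#' `N_A * V * 10^(-pH)`; the exact inverse of [ph_instant()].
#'
#' @param pH pH value(s), finite.
#' @param volume vesicle volume, L.
#' @param constants a [physical_constants()] object.
#' @return Real-valued expected count(s).
#' @export
#' @examples
#' expected_protons(5.5, make_geometry(20)$volume)  # ~0.06
#' expected_protons(5.0, make_geometry(50)$volume)  # ~3
expected_protons <- function(pH, volume, constants = physical_constants()) {
  constants$avogadro * volume * 10^(-pH)
}

#' Time-averaged pH of a trajectory
#'
#' Averages the free proton count over contiguous windows tiling the
#' trajectory, then converts the window-mean concentration to pH.  This is
#' the averaging a camera frame performs, and it removes the discrete pH
#' staircase of small vesicles: a window alternating between 0 and 1
#' protons reports the pH of half a proton.
#'
#' @param traj a `star_trajectory`.
#' @param window window length, s (must be at least the sampling interval).
#' @return Data frame with columns `time` (window midpoint), `mean_NH` and
#'   `pH` (`Inf` for all-zero windows).
#' @export
ph_time_avg <- function(traj, window = 0.5) {
  dt <- traj$params$sample_dt
  k <- round(window / dt)
  if (k < 1 || window < dt)
    stop("window must be at least the sampling interval")
  n <- length(traj$times)
  nw <- n %/% k
  idx <- rep(seq_len(nw), each = k)
  nh <- traj$counts[seq_len(nw * k), "N_H"]
  tm <- traj$times[seq_len(nw * k)]
  mean_nh <- as.numeric(tapply(nh, idx, mean))
  data.frame(time = as.numeric(tapply(tm, idx, mean)),
             mean_NH = mean_nh,
             pH = ph_instant(mean_nh, traj$volume))
}

#' Henderson-Hasselbalch protonated copy number
#'
#' `N_HB = N_T / (1 + 10^(pH - pKa))`; strictly decreasing in pH, equal to
#' `N_T / 2` at `pH = pKa`.
#'
#' @param pH pH value(s).
#' @param pKa buffer pKa.
#' @param N_T total buffer copies (>= 0).
#' @return Real protonated copy number(s).
#' @export
hh_protonated <- function(pH, pKa, N_T) {
  if (any(N_T < 0)) stop("N_T must be >= 0")
  N_T / (1 + 10^(pH - pKa))
}

#' Dye photon calibration
#'
#' The linear photon model: a protonated dye molecule emits on average `c`
#' photons per frame on top of a background of `b` photons per frame, each
#' frame integrating `frame_integration` seconds of signal and reported
#' every `frame_period` seconds.  `lambda_per_dye` (photons per protonated
#' dye per collection time) equals `c`.
#'
#' @param c photons per protonated dye per frame (> 0; a non-positive value
#'   is kept but flagged via `ok = FALSE`).
#' @param b background photons per frame (>= 0).
#' @param frame_integration integration window, s.
#' @param frame_period reporting cadence, s.
#' @return Object of class `dye_calibration`.
#' @export
dye_calibration <- function(c, b, frame_integration = 0.5,
                            frame_period = 2.0) {
  ok <- is.finite(c) && c > 0 && is.finite(b) && b >= 0
  if (!ok) warning("non-physical calibration (need c > 0, b >= 0)")
  structure(list(c = c, b = b, lambda_per_dye = c,
                 frame_integration = frame_integration,
                 frame_period = frame_period, ok = ok),
            class = "dye_calibration")
}

#' Calibrate the dye photon model from two anchor windows
#'
#' Solves the two-point linear system `N_photons = c * N_HB2 + b` at two
#' anchors of known pH (typically the pre-ATP window and the maximally
#' acidified window), with the protonated dye count at each anchor from
#' Henderson-Hasselbalch.
#'
#' @param ph_T1,ph_T2 mean pH in the two anchor windows (must differ).
#' @param mean_photons_T1,mean_photons_T2 mean photon counts there.
#' @param pKa2 dye pKa.
#' @param N_T total dye copies.
#' @param ... passed to [dye_calibration()].
#' @return A [dye_calibration()] object.
#' @export
calibrate_dye <- function(ph_T1, ph_T2, mean_photons_T1, mean_photons_T2,
                          pKa2 = 5.72, N_T, ...) {
  if (isTRUE(all.equal(ph_T1, ph_T2)))
    stop("calibration anchors have equal pH: singular system")
  n1 <- hh_protonated(ph_T1, pKa2, N_T)
  n2 <- hh_protonated(ph_T2, pKa2, N_T)
  cc <- (mean_photons_T1 - mean_photons_T2) / (n1 - n2)
  bb <- mean_photons_T1 - cc * n1
  dye_calibration(cc, bb, ...)
}

#' Simulate the photon readout of the dye
#'
#' For each camera frame, the protonated dye count is averaged over the
#' integration window ending at the frame time, the expected photon count
#' is `c * mean(N_HB2) + b`, and the realized count is drawn Poisson
#' (photon shot noise).  Frames sit on the `frame_period` grid.
#'
#' @param traj a `star_trajectory` sampled at least as finely as the
#'   integration window.
#' @param cal a [dye_calibration()] object.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @param frame_times optional explicit frame times; default the
#'   `frame_period` grid.
#' @return Object of class `photon_trace`: `frame_times`, integer `counts`
#'   and the expected `mean_counts`.
#' @export
emit_photons <- function(traj, cal, seed = NULL, frame_times = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- traj$params$sample_dt
  if (cal$frame_integration < dt)
    stop("frame integration window is shorter than the sampling interval")
  tmax <- max(traj$times)
  if (is.null(frame_times))
    frame_times <- seq(cal$frame_period, tmax, by = cal$frame_period)
  k <- round(cal$frame_integration / dt)
  nhb2 <- traj$counts[, "N_HB2"]
  mean_nhb2 <- vapply(frame_times, function(tf) {
    i1 <- which.min(abs(traj$times - tf))
    mean(nhb2[max(1L, i1 - k + 1L):i1])
  }, numeric(1))
  mu <- cal$c * mean_nhb2 + cal$b
  structure(list(frame_times = frame_times, counts = rpois(length(mu), mu),
                 mean_counts = mu),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("photon_trace: %d frames, mean %.1f photons/frame\n",
              length(x$counts), mean(x$counts)))
  invisible(x)
}

#' pH inferred from photon counts
#'
#' Inverts the linear photon model, `N_HB2 = (N_photons - b) / c`, then the
#' Henderson-Hasselbalch relation,
#' `pH = pKa2 + log10((N_T - N_HB2) / N_HB2)`.  Estimated dye counts are
#' clipped to `(eps, N_T - eps)` to avoid the log singularities; clipped
#' frames carry a quality flag rather than being dropped.
#'
#' @param photons a [emit_photons()] object, or a numeric vector of counts.
#' @param cal a [dye_calibration()] object.
#' @param pKa2 dye pKa.
#' @param N_T total dye copies.
#' @param eps clipping margin in dye molecules.
#' @return Data frame with `frame_time_s`, `photons`, `pH_hnu`,
#'   `clipped_flag`.
#' @export
ph_from_photons <- function(photons, cal, pKa2 = 5.72, N_T, eps = 0.5) {
  counts <- if (inherits(photons, "photon_trace")) photons$counts
            else as.numeric(photons)
  ft <- if (inherits(photons, "photon_trace")) photons$frame_times
        else seq_along(counts)
  nhat <- (counts - cal$b) / cal$c
  clipped <- nhat < eps | nhat > N_T - eps
  nhat <- pmin(pmax(nhat, eps), N_T - eps)
  data.frame(frame_time_s = ft, photons = counts,
             pH_hnu = pKa2 + log10((N_T - nhat) / nhat),
             clipped_flag = clipped)
}
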