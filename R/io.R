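#' Experimental single-vesicle pH trace
#'
#' A measured (or synthetic) pH time series with the metadata the fitting
#' machinery needs: vesicle radius and the trace segmentation into
#' before/during/after pumping.
#'
#' @param times sample times, s (strictly increasing).
#' @param pH pH values (may contain `NA`; `Inf` marks protonless frames).
#' @param radius vesicle radius, nm.
#' @param t_ATP time of ATP addition (pumping starts), s.
#' @param t_pump_stop time the pump permanently stops, s.
#' @param t_valinomycin K+ clamp onset, s (defaults to the first sample:
#'   clamp active throughout the fitted region).
#' @param pH_out bath pH; default the median pH before `t_ATP`.
#' @return Object of class `star_trace`.
#' @export
star_trace <- function(times, pH, radius, t_ATP, t_pump_stop,
                       t_valinomycin = times[1], pH_out = NULL) {
  if (length(times) != length(pH)) stop("times and pH lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (radius <= 0) stop("radius must be positive")
  if (is.finite(t_ATP) && is.finite(t_pump_stop)) {
    if (!(t_ATP < t_pump_stop && t_pump_stop <= max(times)))
      stop("need t_ATP < t_pump_stop <= max(times)")
  }
  if (is.null(pH_out)) {
    pre <- pH[times < t_ATP & is.finite(pH)]
    pH_out <- if (length(pre)) median(pre) else NA_real_
  }
  structure(list(times = times, pH = pH, radius = radius, t_ATP = t_ATP,
                 t_pump_stop = t_pump_stop, t_valinomycin = t_valinomycin,
                 pH_out = pH_out),
            class = "star_trace")
}

#' @export
print.star_trace <- function(x, ...) {
  cat(sprintf(
    "star_trace: %d samples over [%g, %g] s, r = %g nm, bath pH %.3g\n",
    length(x$times), min(x$times), max(x$times), x$radius, x$pH_out))
  cat(sprintf("  pumping on [%g, %g) s, K+ clamp from %g s\n",
              x$t_ATP, x$t_pump_stop, x$t_valinomycin))
  invisible(x)
}

# TRUE if every non-empty token parses as a number.
.all_numeric_tokens <- function(tokens) {
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  length(tokens) > 0 &&
    !any(is.na(suppressWarnings(as.numeric(tokens))))
}

#' Read a single-vesicle pH trace from CSV
#'
#' Comma-separated, `.` decimal; the first column is time in seconds and
#' each subsequent column one pH trace.  A single header row is
#' auto-detected.  `NaN`/empty cells are kept as `NA` and masked later by
#' the fitting objective.
#'
#' @param path CSV file.
#' @param column which pH trace (1 = first column after time).
#' @param radius,t_ATP,t_pump_stop,t_valinomycin trace metadata (not part
#'   of the CSV; supplied here or via a sidecar of your own).
#' @return A [star_trace()] object.
#' @export
read_trace_csv <- function(path, column = 1, radius, t_ATP, t_pump_stop,
                           t_valinomycin = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  header <- !.all_numeric_tokens(strsplit(first, ",", fixed = TRUE)[[1]])
  df <- tryCatch(read.csv(path, header = header),
                 error = function(e)
                   stop("malformed CSV ", path, ": ", conditionMessage(e)))
  if (ncol(df) < column + 1)
    stop(sprintf("column %d requested but file has %d pH column(s)",
                 column, ncol(df) - 1L))
  times <- as.numeric(df[[1]])
  if (any(is.na(times)))
    stop("non-numeric time cell at data line ",
         which(is.na(as.numeric(df[[1]])))[1])
  if (any(diff(times) <= 0))
    stop("non-monotonic time at data line ", which(diff(times) <= 0)[1] + 1L)
  pH <- suppressWarnings(as.numeric(df[[column + 1]]))
  star_trace(times, pH, radius = radius, t_ATP = t_ATP,
             t_pump_stop = t_pump_stop,
             t_valinomycin = if (is.null(t_valinomycin)) times[1]
                             else t_valinomycin)
}

#' Write and read trajectory CSV files
#'
#' Columns `time_s, N_H, N_K, N_HB1, N_HB2, active_pumps, dpsi_mV`; counts
#' are written exactly, the membrane potential to full precision.  A
#' sidecar JSON (same path with extension `.json`) records the full
#' parameter document, the seed and the engine, which is sufficient to
#' regenerate the trajectory bit-identically.
#'
#' @param traj a `star_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the provenance sidecar?
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` a `star_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path, sidecar = TRUE) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (sidecar) {
    doc <- params_to_doc(traj$params)
    doc$seed <- traj$seed
    doc$engine <- traj$engine
    jsonlite::write_json(doc, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  if (!file.exists(side))
    stop("missing sidecar JSON for ", path)
  doc <- jsonlite::read_json(side, simplifyVector = TRUE)
  engine <- doc$engine %||% "DS"
  seed <- doc$seed %||% NA_integer_
  doc$engine <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  pr <- read_params(tmp)
  geom <- make_geometry(pr$params$radius)
  samples <- cbind(df$time_s, df$N_H, df$N_K, df$N_HB1, df$N_HB2,
                   df$active_pumps, df$dpsi_mV / 1e3)
  new_trajectory(samples, engine, seed, pr$params, geom$volume)
}

#' Generate a synthetic single-transporter recording
#'
#' A drop-in stand-in for an experimental trace with known ground truth:
#' one stochastic run of the full model under the standard protocol (bath
#' pH 6.5, K+ clamp throughout, ATP added near 180 s, pump stop near
#' 506 s), pushed through the dye/photon pipeline with a chosen
#' calibration, and reported as a pH trace on the camera's 2-s cadence.
#'
#' @param radius vesicle radius, nm.
#' @param I_P,P_H,P_AHA2 ground-truth pump rate (H+/s) and permeabilities
#'   (cm/s).
#' @param pH_out bath pH.
#' @param t_ATP,t_pump_stop,t_final protocol times, s.
#' @param cal a [dye_calibration()]; defaults to a bright lipid dye (40
#'   photons per protonated dye per frame over 100 background photons).
#' @param observable `"photons"` for the full dye/photon readout, or
#'   `"counts"` for an idealized reporter: the 0.5-s time-averaged free
#'   proton count converted to pH.  The photon readout inherits the slow
#'   simulated dye kinetics, so its pH trace lags the true lumenal pH by a
#'   few seconds during transitions; the count reporter has no such lag and
#'   is the right ground truth for proton-count and continuum fits.
#' @param seed integer seed; the trace is reproduced bit-identically from
#'   `(parameters, seed)`.
#' @param base extra [star_params()] overrides.
#' @return Object of class `synthetic_star`: the `star_trace`, the photon
#'   trace (`NULL` for the count reporter), the underlying DS trajectory,
#'   the truth vector and the calibration.
#' @export
generate_synthetic_star <- function(radius = 100, I_P = 300, P_H = 4.6e-5,
                                    P_AHA2 = 20e-5, pH_out = 6.5,
                                    t_ATP = 180, t_pump_stop = 506,
                                    t_final = 750,
                                    cal = dye_calibration(40, 100),
                                    observable = c("photons", "counts"),
                                    seed = 1, base = list()) {
  observable <- match.arg(observable)
  p <- do.call(star_params,
               modifyList(list(radius = radius, pH_out = pH_out, I_P = I_P,
                               P_H = P_H, P_AHA2 = P_AHA2, n_pumps = 1,
                               pump_mode = "fixed", t_on = t_ATP,
                               t_off = t_pump_stop, t_final = t_final,
                               t_valinomycin = 0), base))
  traj <- simulate_ds(p, seed = seed)
  nt <- round(dye_copy_number(make_geometry(radius),
                              dye_layout(p$A_L, p$phi, p$pKa2))$expected)
  if (observable == "photons") {
    photons <- emit_photons(traj, cal)
    est <- ph_from_photons(photons, cal, pKa2 = p$pKa2, N_T = nt)
    frame_times <- est$frame_time_s
    ph <- est$pH_hnu
  } else {
    photons <- NULL
    frame_times <- seq(cal$frame_period, t_final, by = cal$frame_period)
    nh <- windowed_counts(traj, frame_times, window = cal$frame_integration)
    ph <- ph_instant(nh, traj$volume)
  }
  trace <- star_trace(frame_times, ph, radius = radius,
                      t_ATP = t_ATP, t_pump_stop = t_pump_stop,
                      t_valinomycin = 0, pH_out = pH_out)
  structure(list(trace = trace, photons = photons, trajectory = traj,
                 truth = c(I_P = I_P, P_H = P_H, P_AHA2 = P_AHA2),
                 cal = cal, N_T = nt, params = p, seed = seed),
            class = "synthetic_star")
}

#' @export
print.synthetic_star <- function(x, ...) {
  cat(sprintf(
    "synthetic_star: r = %g nm, truth I_P = %g H+/s, P_H = %g, P_AHA2 = %g cm/s (seed %d)\n",
    x$trace$radius, x$truth[["I_P"]], x$truth[["P_H"]], x$truth[["P_AHA2"]],
    x$seed))
  print(x$trace)
  invisible(x)
}
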