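#' Draw a pump on/off timeline
#'
#' In fixed mode every pump is active on `[t_on, t_off)`.  In stochastic
#' mode each pump is an independent alternating renewal process with
#' exponential dwell times; its initial state is active with the stationary
#' probability `dwell_on / (dwell_on + dwell_off)` unless `start_active`
#' forces all pumps on or off.  Uses the current RNG stream unless `seed`
#' is given.
#'
#' @param params a [star_params()] object.
#' @param t_final horizon, s (default `params$t_final`).
#' @param seed optional integer seed.
#' @return Object of class `pump_timeline`: per-pump ordered switching
#'   times with initial activity flags.
#' @export
draw_pump_timeline <- function(params, t_final = params$t_final,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_pumps
  if (params$pump_mode == "fixed") {
    initial <- rep(params$t_on <= 0, n)
    sw <- c(params$t_on, params$t_off)
    sw <- sw[sw > 0 & sw <= t_final]
    per_pump <- rep(list(sw), n)
  } else {
    p_on <- params$dwell_on / (params$dwell_on + params$dwell_off)
    initial <- if (is.null(params$start_active)) runif(n) < p_on
               else rep(isTRUE(params$start_active), n)
    per_pump <- vector("list", n)
    for (i in seq_len(n)) {
      t <- 0
      active <- initial[i]
      sw <- numeric(0)
      repeat {
        t <- t + rexp(1, 1 / if (active) params$dwell_on else params$dwell_off)
        if (t > t_final) break
        sw <- c(sw, t)
        active <- !active
      }
      per_pump[[i]] <- sw
    }
  }
  structure(list(per_pump = per_pump, initial = initial, t_final = t_final),
            class = "pump_timeline")
}

#' Active-pump count as a step function
#'
#' @param timeline a [draw_pump_timeline()] object.
#' @return Data frame with columns `time` and `n_active`; the first row is
#'   at time 0.
#' @export
active_count_steps <- function(timeline) {
  n0 <- sum(timeline$initial)
  deltas <- do.call(rbind, lapply(seq_along(timeline$per_pump), function(i) {
    sw <- timeline$per_pump[[i]]
    if (!length(sw)) return(NULL)
    sign0 <- if (timeline$initial[i]) -1 else 1
    data.frame(time = sw, delta = sign0 * (-1)^(seq_along(sw) - 1))
  }))
  if (is.null(deltas))
    return(data.frame(time = 0, n_active = n0))
  deltas <- deltas[order(deltas$time), , drop = FALSE]
  agg <- tapply(deltas$delta, deltas$time, sum)
  data.frame(time = c(0, as.numeric(names(agg))),
             n_active = cumsum(c(n0, as.numeric(agg))))
}

# Piecewise-constant external-condition table shared by both engines:
# columns t_start, t_end, kH0, kK0, n_active.
build_segments <- function(bs, timeline) {
  p <- bs$params
  steps <- active_count_steps(timeline)
  t_stop <- if (p$pump_mode == "fixed") p$t_off else Inf
  breaks <- sort(unique(c(0, p$t_valinomycin, t_stop, steps$time,
                          p$t_final)))
  breaks <- breaks[breaks >= 0 & breaks <= p$t_final]
  if (breaks[length(breaks)] < p$t_final) breaks <- c(breaks, p$t_final)
  starts <- breaks[-length(breaks)]
  ends <- breaks[-1]
  nact <- vapply(starts, function(t)
    steps$n_active[max(which(steps$time <= t))], numeric(1))
  kH0 <- bs$k_lipid0 + ifelse(starts >= t_stop, bs$k_AHA2_0, 0)
  kK0 <- ifelse(starts >= p$t_valinomycin, bs$k_K0, 0)
  cbind(t_start = starts, t_end = ends, kH0 = kH0, kK0 = kK0,
        n_active = nact)
}

new_trajectory <- function(samples, engine, seed, params, volume,
                           n_events = NA_real_) {
  counts <- samples[, 2:5, drop = FALSE]
  colnames(counts) <- names(lumen_state())
  structure(list(times = samples[, 1], counts = counts,
                 active_pumps = samples[, 6], dpsi = samples[, 7],
                 engine = engine, seed = seed, params = params,
                 volume = volume, n_events = n_events),
            class = "star_trajectory")
}

#' @export
print.star_trajectory <- function(x, ...) {
  cat(sprintf("star_trajectory [%s]: %d samples over %g s (r = %g nm%s)\n",
              x$engine, length(x$times), max(x$times), x$params$radius,
              if (is.na(x$n_events)) ""
              else sprintf(", %.3g events", x$n_events)))
  invisible(x)
}

#' @export
as.data.frame.star_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$counts, active_pumps = x$active_pumps,
             dpsi_mV = x$dpsi * 1e3)
}

#' Exact stochastic simulation of vesicle acidification
#'
#' Simulates the discrete jump process of the full reaction network with a
#' direct-method Gillespie algorithm in which every propensity is refreshed
#' after every firing (each charge-moving event changes the membrane
#' potential).  Pump on/off switches, valinomycin addition and the
#' post-pump-stop leak are applied as deterministic interrupts; the
#' exponential clock is memoryless, so the sampled path is statistically
#' exact.  The state is recorded left-continuously on the uniform sample
#' grid.
#'
#' The pump timeline is drawn first from the seeded stream, then the
#' chemistry consumes the remainder, so a run is reproduced bit-identically
#' from `(params, seed)`.
#'
#' @param params a [star_params()] object.
#' @param seed integer seed.
#' @param timeline optional pre-drawn [draw_pump_timeline()] object.
#' @return A `star_trajectory` with integer copy numbers.
#' @export
#' @examples
#' p <- star_params(radius = 58, I_P = 117, t_final = 50, t_on = 10,
#'                  t_off = 40)
#' traj <- simulate_ds(p, seed = 1)
#' traj
simulate_ds <- function(params, seed = 1L, timeline = NULL) {
  set.seed(seed)
  if (is.null(timeline)) timeline <- draw_pump_timeline(params)
  bs <- build_system(params, "DS")
  segs <- build_segments(bs, timeline)
  sample_times <- seq(0, params$t_final, by = params$sample_dt)
  res <- ssa_run_cpp(as.numeric(bs$state0), bs$sys, segs, sample_times)
  new_trajectory(res$samples, "DS", seed, params, bs$geom$volume,
                 res$n_events)
}

#' Deterministic (continuum) simulation of vesicle acidification
#'
#' Integrates the continuum rate equations of the same network with a
#' stiff-capable solver (`deSolve::lsoda`), piecewise across the pump
#' on/off, valinomycin and pump-stop discontinuities.  State variables are
#' real-valued copy numbers; the membrane potential is evaluated
#' algebraically from the state at every step.
#'
#' @param params a [star_params()] object.
#' @param timeline optional pump timeline; defaults to the fixed schedule
#'   (stochastic mode requires an explicit timeline).
#' @param times output times; default the uniform sample grid.
#' @param rtol,atol integrator tolerances.
#' @return A `star_trajectory` with real-valued copy numbers.
#' @export
simulate_ode <- function(params, timeline = NULL, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  if (is.null(timeline)) {
    if (params$pump_mode != "fixed")
      stop("stochastic pump mode requires an explicit timeline")
    timeline <- draw_pump_timeline(params)
  }
  bs <- build_system(params, "ODE")
  segs <- build_segments(bs, timeline)
  if (is.null(times))
    times <- seq(0, params$t_final, by = params$sample_dt)
  times <- sort(unique(times))

  base_parms <- unlist(bs$sys[c("q0", "dpsi_q", "beta", "Hin_pref",
                                "Kin_pref", "invV", "konf1", "koff1", "NT1",
                                "konf2", "koff2", "NT2", "IP")])
  rhs <- function(t, y, parms) list(ode_rhs_cpp(t, y, parms))

  y <- as.numeric(bs$state0)
  out <- matrix(NA_real_, length(times), 7)
  if (times[1] == segs[1, "t_start"]) {
    out[1, ] <- c(times[1], y, segs[1, "n_active"],
                  bs$sys$dpsi_q * (sum(y) - bs$sys$q0))
    filled <- 1L
  } else filled <- 0L

  for (i in seq_len(nrow(segs))) {
    t0 <- segs[i, "t_start"]; t1 <- segs[i, "t_end"]
    want <- which(times > t0 & times <= t1)
    seg_times <- unique(c(t0, times[want], t1))
    if (length(seg_times) < 2) seg_times <- c(t0, t1)
    parms <- c(base_parms, segs[i, c("kH0", "kK0", "n_active")])
    sol <- deSolve::lsoda(y, seg_times, rhs, parms, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE integration failed in segment [%g, %g] s", t0, t1))
    y <- as.numeric(sol[nrow(sol), 2:5])
    if (length(want)) {
      rows <- sol[match(times[want], sol[, 1]), , drop = FALSE]
      q <- rowSums(rows[, 2:5, drop = FALSE]) - bs$sys$q0
      out[want, ] <- cbind(rows[, 1], rows[, 2:5, drop = FALSE],
                           segs[i, "n_active"], bs$sys$dpsi_q * q)
    }
  }
  new_trajectory(out, "ODE", NA_integer_, params, bs$geom$volume)
}

#' Pointwise ensemble mean of trajectories
#'
#' Averages copy numbers (and membrane potential and active pump count)
#' across trajectories sharing a common sample grid.  Downstream pH is the
#' pH of the mean count, not the mean of per-trajectory pH.
#'
#' @param trajectories list of `star_trajectory` objects.
#' @return A `star_trajectory` with real-valued mean counts.
#' @export
ensemble_mean <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  t0 <- trajectories[[1]]$times
  for (tr in trajectories)
    if (!isTRUE(all.equal(tr$times, t0)))
      stop("trajectories are not on a common sample grid")
  n <- length(trajectories)
  acc <- trajectories[[1]]
  counts <- Reduce(`+`, lapply(trajectories, `[[`, "counts")) / n
  dpsi <- Reduce(`+`, lapply(trajectories, `[[`, "dpsi")) / n
  act <- Reduce(`+`, lapply(trajectories, `[[`, "active_pumps")) / n
  structure(list(times = t0, counts = counts, active_pumps = act,
                 dpsi = dpsi, engine = paste0(acc$engine, "-mean"),
                 seed = NA_integer_, params = acc$params,
                 volume = acc$volume, n_events = NA_real_),
            class = "star_trajectory")
}

#' Instantaneous pH series of a trajectory
#'
#' @param traj a `star_trajectory`.
#' @return Numeric vector of pH values (`Inf` where the free proton count
#'   is zero).
#' @export
trajectory_ph <- function(traj) {
  ph_instant(traj$counts[, "N_H"], traj$volume)
}
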