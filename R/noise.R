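#' Fano factor of a count series
#'
#' Variance divided by the mean; 1 for a Poisson sample, 0 for a constant
#' series, `NaN` sentinel for a zero-mean series.
#'
#' @param count_series non-empty numeric vector.
#' @return Variance-to-mean ratio.
#' @export
fano_factor <- function(count_series) {
  if (!length(count_series)) stop("empty count series")
  m <- mean(count_series)
  if (m == 0) return(NaN)
  var(count_series) / m
}

#' Chi-square Poisson goodness of fit
#'
#' Bins an integer count sample, estimates the Poisson mean from the data,
#' merges adjacent bins until every expected count is at least 5 and
#' applies the chi-square test with `nbins - 2` degrees of freedom.
#'
#' @param counts integer-valued sample.
#' @param min_expected minimum expected count per merged bin.
#' @return List with `lambda_hat`, `statistic`, `df`, `p_value` (`NA` when
#'   fewer than three merged bins remain).
#' @export
poisson_gof <- function(counts, min_expected = 5) {
  lambda <- mean(counts)
  n <- length(counts)
  kmax <- max(counts, qpois(1 - 1e-9, lambda))
  probs <- dpois(0:(kmax - 1), lambda)
  probs <- c(probs, 1 - sum(probs))          # upper tail lumped
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)

  # greedy left-to-right merge to expected >= min_expected; fold any
  # deficient final bin into its neighbour
  exp_merged <- obs_merged <- numeric(0)
  acc_e <- acc_o <- 0
  for (i in seq_along(probs)) {
    acc_e <- acc_e + n * probs[i]
    acc_o <- acc_o + obs[i]
    if (acc_e >= min_expected) {
      exp_merged <- c(exp_merged, acc_e)
      obs_merged <- c(obs_merged, acc_o)
      acc_e <- acc_o <- 0
    }
  }
  if (acc_e > 0 && length(exp_merged)) {
    exp_merged[length(exp_merged)] <- exp_merged[length(exp_merged)] + acc_e
    obs_merged[length(obs_merged)] <- obs_merged[length(obs_merged)] + acc_o
  }
  k <- length(exp_merged)
  if (k < 3)
    return(list(lambda_hat = lambda, statistic = NA_real_, df = NA_real_,
                p_value = NA_real_))
  stat <- sum((obs_merged - exp_merged)^2 / exp_merged)
  df <- k - 2
  list(lambda_hat = lambda, statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Fluctuation statistics of a trajectory window
#'
#' Sample mean and standard deviation of the free proton count, standard
#' deviation of the finite instantaneous pH values (infinite-pH samples
#' from protonless snapshots are masked and counted), the Fano factor of
#' the count, and a chi-square Poisson goodness-of-fit test.  The caller is
#' responsible for choosing a window in which the system is stationary.
#'
#' @param traj a `star_trajectory`.
#' @param window `c(t_start, t_end)` in s; default the final half of the
#'   run.
#' @param thin keep every `thin`-th sample.
#' @return Object of class `noise_summary`.
#' @export
window_stats <- function(traj, window = NULL, thin = 1L) {
  tmax <- max(traj$times)
  if (is.null(window)) window <- c(tmax / 2, tmax)
  sel <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(sel)) stop("empty window")
  sel <- sel[seq(1L, length(sel), by = thin)]
  nh <- traj$counts[sel, "N_H"]
  ph <- ph_instant(nh, traj$volume)
  finite <- is.finite(ph)
  gof <- poisson_gof(nh)
  structure(list(window = window, n_samples = length(sel),
                 mean_NH = mean(nh), sigma_NH = sd(nh),
                 sigma_pH = if (any(finite)) sd(ph[finite]) else NA_real_,
                 mean_pH = if (any(finite)) mean(ph[finite]) else NA_real_,
                 fano = fano_factor(nh),
                 poisson_lambda_hat = gof$lambda_hat,
                 poisson_gof_p = gof$p_value,
                 infinite_pH_mask_count = sum(!finite)),
            class = "noise_summary")
}

#' @export
print.noise_summary <- function(x, ...) {
  cat(sprintf(
    "noise_summary [%g, %g] s: <N_H> = %.3g, sigma(N_H) = %.3g, sigma(pH) = %.3g\n",
    x$window[1], x$window[2], x$mean_NH, x$sigma_NH, x$sigma_pH))
  cat(sprintf("  Fano = %.3g, Poisson GOF p = %.3g (%d samples, %d masked)\n",
              x$fano, x$poisson_gof_p, x$n_samples,
              x$infinite_pH_mask_count))
  invisible(x)
}

#' Closed-form pH noise from Poisson proton statistics
#'
#' Propagating Poisson count noise through the log transform gives
#' `sigma(pH) = sigma(N_H) / (ln 10 * N_H) = 1 / (ln 10 * sqrt(N_H))`,
#' which scales as `r^(-3/2)` at fixed pH and as `10^(+pH/2)` at fixed
#' radius.
#'
#' @param mean_NH mean free proton count (> 0).
#' @return Predicted standard deviation of pH.
#' @export
sigma_ph_closed_form <- function(mean_NH) {
  if (any(mean_NH <= 0)) stop("mean_NH must be positive")
  1 / (log(10) * sqrt(mean_NH))
}

#' Closed-form reporter pH noise
#'
#' Standard deviation of dye-reported pH from binomial protonation noise of
#' a fixed dye pool plus Poisson photon shot noise:
#' `sigma = sqrt((f(1-f) + f/lambda) / N_dye) / (ln 10 * f(1-f))`,
#' where `f` is the protonated dye fraction, `lambda` the mean photons per
#' protonated dye per collection time and `N_dye` the pool size.  In the
#' bright-dye limit (`lambda -> Inf`) the pure binomial term remains.
#'
#' @param f protonated dye fraction, strictly inside (0, 1).
#' @param lambda_per_dye photons per protonated dye per collection time.
#' @param N_dye total dye molecules (> 0).
#' @return Predicted standard deviation of the reported pH.
#' @export
sigma_ph_hnu_closed_form <- function(f, lambda_per_dye, N_dye) {
  if (any(f <= 0 | f >= 1)) stop("f must lie strictly inside (0, 1)")
  if (any(N_dye <= 0) || any(lambda_per_dye <= 0))
    stop("N_dye and lambda_per_dye must be positive")
  1 / (log(10) * f * (1 - f)) *
    sqrt((f * (1 - f) + f / lambda_per_dye) / N_dye)
}

#' Empirical reporter pH noise at a clamped pH
#'
#' Monte-Carlo counterpart of [sigma_ph_hnu_closed_form()]: per frame the
#' protonated dye count is drawn binomially at fraction `f` (the stationary
#' law of the dye pool at a fixed lumenal pH), photon counts Poisson with
#' `lambda` photons per protonated dye, and the reported pH is recovered by
#' [ph_from_photons()].  Clipped frames are excluded from the spread.
#'
#' @param f protonated dye fraction.
#' @param lambda_per_dye photons per protonated dye.
#' @param N_dye dye pool size.
#' @param n_frames frames simulated.
#' @param pKa2 dye pKa (affects only the pH offset, not the spread).
#' @return Sample standard deviation of the reported pH.
#' @export
simulate_reporter_noise <- function(f, lambda_per_dye, N_dye,
                                    n_frames = 4000, pKa2 = 5.72) {
  nhb <- rbinom(n_frames, N_dye, f)
  photons <- rpois(n_frames, lambda_per_dye * nhb)
  cal <- dye_calibration(lambda_per_dye, 0)
  est <- ph_from_photons(photons, cal, pKa2 = pKa2, N_T = N_dye)
  sd(est$pH_hnu[!est$clipped_flag])
}
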