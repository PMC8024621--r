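#' Simulation configuration for the delayed Kuramoto model
#'
#' Bundles every parameter of the stochastic delay-coupled phase-oscillator
#' simulation with the study defaults. The integrator works on a millisecond
#' time base, and the rate-like model parameters follow it: the coupling
#' prefactor is in rad/ms and the noise intensity in rad per square-root
#' millisecond. Natural frequencies are quoted in Hz and converted
#' internally (omega = 2 pi nu / 1000 rad/ms). At the default coupling the
#' weighted network sits above its synchronization transition at low
#' frequencies, the regime in which delays progressively decorrelate pairs
#' as the mean frequency grows.
#'
#' @param mean_freq mean natural frequency nu0 of the oscillators (Hz).
#' @param freq_sd standard deviation of the natural-frequency distribution
#'   (Hz, default 0.1).
#' @param coupling coupling prefactor K/N multiplying the weighted coupling
#'   sum (rad/ms, default 0.25).
#' @param noise_sd white-noise intensity of the phase noise
#'   (rad ms^-1/2, default 0.05).
#' @param t_transient initial transient discarded before recording (s,
#'   default 7).
#' @param t_record length of the recording window (s, default 12).
#' @param record_dt sampling interval of the recorded phases and length of
#'   the Euler-Maruyama noise macro-step (ms, default 1). Must resolve the
#'   fastest oscillation: `record_dt <= 250 / mean_freq`.
#' @param abs_tol,rel_tol absolute and relative local error tolerances of the
#'   adaptive integrator (defaults 1e-8 and 1e-5).
#' @param min_step minimum integrator step (ms, default 0.001).
#' @param n_realizations ensemble size: number of repetitions with fresh
#'   initial phases and natural-frequency draws (default 200).
#' @param seed integer seed from which per-realization seeds are derived.
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(mean_freq = 11, n_realizations = 4, t_record = 1)
#' cfg
#' @export
sim_config <- function(mean_freq, freq_sd = 0.1, coupling = 0.25,
                       noise_sd = 0.05, t_transient = 7, t_record = 12,
                       record_dt = 1, abs_tol = 1e-8, rel_tol = 1e-5,
                       min_step = 0.001, n_realizations = 200, seed = 1) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(mean_freq) || mean_freq <= 0)
    stop("'mean_freq' must be a positive frequency in Hz")
  if (!num1(freq_sd) || freq_sd < 0) stop("'freq_sd' must be >= 0")
  if (!num1(coupling) || coupling < 0) stop("'coupling' must be >= 0")
  if (!num1(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!num1(t_transient) || t_transient <= 0)
    stop("'t_transient' must be positive (s)")
  if (!num1(t_record) || t_record <= 0)
    stop("'t_record' must be positive (s)")
  if (!num1(record_dt) || record_dt <= 0)
    stop("'record_dt' must be positive (ms)")
  if (record_dt > 250 / mean_freq)
    stop("'record_dt' must resolve the oscillation: record_dt <= 250/mean_freq ms")
  if (!num1(min_step) || min_step <= 0 || min_step > record_dt)
    stop("'min_step' must be in (0, record_dt]")
  if (!num1(n_realizations) || n_realizations < 1)
    stop("'n_realizations' must be >= 1")
  structure(
    list(mean_freq = mean_freq, freq_sd = freq_sd, coupling = coupling,
         noise_sd = noise_sd, t_transient = t_transient,
         t_record = t_record, record_dt = record_dt, abs_tol = abs_tol,
         rel_tol = rel_tol, min_step = min_step,
         n_realizations = as.integer(n_realizations), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: nu0 = %g Hz (sd %g), K/N = %g rad/ms, noise %g rad/sqrt(ms)\n",
    x$mean_freq, x$freq_sd, x$coupling, x$noise_sd))
  cat(sprintf("  transient %g s, recording %g s at %g ms, %d realization(s), seed %d\n",
              x$t_transient, x$t_record, x$record_dt, x$n_realizations, x$seed))
  invisible(x)
}

#' Draw natural angular frequencies
#'
#' Samples natural frequencies nu_i from Normal(`mean_freq`, `freq_sd`) in Hz
#' and returns the angular frequencies omega_i = 2 pi nu_i expressed in
#' rad/ms, the unit used by the integrator.
#'
#' @param n number of oscillators.
#' @param mean_freq mean frequency in Hz (> 0).
#' @param freq_sd standard deviation in Hz (default 0.1).
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (as inside ensemble runs).
#' @return Numeric vector of omega_i in rad/ms with attribute `"nu"` holding
#'   the sampled frequencies in Hz.
#' @examples
#' w <- draw_natural_frequencies(5, mean_freq = 10, freq_sd = 0, seed = 1)
#' all.equal(w, rep(2 * pi * 10 / 1000, 5), check.attributes = FALSE)
#' @export
draw_natural_frequencies <- function(n, mean_freq, freq_sd = 0.1, seed = NULL) {
  if (mean_freq <= 0) stop("'mean_freq' must be positive")
  if (freq_sd < 0) stop("'freq_sd' must be non-negative")
  nu <- if (is.null(seed)) stats::rnorm(n, mean_freq, freq_sd)
        else with_seed(seed, stats::rnorm(n, mean_freq, freq_sd))
  structure(2 * pi * nu / 1000, nu = nu)
}

#' Simulate phases of the delayed Kuramoto model
#'
#' Integrates `dtheta_i/dt = omega_i + xi_i(t) + (K/N) sum_j a_ij
#' sin(theta_j(t - tau_ij) - theta_i(t))` for one realization. Initial phases
#' are uniform on \[0, 2 pi); for t < 0 each oscillator is held at its
#' initial phase. The deterministic part is advanced with an adaptive
#' embedded Bogacki-Shampine 3(2) pair between fixed macro-steps of
#' `record_dt`, after each of which a Gaussian increment of standard
#' deviation `noise_sd * sqrt(record_dt)` is added (Euler-Maruyama).
#' Phases are recorded every `record_dt` over the post-transient window and
#' stored wrapped to (-pi, pi].
#'
#' @param x a `connectome`.
#' @param delays a `delay_matrix` conforming to `x`; the largest delay must
#'   be smaller than the transient.
#' @param config a [sim_config()].
#' @param seed integer seed for this realization (defaults to `config$seed`).
#' @return An object of class `"phase_trajectory"`: list with `times` (ms,
#'   uniform grid over the recording window), `phases` (n x T matrix, rad,
#'   wrapped), `omega` (rad/ms), `stats` (accepted/rejected step counts),
#'   `mean_freq`, and `seed`.
#' @seealso [run_ensemble()], [unwrap_phases()], [correlation_index()]
#' @export
simulate_phases <- function(x, delays, config, seed = NULL) {
  stopifnot(inherits(x, "connectome"), inherits(config, "sim_config"))
  delays <- as.matrix(delays)
  if (!identical(dim(delays), dim(x$weights)))
    stop("'delays' must conform to the connectome")
  if (any(delays < 0)) stop("delays must be non-negative")
  if (any(delays > 0 & x$weights == 0))
    stop("delays on non-edges are not allowed")
  max_tau <- max(delays)
  if (max_tau >= config$t_transient * 1000)
    stop("maximum delay (", max_tau, " ms) must be below the transient horizon")
  if (config$record_dt > 250 / config$mean_freq)
    stop("'record_dt' does not resolve oscillations at ", config$mean_freq, " Hz")
  if (is.null(seed)) seed <- config$seed

  n <- x$n
  with_seed(seed, {
    omega <- draw_natural_frequencies(n, config$mean_freq, config$freq_sd)
    theta0 <- stats::runif(n, 0, 2 * pi)
    res <- dde_kuramoto_cpp(
      Wg = config$coupling * x$weights,
      tau = delays,
      omega = as.numeric(omega),
      theta0 = theta0,
      noise_step_sd = config$noise_sd * sqrt(config$record_dt),
      t_end = (config$t_transient + config$t_record) * 1000,
      t_record_start = config$t_transient * 1000,
      record_dt = config$record_dt,
      abs_tol = config$abs_tol,
      rel_tol = config$rel_tol,
      min_step = config$min_step
    )
    ph <- res$phases %% (2 * pi)
    ph[ph > pi] <- ph[ph > pi] - 2 * pi
    structure(
      list(times = res$times, phases = ph, omega = as.numeric(omega),
           stats = list(n_accepted = res$n_accepted,
                        n_rejected = res$n_rejected),
           mean_freq = config$mean_freq, record_dt = config$record_dt,
           seed = seed),
      class = "phase_trajectory"
    )
  })
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf(
    "Phase trajectory: %d oscillators, %d samples over [%g, %g] ms (dt %g ms)\n",
    nrow(x$phases), ncol(x$phases), min(x$times), max(x$times), x$record_dt))
  cat(sprintf("  integrator: %d accepted / %d rejected steps; seed %d\n",
              x$stats$n_accepted, x$stats$n_rejected, x$seed))
  invisible(x)
}

#' @export
plot.phase_trajectory <- function(x, nodes = seq_len(min(5, nrow(x$phases))),
                                  ...) {
  graphics::matplot(x$times / 1000, t(x$phases[nodes, , drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = expression(theta ~ "(rad, wrapped)"), ...)
  invisible(x)
}

#' Unwrap recorded phases
#'
#' Reconstructs continuous phases from the wrapped record by removing the
#' 2 pi jumps between consecutive samples. Valid while the phase advances
#' less than pi per recording step, i.e. for mean frequencies below
#' `500 / record_dt` Hz.
#'
#' @param traj a `phase_trajectory`.
#' @return n x T matrix of unwrapped phases in rad.
#' @export
unwrap_phases <- function(traj) {
  stopifnot(inherits(traj, "phase_trajectory"))
  ph <- traj$phases
  if (ncol(ph) < 2) return(ph)
  d <- ph[, -1, drop = FALSE] - ph[, -ncol(ph), drop = FALSE]
  d <- d - 2 * pi * round(d / (2 * pi))
  t(apply(cbind(ph[, 1], d), 1, cumsum))
}

#' Run an ensemble of realizations
#'
#' Repeats the simulation `config$n_realizations` times, each with fresh
#' uniform initial phases and a fresh draw of the natural frequencies.
#' Per-realization seeds are derived reproducibly from `config$seed`, so the
#' whole ensemble is deterministic.
#'
#' @inheritParams simulate_phases
#' @return A list of `phase_trajectory` objects (class `"phase_ensemble"`).
#' @seealso [ensemble_fc()]
#' @export
run_ensemble <- function(x, delays, config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, config$n_realizations))
  out <- lapply(seeds, function(s) simulate_phases(x, delays, config, seed = s))
  class(out) <- c("phase_ensemble", "list")
  out
}

#' @export
print.phase_ensemble <- function(x, ...) {
  cat(sprintf("Phase ensemble: %d realization(s)\n", length(x)))
  print(x[[1]])
  invisible(x)
}

#' Simulate method for connectomes
#'
#' Convenience wrapper around [run_ensemble()] following the base-R
#' `simulate` idiom: `simulate(con, nsim, seed, delays = ..., config = ...)`.
#'
#' @param object a `connectome`.
#' @param nsim number of realizations (overrides `config$n_realizations`).
#' @param seed integer seed (overrides `config$seed`).
#' @param delays a `delay_matrix`.
#' @param config a [sim_config()].
#' @param ... unused.
#' @return A `phase_ensemble`.
#' @export
simulate.connectome <- function(object, nsim = 1, seed = NULL,
                                delays, config, ...) {
  stopifnot(inherits(config, "sim_config"))
  config$n_realizations <- as.integer(nsim)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run_ensemble(object, delays, config)
}
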