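#' Graph density in percent
#'
#' @param n node count (>= 2).
#' @param m edge count: ordered pairs if `directed`, unordered otherwise.
#' @param directed logical.
#' @return Density as a percentage: `100 m / (n (n - 1))` for directed
#'   graphs, `100 m / (n (n - 1) / 2)` otherwise.
#' @examples
#' graph_density(29, 536, directed = TRUE) # ~66%
#' @export
graph_density <- function(n, m, directed = FALSE) {
  if (n < 2) stop("'n' must be at least 2")
  mx <- if (directed) n * (n - 1) else n * (n - 1) / 2
  if (m < 0 || m > mx)
    stop("'m' must lie in [0, ", mx, "]")
  100 * m / mx
}

#' Structure-function similarity distance
#'
#' Distance between the functional (correlation-index) and structural
#' (weight) matrices: the Euclidean norm of the element-wise difference over
#' the selected upper-triangle pairs, divided by the number of pairs. Zero
#' means the matrices agree exactly on the mask; a larger value means less
#' similarity. By default only directly connected pairs enter, since the
#' comparison of correlations with connection strengths is meaningful where a
#' structural link exists; `pairs = "all"` is available for sensitivity
#' checks.
#'
#' @param fc an `fc_matrix`.
#' @param x a `connectome` of matching dimension. For directed connectomes
#'   the symmetrized weights `(W + t(W)) / 2` are compared with the (always
#'   symmetric) correlation index.
#' @param pairs `"edges"` (default) or `"all"`.
#' @return Non-negative scalar.
#' @examples
#' con <- pair_connectome(c(0.5, 0.5), 30)
#' sig <- con$weights; diag(sig) <- 1
#' fc_similarity(fc_matrix(sig), con) # identical on the edge mask: 0
#' @export
fc_similarity <- function(fc, x, pairs = c("edges", "all")) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(x, "connectome"))
  pairs <- match.arg(pairs)
  if (nrow(fc) != x$n) stop("dimension mismatch between fc and connectome")
  w <- x$weights
  if (x$directed) w <- (w + t(w)) / 2
  ut <- upper.tri(w)
  mask <- if (pairs == "edges") ut & w > 0 else ut
  np <- sum(mask)
  if (np == 0) stop("empty pair mask")
  sqrt(sum((unclass(fc)[mask] - w[mask])^2)) / np
}

#' Bin mean correlation by connection weight or distance
#'
#' Groups directly connected node pairs into bins of their structural weight
#' (default width 0.05) or Euclidean distance (default width 16 mm) and
#' reports the mean correlation index per bin with a 95 percent t-interval
#' across the contributing pairs. Bins are half-open,
#' `[centre - width/2, centre + width/2)`, and empty bins are omitted.
#'
#' @param fc an `fc_matrix`.
#' @param x a `connectome` of matching dimension.
#' @param by `"weight"` or `"distance"`.
#' @param width bin width; defaults to 0.05 for weights and 16 mm for
#'   distances.
#' @param centers optional bin centres; by default a regular grid of step
#'   `width` covering the observed range.
#' @param level confidence level of the interval (default 0.95).
#' @return A data frame of class `"binned_summary"` with columns
#'   `bin_center`, `mean_sigma`, `ci_low`, `ci_high`, `n_pairs`, `mean_freq`.
#' @export
bin_correlation <- function(fc, x, by = c("weight", "distance"),
                            width = NULL, centers = NULL, level = 0.95) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(x, "connectome"))
  by <- match.arg(by)
  if (is.null(width)) width <- if (by == "weight") 0.05 else 16
  if (width <= 0) stop("'width' must be positive")
  if (nrow(fc) != x$n) stop("dimension mismatch between fc and connectome")
  w <- x$weights
  if (x$directed) w <- pmax(w, t(w))
  ut <- upper.tri(w)
  con <- ut & w > 0
  if (!any(con)) stop("no connected pairs")
  val <- if (by == "weight") w[con] else x$distances[con]
  sig <- unclass(fc)[con]
  if (is.null(centers)) {
    k0 <- floor(min(val) / width)
    k1 <- ceiling(max(val) / width)
    centers <- (k0:k1) * width + width / 2
  }
  rows <- lapply(centers, function(ctr) {
    inb <- val >= ctr - width / 2 & val < ctr + width / 2
    np <- sum(inb)
    if (np == 0) return(NULL)
    mu <- mean(sig[inb])
    if (np > 1) {
      half <- stats::qt(1 - (1 - level) / 2, df = np - 1) *
        stats::sd(sig[inb]) / sqrt(np)
    } else half <- 0
    data.frame(bin_center = ctr, mean_sigma = mu,
               ci_low = mu - half, ci_high = mu + half, n_pairs = np)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all bins are empty")
  out$mean_freq <- attr(fc, "mean_freq") %||% NA_real_
  class(out) <- c("binned_summary", "data.frame")
  attr(out, "by") <- by
  attr(out, "width") <- width
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep the mean natural frequency
#'
#' Runs a full ensemble simulation at each requested mean frequency, computes
#' the ensemble-averaged functional network, and assembles the
#' structure-function similarity curve across frequencies. Seeds for each
#' frequency are derived from `config$seed` so the sweep is deterministic.
#'
#' @param x a `connectome`.
#' @param delays a `delay_matrix`.
#' @param config a [sim_config()]; its `mean_freq` is overridden per
#'   frequency.
#' @param freqs vector of mean frequencies in Hz (e.g. the band
#'   representatives 3, 11, 23, 35, 51).
#' @param pairs mask passed to [fc_similarity()].
#' @return An object of class `"freq_sweep"`: list with `freqs`, `fc` (named
#'   list of `fc_matrix`), and `summary` (data frame with `freq`,
#'   `similarity`, `mean_sigma_connected`, `min_sigma_connected`).
#' @export
frequency_sweep <- function(x, delays, config, freqs = c(3, 11, 23, 35, 51),
                            pairs = "edges") {
  stopifnot(inherits(config, "sim_config"))
  if (!length(freqs) || any(freqs <= 0))
    stop("'freqs' must be positive frequencies in Hz")
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, length(freqs)))
  w <- x$weights
  if (x$directed) w <- pmax(w, t(w))
  con <- upper.tri(w) & w > 0
  fcs <- vector("list", length(freqs))
  sim <- ms <- mn <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    cfg <- config
    cfg$mean_freq <- freqs[k]
    cfg$seed <- seeds[k]
    class(cfg) <- "sim_config"
    ens <- run_ensemble(x, delays, cfg)
    fc <- ensemble_fc(ens)
    fcs[[k]] <- fc
    sim[k] <- fc_similarity(fc, x, pairs = pairs)
    ms[k] <- mean(unclass(fc)[con])
    mn[k] <- min(unclass(fc)[con])
  }
  names(fcs) <- paste0(freqs, "Hz")
  structure(
    list(freqs = freqs, fc = fcs,
         summary = data.frame(freq = freqs, similarity = sim,
                              mean_sigma_connected = ms,
                              min_sigma_connected = mn)),
    class = "freq_sweep"
  )
}

#' @export
print.freq_sweep <- function(x, ...) {
  cat("Frequency sweep over", length(x$freqs), "mean frequencies (Hz)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  amin <- x$summary$freq[which.min(x$summary$similarity)]
  cat(sprintf("  similarity minimum at %g Hz (grid resolution %s)\n",
              amin, paste(signif(diff(sort(unique(x$freqs))), 3)[1])))
  invisible(x)
}

#' @export
plot.freq_sweep <- function(x, what = c("similarity", "mean_sigma"), ...) {
  what <- match.arg(what)
  y <- if (what == "similarity") x$summary$similarity
       else x$summary$mean_sigma_connected
  graphics::plot(x$summary$freq, y, type = "b", pch = 16,
                 xlab = "mean frequency (Hz)",
                 ylab = if (what == "similarity")
                   "structure-function distance" else
                   expression(bar(sigma) ~ "(connected pairs)"), ...)
  invisible(x)
}

#' Correlation-versus-frequency curve for an isolated pair
#'
#' Simulates an isolated two-node system (one coupled pair) across a grid of
#' mean frequencies and records the ensemble-averaged correlation index of
#' the pair. This is the controlled setting in which the delay sets the rate
#' at which sigma oscillates with frequency while the coupling weight sets
#' the amplitude of the oscillation.
#'
#' @param freqs mean frequencies in Hz.
#' @param tau pair transmission delay in ms.
#' @param weight pair coupling weight in (0, 1].
#' @param config a [sim_config()] (its `mean_freq` is overridden). For a
#'   controlled pair experiment matching the analytic oracle use
#'   `freq_sd = 0`.
#' @return Data frame with columns `freq` and `sigma`.
#' @seealso [two_node_locked_state()], [first_zero_crossing()]
#' @export
pair_correlation_curve <- function(freqs, tau, weight = 1, config) {
  con <- pair_connectome(weight, distances = max(tau * 5, 1))
  delays <- uniform_delays(con, tau)
  sw <- frequency_sweep(con, delays, config, freqs = freqs)
  data.frame(freq = freqs,
             sigma = vapply(sw$fc, function(f) unclass(f)[1, 2], numeric(1)))
}

#' First zero crossing of a sampled curve
#'
#' Smallest abscissa at which a sampled curve first crosses from positive to
#' non-positive values, linearly interpolated between grid points. `NA` if
#' the curve never crosses.
#'
#' @param x abscissa grid (increasing).
#' @param y sampled values.
#' @return Scalar crossing location or `NA`.
#' @export
first_zero_crossing <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (y[1] <= 0) return(x[1])
  for (i in seq_len(length(y) - 1)) {
    if (y[i] > 0 && y[i + 1] <= 0) {
      return(x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1]))
    }
  }
  NA_real_
}

#' Analytic phase-locked states of a delay-coupled oscillator pair
#'
#' For two identical phase oscillators coupled symmetrically with strength
#' `K = coupling * weight` (rad/ms) through a transmission delay `tau` (ms),
#' the locked states satisfy the self-consistency condition
#' `Omega = omega -/+ K sin(Omega tau)` for the in-phase / anti-phase branch,
#' where `omega = 2 pi freq / 1000` rad/ms. The in-phase state is stable
#' where `cos(Omega tau) > 0` and the anti-phase state where
#' `cos(Omega tau) < 0`. All self-consistent roots are located by a
#' sign-change scan plus root polishing, and a damped fixed-point iteration
#' from `Omega = omega` supplies the principal root. In the weak-coupling
#' limit (`K tau` small) the stability boundaries sit at
#' `nu = (2k + 1) * 250 / tau` Hz; a finite `K` shifts them by up to
#' `1000 K / (2 pi)` Hz.
#'
#' @param coupling coupling prefactor K/N in rad/ms.
#' @param tau transmission delay in ms (>= 0).
#' @param freq natural frequency nu in Hz (> 0).
#' @param weight connection weight in (0, 1] (default 1).
#' @return An object of class `"locked_state"`: list with `state` (one of
#'   `"in_phase"`, `"anti_phase"`, `"bistable"`, `"drift"`), `roots` (data
#'   frame: `branch`, `Omega` rad/ms, `Omega_tau` rad, `stable`), and the
#'   inputs.
#' @examples
#' two_node_locked_state(0.001, tau = 5, freq = 10)$state  # "in_phase"
#' two_node_locked_state(0.001, tau = 5, freq = 70)$state  # "anti_phase"
#' @export
two_node_locked_state <- function(coupling, tau, freq, weight = 1) {
  if (coupling < 0) stop("'coupling' must be >= 0")
  if (tau < 0) stop("'tau' must be >= 0")
  if (freq <= 0) stop("'freq' must be positive")
  omega <- 2 * pi * freq / 1000   # rad/ms
  taus <- tau                     # ms
  K <- coupling * weight          # rad/ms

  branch_roots <- function(sgn) {
    # F(Omega) = Omega - omega + sgn * K * sin(Omega * taus)
    f <- function(Om) Om - omega + sgn * K * sin(Om * taus)
    lo <- omega - 1.5 * K - 1e-9
    hi <- omega + 1.5 * K + 1e-9
    grid <- seq(lo, hi, length.out = max(64L, ceiling((hi - lo) * taus / pi * 32) + 2L))
    fv <- f(grid)
    roots <- c()
    for (i in seq_len(length(grid) - 1)) {
      if (fv[i] == 0) roots <- c(roots, grid[i])
      else if (fv[i] * fv[i + 1] < 0)
        roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                         tol = 1e-12)$root)
    }
    # damped fixed-point iteration from Omega = omega (principal root)
    Om <- omega
    for (it in seq_len(1000)) {
      Om_new <- Om + 0.5 * (omega - sgn * K * sin(Om * taus) - Om)
      if (abs(Om_new - Om) < 1e-10) break
      Om <- Om_new
    }
    roots <- c(roots, Om)
    roots <- roots[abs(f(roots)) < 1e-6 * max(1, omega)]
    if (!length(roots)) return(numeric(0))
    sort(unique(round(roots, 9)))
  }

  rows <- list()
  for (br in c("in_phase", "anti_phase")) {
    sgn <- if (br == "in_phase") 1 else -1
    rts <- branch_roots(sgn)
    if (!length(rts)) next
    ct <- cos(rts * taus)
    stable <- if (br == "in_phase") ct > 0 else ct < 0
    rows[[br]] <- data.frame(branch = br, Omega = rts,
                             Omega_tau = rts * taus, stable = stable)
  }
  roots <- do.call(rbind, rows)
  if (is.null(roots) || !nrow(roots))
    stop("no self-consistent locked state found")
  rownames(roots) <- NULL
  s_in <- any(roots$stable[roots$branch == "in_phase"])
  s_anti <- any(roots$stable[roots$branch == "anti_phase"])
  state <- if (s_in && s_anti) "bistable"
           else if (s_in) "in_phase"
           else if (s_anti) "anti_phase"
           else "drift"
  structure(list(state = state, roots = roots, coupling = coupling,
                 tau = tau, freq = freq, weight = weight),
            class = "locked_state")
}

#' @export
print.locked_state <- function(x, ...) {
  cat(sprintf("Two-oscillator locked state at nu = %g Hz, tau = %g ms, K = %g rad/ms: %s\n",
              x$freq, x$tau, x$coupling * x$weight, x$state))
  print(x$roots, row.names = FALSE, digits = 6)
  invisible(x)
}
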