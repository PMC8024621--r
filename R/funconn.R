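#' Correlation-index functional network of one realization
#'
#' Computes the pairwise correlation index sigma_ij, the time average of
#' cos(theta_i(t) - theta_j(t)) over the recording window. Sigma is 1 for
#' fully correlated (in-phase) pairs, -1 for anti-correlated (anti-phase)
#' pairs and 0 for uncorrelated phases. Because only phase differences enter,
#' the index is invariant to wrapping and to global phase shifts.
#'
#' @param traj a `phase_trajectory` covering the post-transient window.
#' @param mean_freq optional mean frequency label (Hz); defaults to the
#'   trajectory's.
#' @return An object of class `"fc_matrix"`: symmetric n x n matrix with unit
#'   diagonal, entries in \[-1, 1\], and attributes `mean_freq` and
#'   `n_realizations_averaged`.
#' @examples
#' tr <- structure(list(times = 0:99, phases = rbind(seq(0, 5, length = 100),
#'                                                   seq(0, 5, length = 100) + pi)),
#'                 class = "phase_trajectory")
#' correlation_index(tr)[1, 2] # anti-phase pair: -1
#' @export
correlation_index <- function(traj, mean_freq = NULL) {
  stopifnot(inherits(traj, "phase_trajectory"))
  ph <- traj$phases
  if (is.null(ph) || ncol(ph) < 1) stop("empty trajectory")
  Tn <- ncol(ph)
  C <- cos(ph)
  S <- sin(ph)
  sigma <- (tcrossprod(C) + tcrossprod(S)) / Tn
  sigma[sigma > 1] <- 1
  sigma[sigma < -1] <- -1
  diag(sigma) <- 1
  if (is.null(mean_freq)) mean_freq <- traj$mean_freq
  fc_matrix(sigma, mean_freq = mean_freq, n_realizations = 1L)
}

#' Construct a correlation-index matrix
#'
#' Low-level constructor validating symmetry, the \[-1, 1\] range, and the
#' unit diagonal. Mostly used internally and in tests; analyses usually get
#' their `fc_matrix` from [correlation_index()] or [ensemble_fc()].
#'
#' @param sigma symmetric numeric matrix with entries in \[-1, 1\].
#' @param mean_freq optional mean frequency label (Hz).
#' @param n_realizations number of realizations averaged into `sigma`.
#' @param sigma_sd optional element-wise SD across realizations.
#' @return An `"fc_matrix"`.
#' @export
fc_matrix <- function(sigma, mean_freq = NULL, n_realizations = 1L,
                      sigma_sd = NULL) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma)) stop("sigma must be square")
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  sigma <- (sigma + t(sigma)) / 2
  if (any(sigma < -1 - 1e-12) || any(sigma > 1 + 1e-12))
    stop("sigma entries must lie in [-1, 1]")
  diag(sigma) <- 1
  structure(sigma, mean_freq = mean_freq,
            n_realizations_averaged = as.integer(n_realizations),
            sigma_sd = sigma_sd, class = "fc_matrix")
}

#' Ensemble-averaged functional network
#'
#' Averages the per-realization correlation-index matrices element-wise over
#' an ensemble of trajectories with fresh initial conditions and frequency
#' draws. The across-realization standard deviation is retained so that
#' 95 percent t-intervals of the mean can be formed (see [fc_ci()]).
#'
#' @param trajs a `phase_ensemble` or list of `phase_trajectory` objects with
#'   identical dimensions and windows.
#' @return An `"fc_matrix"` with attributes `n_realizations_averaged` and
#'   `sigma_sd` (element-wise SD across realizations; `NULL` for a single
#'   realization).
#' @export
ensemble_fc <- function(trajs) {
  if (inherits(trajs, "phase_trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("empty ensemble")
  dims <- vapply(trajs, function(tr) dim(tr$phases), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all trajectories must have identical dimensions")
  mats <- lapply(trajs, function(tr) unclass(correlation_index(tr)))
  R <- length(mats)
  m1 <- Reduce(`+`, mats) / R
  sd_mat <- NULL
  if (R > 1) {
    m2 <- Reduce(`+`, lapply(mats, function(m) m * m)) / R
    v <- pmax(m2 - m1 * m1, 0) * R / (R - 1)
    sd_mat <- sqrt(v)
    diag(sd_mat) <- 0
  }
  fc_matrix(m1, mean_freq = trajs[[1]]$mean_freq, n_realizations = R,
            sigma_sd = sd_mat)
}

#' Confidence band of an ensemble FC matrix
#'
#' Across-realization t-interval of the mean correlation index,
#' mean +/- t_(1-alpha/2, R-1) * SD / sqrt(R).
#'
#' @param fc an `fc_matrix` averaged over at least two realizations.
#' @param level confidence level (default 0.95).
#' @return List with matrices `low` and `high`.
#' @export
fc_ci <- function(fc, level = 0.95) {
  stopifnot(inherits(fc, "fc_matrix"))
  R <- attr(fc, "n_realizations_averaged")
  sd_mat <- attr(fc, "sigma_sd")
  if (is.null(sd_mat) || R < 2)
    stop("confidence bands need an ensemble of at least two realizations")
  half <- stats::qt(1 - (1 - level) / 2, df = R - 1) * sd_mat / sqrt(R)
  list(low = unclass(fc) - half, high = unclass(fc) + half)
}

#' @export
print.fc_matrix <- function(x, ...) {
  v <- unclass(x)[upper.tri(x)]
  cat(sprintf("Correlation-index matrix: %d nodes", nrow(x)))
  mf <- attr(x, "mean_freq")
  if (!is.null(mf)) cat(sprintf(", nu0 = %g Hz", mf))
  cat(sprintf(", averaged over %d realization(s)\n",
              attr(x, "n_realizations_averaged")))
  cat(sprintf("  sigma: min %.3f, mean %.3f, max %.3f; %.1f%% negative pairs\n",
              min(v), mean(v), max(v), 100 * mean(v < 0)))
  invisible(x)
}

#' @export
plot.fc_matrix <- function(x, ...) {
  n <- nrow(x)
  cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(unclass(x)[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = cols, xlab = "node", ylab = "node",
                  main = if (!is.null(attr(x, "mean_freq")))
                    sprintf("sigma at %g Hz", attr(x, "mean_freq")) else "sigma",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write / read a functional-connectivity matrix
#'
#' The matrix is written as a delimited text file next to a small JSON
#' sidecar (`<file>.json`) holding the mean frequency and ensemble size.
#'
#' @param fc an `fc_matrix`.
#' @param file output path (sidecar written to `paste0(file, ".json")`).
#' @param sep field separator.
#' @return `write_fc` invisibly returns `fc`; `read_fc` returns an
#'   `fc_matrix`.
#' @export
write_fc <- function(fc, file, sep = "\t") {
  stopifnot(inherits(fc, "fc_matrix"))
  write_matrix_file(unclass(fc), file, sep = sep)
  meta <- list(mean_freq = attr(fc, "mean_freq"),
               n_realizations = attr(fc, "n_realizations_averaged"))
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fc)
}

#' @rdname write_fc
#' @export
read_fc <- function(file, sep = "") {
  m <- read_matrix_file(file, sep = sep)
  meta_path <- paste0(file, ".json")
  mf <- NULL; nr <- 1L
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$mean_freq)) mf <- as.numeric(meta$mean_freq)
    if (!is.null(meta$n_realizations)) nr <- as.integer(meta$n_realizations)
  }
  fc_matrix(m, mean_freq = mf, n_realizations = nr)
}
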