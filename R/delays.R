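#' Distance-proportional transmission delays
#'
#' Derives the per-edge transmission delay from the Euclidean distance and a
#' fixed conduction speed, tau_ij = d_ij / speed. With distances in mm and
#' speed in m/s (1 m/s = 1 mm/ms) the delays come out in ms. Non-edges get a
#' zero delay.
#'
#' @param x a `connectome`.
#' @param speed conduction speed in m/s (default 5, a typical value for
#'   myelinated cortico-cortical fibers).
#' @return A `"delay_matrix"`: an n x n matrix of delays in ms with
#'   attributes `speed` (m/s) and `kind = "distance"`.
#' @examples
#' con <- pair_connectome(1, 25)
#' distance_delays(con, speed = 5) # 25 mm / 5 m/s = 5 ms
#' @export
distance_delays <- function(x, speed = 5) {
  stopifnot(inherits(x, "connectome"))
  if (!is.numeric(speed) || length(speed) != 1 || speed <= 0)
    stop("'speed' must be a positive scalar (m/s)")
  tau <- ifelse(x$weights > 0, x$distances / speed, 0)
  structure(tau, speed = speed, kind = "distance", class = "delay_matrix")
}

#' Uniform transmission delays
#'
#' Assigns the same delay to every edge regardless of its length. With the
#' structural weights retained, this control removes the distance dependence
#' of the delay so that only the connection strengths differentiate pairs.
#'
#' @param x a `connectome`.
#' @param tau0 common delay in ms (>= 0); `tau0 = 0` reduces the model to the
#'   classic (delay-free) Kuramoto system.
#' @return A `"delay_matrix"` with attributes `tau0` and `kind = "fixed"`.
#' @export
uniform_delays <- function(x, tau0) {
  stopifnot(inherits(x, "connectome"))
  if (!is.numeric(tau0) || length(tau0) != 1 || tau0 < 0)
    stop("'tau0' must be a non-negative scalar (ms)")
  tau <- (x$weights > 0) * tau0
  structure(tau, tau0 = tau0, kind = "fixed", class = "delay_matrix")
}

#' @export
print.delay_matrix <- function(x, ...) {
  pos <- x[x > 0]
  kind <- attr(x, "kind")
  if (identical(kind, "distance"))
    cat(sprintf("Delay matrix (distance / %g m/s): ", attr(x, "speed")))
  else
    cat(sprintf("Delay matrix (fixed tau0 = %g ms): ", attr(x, "tau0")))
  if (length(pos))
    cat(sprintf("%d delayed edges, %.2f - %.2f ms\n",
                length(pos), min(pos), max(pos)))
  else cat("no delayed edges\n")
  invisible(x)
}
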