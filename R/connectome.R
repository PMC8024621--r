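#' Weighted connectome with Euclidean distances
#'
#' Constructs and validates a connectome object: a square non-negative weight
#' matrix (normalized so the largest weight is at most 1) together with a
#' symmetric matrix of Euclidean distances in millimetres. Weights below
#' `weight_threshold` are treated as absent edges and set to zero, mirroring
#' the background threshold commonly applied to normalized fiber-count
#' matrices.
#'
#' @param weights n x n numeric matrix of non-negative connection weights;
#'   `weights[i, j] > 0` means node `i` receives input from node `j`. If the
#'   maximum exceeds 1 the matrix is rescaled to maximum 1 and the factor is
#'   recorded in the `"scale_factor"` attribute.
#' @param distances n x n numeric matrix of Euclidean distances (mm);
#'   symmetric, non-negative, zero diagonal. Every edge must have a positive
#'   distance.
#' @param directed logical; if `FALSE` (default) the weight matrix must be
#'   symmetric (within tolerance) and is symmetrized exactly.
#' @param hemisphere optional character vector of per-node hemisphere labels
#'   (`"L"`/`"R"`).
#' @param module optional integer vector of per-node structural module labels.
#' @param weight_threshold weights strictly below this value are set to zero
#'   (default `1e-5`).
#' @param tol relative tolerance for symmetry checks.
#' @return An object of class `"connectome"`: a list with elements `n`,
#'   `weights`, `distances`, `directed`, `hemisphere`, `module`.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' d <- matrix(10, 3, 3); diag(d) <- 0
#' con <- connectome(w, d)
#' n_edges(con)
#' @seealso [read_connectome()], [synthetic_connectome()], [binarize()]
#' @export
connectome <- function(weights, distances, directed = FALSE,
                       hemisphere = NULL, module = NULL,
                       weight_threshold = 1e-5, tol = 1e-8) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("'weights' must be a square matrix")
  if (nrow(distances) != n || ncol(distances) != n)
    stop("'distances' must match the dimension of 'weights' (", n, ")")
  storage.mode(weights) <- "double"
  storage.mode(distances) <- "double"
  if (anyNA(weights) || anyNA(distances) ||
      any(!is.finite(weights)) || any(!is.finite(distances)))
    stop("matrices must be finite and free of missing values")
  if (any(weights < 0))
    stop("negative weights are not allowed")
  diag(weights) <- 0

  scale_factor <- 1
  mx <- max(weights)
  if (mx > 1) {
    scale_factor <- mx
    weights <- weights / mx
  }
  weights[weights < weight_threshold] <- 0

  if (!directed) {
    if (max(abs(weights - t(weights))) > tol * max(1, max(weights)))
      stop("undirected connectome requires a symmetric weight matrix")
    weights <- (weights + t(weights)) / 2
  }

  if (any(distances < 0))
    stop("distances must be non-negative")
  if (max(abs(distances - t(distances))) > tol * max(1, max(distances)))
    stop("distance matrix is asymmetric beyond tolerance")
  distances <- (distances + t(distances)) / 2
  if (any(diag(distances) != 0))
    stop("distance matrix must have a zero diagonal")
  if (any(weights > 0 & distances == 0))
    stop("every edge must have a positive distance")

  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != n)
      stop("'hemisphere' must have one label per node")
  }
  if (!is.null(module)) {
    module <- as.integer(module)
    if (length(module) != n)
      stop("'module' must have one label per node")
  }

  structure(
    list(n = n, weights = weights, distances = distances,
         directed = isTRUE(directed), hemisphere = hemisphere,
         module = module),
    scale_factor = scale_factor,
    class = "connectome"
  )
}

#' Number of edges of a connectome
#'
#' @param x a `connectome`.
#' @return Integer edge count; ordered pairs for directed connectomes,
#'   unordered pairs otherwise.
#' @export
n_edges <- function(x) {
  stopifnot(inherits(x, "connectome"))
  m <- sum(x$weights > 0)
  if (x$directed) m else m %/% 2L
}

#' @export
print.connectome <- function(x, ...) {
  m <- n_edges(x)
  cat(sprintf("Connectome: %d nodes, %d %s edges (density %.1f%%)\n",
              x$n, m, if (x$directed) "directed" else "undirected",
              graph_density(x$n, m, x$directed)))
  pos <- x$weights[x$weights > 0]
  if (length(pos))
    cat(sprintf("  weights: [%.2e, %.3g]  (%.1f decades)\n",
                min(pos), max(pos), log10(max(pos) / min(pos))))
  dpos <- x$distances[upper.tri(x$distances)][x$weights[upper.tri(x$weights)] > 0 |
                                              t(x$weights)[upper.tri(x$weights)] > 0]
  if (length(dpos))
    cat(sprintf("  edge distances: %.1f - %.1f mm\n", min(dpos), max(dpos)))
  if (!is.null(x$hemisphere))
    cat("  hemispheres:", paste(names(table(x$hemisphere)),
                                table(x$hemisphere), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  w <- object$weights
  ut <- upper.tri(w)
  con <- ut & (w > 0 | t(w) > 0)
  wv <- pmax(w, t(w))[con]
  dv <- object$distances[con]
  out <- list(
    n = object$n,
    n_edges = n_edges(object),
    directed = object$directed,
    density_pct = graph_density(object$n, n_edges(object), object$directed),
    weight_range = range(wv),
    weight_decades = log10(max(wv) / min(wv)),
    distance_range = range(dv),
    weight_distance_cor = if (length(wv) > 2) stats::cor(wv, dv) else NA_real_
  )
  class(out) <- "summary.connectome"
  out
}

#' @export
print.summary.connectome <- function(x, ...) {
  cat(sprintf("Connectome summary: n = %d, m = %d, density = %.1f%%\n",
              x$n, x$n_edges, x$density_pct))
  cat(sprintf("  weight span: %.2e - %.3g (%.2f decades)\n",
              x$weight_range[1], x$weight_range[2], x$weight_decades))
  cat(sprintf("  edge distances: %.1f - %.1f mm\n",
              x$distance_range[1], x$distance_range[2]))
  cat(sprintf("  Pearson cor(weight, distance) over edges: %.3f\n",
              x$weight_distance_cor))
  invisible(x)
}

#' @export
plot.connectome <- function(x, what = c("weights", "distances"), log = TRUE, ...) {
  what <- match.arg(what)
  m <- if (what == "weights") x$weights else x$distances
  if (what == "weights" && log) {
    m[m <= 0] <- NA
    m <- log10(m)
  }
  graphics::image(seq_len(x$n), seq_len(x$n), t(m[x$n:1, , drop = FALSE]),
                  xlab = "node", ylab = "node",
                  main = if (what == "weights") "log10 weights" else "distance (mm)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Read a connectome from delimited matrix files
#'
#' Reads whitespace- or comma-delimited square numeric matrices (no header by
#' default) for weights and distances and validates them as a [connectome()].
#' Weights are rescaled to maximum 1 when necessary; the factor is recorded in
#' the `"scale_factor"` attribute.
#'
#' @param weights_file,distances_file paths to delimited square matrices.
#' @param directed logical; keep the weight matrix directed.
#' @param header logical; if `TRUE` the first row and column hold labels and
#'   are skipped.
#' @param sep field separator; `""` (default) means any whitespace, or use
#'   `","` for CSV dumps.
#' @inheritParams connectome
#' @return A `connectome`.
#' @export
read_connectome <- function(weights_file, distances_file, directed = FALSE,
                            header = FALSE, sep = "",
                            weight_threshold = 1e-5) {
  w <- read_matrix_file(weights_file, header = header, sep = sep)
  d <- read_matrix_file(distances_file, header = header, sep = sep)
  if (!identical(dim(w), dim(d)))
    stop("weight and distance matrices have different dimensions (",
         nrow(w), " vs ", nrow(d), ")")
  connectome(w, d, directed = directed, weight_threshold = weight_threshold)
}

read_matrix_file <- function(path, header = FALSE, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.table(path, header = FALSE, sep = sep,
                         stringsAsFactors = FALSE,
                         skip = if (header) 1L else 0L)
  if (header) m <- m[, -1, drop = FALSE]
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("file does not contain a square matrix: ", path)
  dimnames(m) <- NULL
  m
}

#' Write a connectome to delimited matrix files
#'
#' @param x a `connectome`.
#' @param weights_file,distances_file output paths.
#' @param sep field separator (default tab).
#' @return Invisibly, `x`.
#' @export
write_connectome <- function(x, weights_file, distances_file, sep = "\t") {
  stopifnot(inherits(x, "connectome"))
  write_matrix_file(x$weights, weights_file, sep = sep)
  write_matrix_file(x$distances, distances_file, sep = sep)
  invisible(x)
}

write_matrix_file <- function(m, path, sep = "\t") {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

#' Binarize a connectome
#'
#' Replaces every positive weight by exactly 1 while keeping the distances
#' (hence the delays) untouched. This isolates the effect of transmission
#' delay from that of connection strength in the control experiments.
#'
#' @param x a `connectome`.
#' @return A `connectome` with 0/1 weights.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "connectome"))
  w <- (x$weights > 0) * 1
  connectome(w, x$distances, directed = x$directed,
             hemisphere = x$hemisphere, module = x$module,
             weight_threshold = 0)
}
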