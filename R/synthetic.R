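#' Generate a synthetic human-like connectome
#'
#' Builds a weighted, spatially embedded random connectome that emulates the
#' gross structural statistics of cortical connectome matrices: two
#' hemispheric blocks of nodes placed in 3D, a modular edge topology (dense
#' within modules, sparser between, sparsest across hemispheres), connection
#' weights spanning several orders of magnitude, and a negative relation
#' between weight and Euclidean distance so that strong links concentrate at
#' short range.
#'
#' Nodes are placed around module centres inside two 80 x 100 x 80 mm
#' hemisphere boxes; when the resulting diameter exceeds 160 mm the
#' coordinates are shrunk so the largest inter-node distance is about 160 mm,
#' the span typical of cortical parcellations. Edge weights are drawn
#' log-uniformly over `weight_decades` decades, multiplied by
#' `exp(-d / decay_length)`, and renormalized to maximum 1; weights falling
#' below the absence threshold of `1e-5` are dropped. Disconnected components
#' are joined through their closest node pair so the graph is always
#' connected.
#'
#' @param n number of nodes (>= 2).
#' @param n_modules number of structural modules (>= 1), split across the two
#'   hemispheres.
#' @param weight_decades decades spanned by the log-uniform weight draw.
#' @param decay_length exponential decay length of weight with distance (mm).
#' @param seed integer seed; the generator is deterministic given `seed`.
#' @param p_intra,p_inter,p_cross edge probabilities within a module, between
#'   modules of one hemisphere, and across hemispheres.
#' @return A `connectome` with hemisphere (`"L"`/`"R"`) and module labels and
#'   a `"coords"` attribute holding the n x 3 node coordinates (mm).
#' @examples
#' con <- synthetic_connectome(n = 20, n_modules = 2, seed = 1)
#' summary(con)
#' @export
synthetic_connectome <- function(n = 66, n_modules = 6, weight_decades = 5,
                                 decay_length = 40, seed = 1,
                                 p_intra = 0.7, p_inter = 0.25,
                                 p_cross = 0.08) {
  if (n < 2) stop("'n' must be at least 2")
  if (n_modules < 1) stop("'n_modules' must be at least 1")
  if (weight_decades < 1) stop("'weight_decades' must be at least 1")
  if (decay_length <= 0) stop("'decay_length' must be positive")

  with_seed(seed, {
    n_left <- ceiling(n / 2)
    hemisphere <- rep(c("L", "R"), c(n_left, n - n_left))

    mod_left <- max(1L, ceiling(n_modules / 2))
    mod_right <- max(1L, n_modules - mod_left)
    if (n_modules == 1L) mod_right <- 1L
    module <- integer(n)
    module[hemisphere == "L"] <-
      rep_len(seq_len(mod_left), n_left)
    module[hemisphere == "R"] <-
      rep_len(if (n_modules == 1L) 1L else mod_left + seq_len(mod_right),
              n - n_left)

    # module centres inside each hemisphere box, nodes clustered around them
    box <- function(hemi) {
      if (hemi == "L") c(-80, 0) else c(0, 80)
    }
    centres <- matrix(NA_real_, max(module), 3)
    for (m in unique(module)) {
      hemi <- hemisphere[match(m, module)]
      bx <- box(hemi)
      centres[m, ] <- c(stats::runif(1, bx[1] + 15, bx[2] - 15),
                        stats::runif(1, 15, 85),
                        stats::runif(1, 15, 65))
    }
    coords <- centres[module, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = 15), n, 3)
    for (i in seq_len(n)) {
      bx <- box(hemisphere[i])
      coords[i, 1] <- min(max(coords[i, 1], bx[1]), bx[2])
      coords[i, 2] <- min(max(coords[i, 2], 0), 100)
      coords[i, 3] <- min(max(coords[i, 3], 0), 80)
    }
    d <- as.matrix(stats::dist(coords))
    if (max(d) > 160) {
      coords <- coords * (160 / max(d))
      d <- as.matrix(stats::dist(coords))
    }
    dimnames(d) <- NULL

    same_mod <- outer(module, module, "==")
    same_hemi <- outer(hemisphere, hemisphere, "==")
    p <- ifelse(same_mod & same_hemi, p_intra,
                ifelse(same_hemi, p_inter, p_cross))
    ut <- upper.tri(p)
    edge <- matrix(FALSE, n, n)
    edge[ut] <- stats::runif(sum(ut)) < p[ut]
    edge <- edge | t(edge)

    # guarantee a connected graph: join components at their closest pair
    comp <- components_of(edge)
    while (length(unique(comp)) > 1) {
      ids <- unique(comp)
      a <- which(comp == ids[1])
      b <- which(comp != ids[1])
      sub <- d[a, b, drop = FALSE]
      k <- arrayInd(which.min(sub), dim(sub))
      i <- a[k[1]]; j <- b[k[2]]
      edge[i, j] <- edge[j, i] <- TRUE
      comp <- components_of(edge)
    }

    w <- matrix(0, n, n)
    idx <- which(ut & edge)
    raw <- 10^(-stats::runif(length(idx), 0, weight_decades)) *
      exp(-d[idx] / decay_length)
    w[idx] <- raw / max(raw)
    w <- w + t(w)

    connectome(w, d, directed = FALSE, hemisphere = hemisphere,
               module = module) -> con
    attr(con, "coords") <- coords
    con
  })
}

components_of <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[i], comp[nb])
        if (any(c(comp[i], comp[nb]) != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

#' Connectome made of independent node pairs
#'
#' Builds a block-diagonal connectome of `length(weights)` mutually
#' disconnected two-node systems, one per weight/distance combination. Used
#' for controlled experiments in which each pair evolves independently, so
#' the effect of connection weight and transmission delay can be read off
#' per pair.
#'
#' @param weights vector of pair coupling weights in (0, 1].
#' @param distances vector (recycled) of pair distances in mm.
#' @return A `connectome` with `2 * length(weights)` nodes; `module` labels
#'   index the pairs.
#' @examples
#' pc <- pair_connectome(c(0.15, 0.25), 50)
#' n_edges(pc)
#' @export
pair_connectome <- function(weights, distances) {
  k <- length(weights)
  if (k < 1) stop("at least one pair is required")
  distances <- rep_len(distances, k)
  if (any(weights <= 0) || any(weights > 1))
    stop("pair weights must lie in (0, 1]")
  if (any(distances <= 0))
    stop("pair distances must be positive")
  n <- 2L * k
  w <- matrix(0, n, n)
  d <- matrix(0, n, n)
  for (p in seq_len(k)) {
    i <- 2L * p - 1L
    w[i, i + 1L] <- w[i + 1L, i] <- weights[p]
    d[i, i + 1L] <- d[i + 1L, i] <- distances[p]
  }
  connectome(w, d, directed = FALSE,
             hemisphere = rep(c("L", "R"), k),
             module = rep(seq_len(k), each = 2L),
             weight_threshold = 0)
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
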