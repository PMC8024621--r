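#' Specify a reproducible simulation experiment
#'
#' Collects everything a full experiment needs: the structural network (an
#' in-memory connectome, matrix files, or synthetic-generator parameters),
#' the delay rule (conduction speed or a fixed delay), the simulation
#' configuration, the frequency grid, and a scale factor that shrinks the
#' ensemble size and recording window proportionally for desk-scale runs
#' (full scale, 200 realizations x 12 s, is `scale = 1`).
#'
#' @param connectome optional `connectome` object.
#' @param weights_file,distances_file optional matrix files (used when
#'   `connectome` is `NULL`).
#' @param synthetic optional named list of [synthetic_connectome()] arguments
#'   (used when neither an object nor files are given).
#' @param directed logical, for file input.
#' @param speed conduction speed in m/s for distance-proportional delays.
#' @param fixed_delay if non-`NULL`, a common delay in ms overriding `speed`.
#' @param binarize logical; replace all positive weights by 1 before
#'   simulating (the binary-network control).
#' @param config a [sim_config()].
#' @param freqs mean-frequency grid in Hz.
#' @param scale scale factor in (0, 1] applied to `n_realizations` and
#'   `t_record`.
#' @param out_dir output directory (created if missing).
#' @return An object of class `"experiment_spec"`.
#' @seealso [run_experiment()]
#' @export
experiment_spec <- function(connectome = NULL, weights_file = NULL,
                            distances_file = NULL, synthetic = NULL,
                            directed = FALSE, speed = 5, fixed_delay = NULL,
                            binarize = FALSE,
                            config = sim_config(mean_freq = 10),
                            freqs = c(3, 11, 23, 35, 51), scale = 1,
                            out_dir = tempfile("experiment")) {
  if (is.null(connectome) && is.null(weights_file) && is.null(synthetic))
    synthetic <- list()
  if (!is.null(connectome)) stopifnot(inherits(connectome, "connectome"))
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stop("'scale' must lie in (0, 1]")
  structure(
    list(connectome = connectome, weights_file = weights_file,
         distances_file = distances_file, synthetic = synthetic,
         directed = directed, speed = speed, fixed_delay = fixed_delay,
         binarize = isTRUE(binarize), config = config, freqs = freqs,
         scale = scale, out_dir = out_dir),
    class = "experiment_spec"
  )
}

#' Run a specified experiment and persist its outputs
#'
#' Resolves the structural network, derives the delay matrix, runs the
#' frequency sweep at the requested scale, and writes to `spec$out_dir`:
#' one functional-connectivity matrix per frequency (with JSON sidecars),
#' weight- and distance-binned correlation summaries, the similarity curve
#' and per-frequency summary table, and a JSON manifest recording every
#' parameter, the derived per-frequency seeds, integrator statistics, and
#' the package version. Re-running the same spec reproduces all outputs
#' bitwise.
#'
#' @param spec an [experiment_spec()].
#' @return Invisibly, a list with the `freq_sweep` result, the resolved
#'   `connectome`, and the manifest.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  con <- resolve_connectome(spec)
  if (spec$binarize) con <- binarize(con)
  delays <- if (!is.null(spec$fixed_delay))
    uniform_delays(con, spec$fixed_delay)
  else
    distance_delays(con, spec$speed)

  cfg <- spec$config
  cfg$n_realizations <- max(1L, as.integer(round(cfg$n_realizations * spec$scale)))
  cfg$t_record <- max(cfg$record_dt / 1000, cfg$t_record * spec$scale)
  class(cfg) <- "sim_config"

  dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  sweep <- frequency_sweep(con, delays, cfg, freqs = spec$freqs)

  stats_tot <- c(accepted = 0, rejected = 0)
  for (k in seq_along(spec$freqs)) {
    f <- spec$freqs[k]
    write_fc(sweep$fc[[k]],
             file.path(spec$out_dir, sprintf("fc_%gHz.tsv", f)))
    bw <- bin_correlation(sweep$fc[[k]], con, by = "weight")
    bd <- bin_correlation(sweep$fc[[k]], con, by = "distance")
    utils::write.table(bw, file.path(spec$out_dir,
                                     sprintf("binned_weight_%gHz.tsv", f)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(bd, file.path(spec$out_dir,
                                     sprintf("binned_distance_%gHz.tsv", f)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(sweep$summary, file.path(spec$out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max,
                                          length(spec$freqs)))
  manifest <- list(
    package = "kuramotoFC",
    version = as.character(utils::packageVersion("kuramotoFC")),
    n_nodes = con$n,
    n_edges = n_edges(con),
    directed = con$directed,
    binarized = spec$binarize,
    delay_rule = if (!is.null(spec$fixed_delay))
      list(kind = "fixed", tau0_ms = spec$fixed_delay)
    else list(kind = "distance", speed_m_per_s = spec$speed),
    synthetic = spec$synthetic,
    config = unclass(cfg),
    freqs_hz = spec$freqs,
    per_freq_seeds = seeds,
    scale = spec$scale
  )
  jsonlite::write_json(manifest, file.path(spec$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(sweep = sweep, connectome = con, manifest = manifest))
}

resolve_connectome <- function(spec) {
  if (!is.null(spec$connectome)) return(spec$connectome)
  if (!is.null(spec$weights_file)) {
    if (is.null(spec$distances_file))
      stop("'distances_file' is required with 'weights_file'")
    return(read_connectome(spec$weights_file, spec$distances_file,
                           directed = spec$directed))
  }
  do.call(synthetic_connectome, spec$synthetic)
}

#' Write bundled test fixtures
#'
#' Generates the small connectome fixtures used in examples and tests: an
#' 8-node toy network and a 66-node human-like synthetic network, written as
#' delimited weight/distance matrices together with a JSON file of expected
#' summary statistics computed at generation time. Regeneration with the
#' same seed is byte-identical.
#'
#' @param dir output directory.
#' @param seed integer seed (default 20210324).
#' @return Invisibly, a list with the two connectomes and the expected
#'   statistics.
#' @export
make_fixtures <- function(dir, seed = 20210324) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- synthetic_connectome(n = 8, n_modules = 2, weight_decades = 3,
                              decay_length = 40, seed = seed)
  human <- synthetic_connectome(n = 66, n_modules = 6, weight_decades = 5,
                                decay_length = 40, seed = seed + 1L)
  write_connectome(toy, file.path(dir, "toy8_weights.tsv"),
                   file.path(dir, "toy8_distances.tsv"))
  write_connectome(human, file.path(dir, "human66_synthetic_weights.tsv"),
                   file.path(dir, "human66_synthetic_distances.tsv"))
  stat <- function(con) {
    s <- summary(con)
    list(n = s$n, n_edges = s$n_edges, density_pct = s$density_pct,
         weight_decades = s$weight_decades,
         weight_distance_cor = s$weight_distance_cor,
         max_distance_mm = max(con$distances))
  }
  expected <- list(seed = seed, toy8 = stat(toy), human66 = stat(human))
  jsonlite::write_json(expected, file.path(dir, "expected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(toy8 = toy, human66 = human, expected = expected))
}
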