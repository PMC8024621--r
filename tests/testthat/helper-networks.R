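# small networks and short configs shared across tests

toy_connectome <- function(n = 3, w = 0.5, d = 10) {
  wm <- matrix(w, n, n); diag(wm) <- 0
  dm <- matrix(d, n, n); diag(dm) <- 0
  connectome(wm, dm)
}

# quick config: short windows, few realizations
quick_config <- function(mean_freq = 10, ..., t_transient = 1, t_record = 0.5,
                         n_realizations = 1, freq_sd = 0, noise_sd = 0,
                         seed = 1) {
  sim_config(mean_freq = mean_freq, freq_sd = freq_sd, noise_sd = noise_sd,
             t_transient = t_transient, t_record = t_record,
             n_realizations = n_realizations, seed = seed, ...)
}

# hand-built trajectory for functional-connectivity tests
fake_trajectory <- function(phases, record_dt = 1, mean_freq = NULL) {
  structure(
    list(times = seq_len(ncol(phases)) - 1, phases = phases,
         mean_freq = mean_freq, record_dt = record_dt,
         stats = list(n_accepted = 0, n_rejected = 0), seed = 0L),
    class = "phase_trajectory"
  )
}
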