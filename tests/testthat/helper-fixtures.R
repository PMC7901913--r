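# shared fixtures, built once per test run
fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function(n_train = 200, n_test = 80, n_classes = 5,
                          seed = 42) {
  key <- paste(n_train, n_test, n_classes, seed, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    sp <- synthetic_spec(n_classes = n_classes, n_train = n_train,
                         n_test = n_test, seed = seed)
    pr <- make_prototypes(sp)
    fixture_cache[[key]] <- list(
      spec = sp, prototypes = pr,
      train = sample_dataset(sp, n_train, pr),
      test = sample_dataset(sp, n_test, pr, split_seed_offset = 1L)
    )
  }
  fixture_cache[[key]]
}

# a network whose geometry and thresholds are fully hand-specified,
# with deterministic distinct firing delays
tiny_network <- function(n_input, n_output, threshold,
                         dyn = dynamics_spec("L_HB", alpha_plus = 0.1),
                         tau_leak = 120, t_inhibit = 10, t_refrac = 1e-3,
                         w = NULL, w_init = 0.8, t_stdp = 60) {
  cfg <- neuron_config(tau_leak = tau_leak, t_refrac = t_refrac,
                       t_inhibit = t_inhibit, threshold = threshold,
                       t_emit_sigma = 0)
  net <- snn_network(n_input, n_output, cfg, stdp_rule(dyn, t_stdp),
                     w_init = w_init, seed = 99)
  net$t_emit <- 1e-4 * seq_len(n_output)  # distinct, ordered delays
  if (!is.null(w)) net$weights <- w
  net
}

spike_train <- function(pixel, time) {
  o <- order(time, pixel)
  tibble::tibble(pixel = as.integer(pixel[o]), time = time[o])
}

# shipped dynamics grid rows as spec objects
grid_specs <- function() {
  g <- dynamics_grid()
  lapply(seq_len(nrow(g)), function(i) {
    as_dynamics_spec(as.list(g[i, ]))
  })
}
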