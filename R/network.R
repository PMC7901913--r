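#' Output-neuron configuration
#'
#' Parameters of the leaky integrate-and-fire output layer and its
#' winner-take-all mechanics. All times are in microseconds.
#'
#' @param tau_leak Membrane leak time constant (default 120).
#' @param t_refrac Refractory period after a neuron's own spike during
#'   which it cannot integrate (default 1e-3, i.e. 1 ns).
#' @param t_inhibit Lateral-inhibition window imposed on all other
#'   neurons when one fires (default 10).
#' @param threshold Membrane firing threshold, in units of summed synaptic
#'   weight. Not a biological constant: it must be set relative to the
#'   input drive; see [calibrate_threshold()].
#' @param t_emit_mu,t_emit_sigma Mean and standard deviation of the
#'   per-neuron firing delay (defaults 1e-4 and 1e-6, i.e. 0.1 ns and
#'   1 ps): each neuron fires its spike this long after crossing
#'   threshold, which breaks ties in the winner-take-all race.
#' @return An object of class `neuron_config`.
#' @export
neuron_config <- function(tau_leak = 120, t_refrac = 1e-3, t_inhibit = 10,
                          threshold = NULL, t_emit_mu = 1e-4,
                          t_emit_sigma = 1e-6) {
  stopifnot(tau_leak > 0, t_refrac >= 0, t_inhibit >= 0,
            t_emit_mu >= 0, t_emit_sigma >= 0)
  if (!is.null(threshold)) stopifnot(threshold > 0)
  structure(list(tau_leak = tau_leak, t_refrac = t_refrac,
                 t_inhibit = t_inhibit, threshold = threshold,
                 t_emit_mu = t_emit_mu, t_emit_sigma = t_emit_sigma),
            class = "neuron_config")
}

#' Simplified STDP rule
#'
#' The plasticity rule applied when an output neuron fires: every input
#' synapse whose most recent pre-synaptic spike falls within the STDP
#' window `[t_post - t_stdp, t_post]` (boundary inclusive) is
#' potentiated by one event of the synapse dynamics; every other input
#' synapse (including those that never spiked) is depressed.
#'
#' @param dynamics A [dynamics_spec()] giving the per-event weight update.
#' @param t_stdp STDP window in microseconds (default 60).
#' @return An object of class `stdp_rule`.
#' @export
stdp_rule <- function(dynamics, t_stdp = 60) {
  stopifnot(inherits(dynamics, "dynamics_spec"), t_stdp > 0)
  structure(list(dynamics = dynamics, t_stdp = t_stdp), class = "stdp_rule")
}

#' Construct a two-layer fully connected spiking network
#'
#' Input neurons (one per pixel) project through plastic synapses to a
#' layer of LIF output neurons coupled by lateral inhibition. All weights
#' start at `w_init` (a uniform high initial conductance, as obtained in
#' hardware by an electroforming step). Each output neuron's firing delay
#' `t_emit` is drawn once at construction from
#' `Normal(t_emit_mu, t_emit_sigma)` under a dedicated seed.
#'
#' @param n_input Number of input neurons (pixels).
#' @param n_output Number of output neurons.
#' @param config A [neuron_config()] with a non-NULL threshold.
#' @param rule An [stdp_rule()].
#' @param w_init Initial synaptic weight (default 0.8).
#' @param seed Seed for the per-neuron firing-delay draw.
#' @return An object of class `snn_network`.
#' @export
snn_network <- function(n_input, n_output, config, rule, w_init = 0.8,
                        seed = 1L) {
  stopifnot(n_input >= 1, n_output >= 1, inherits(config, "neuron_config"),
            inherits(rule, "stdp_rule"), w_init >= 0, w_init <= 1)
  if (is.null(config$threshold)) {
    stop("`config$threshold` must be set; see calibrate_threshold()",
         call. = FALSE)
  }
  t_emit <- with_preserved_seed(seed, {
    pmax(0, stats::rnorm(n_output, config$t_emit_mu, config$t_emit_sigma))
  })
  structure(list(
    weights = matrix(w_init, n_input, n_output),
    config = config, rule = rule, t_emit = t_emit,
    n_input = as.integer(n_input), n_output = as.integer(n_output),
    seed = as.integer(seed)
  ), class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network>", x$n_input, "inputs ->", x$n_output,
      "LIF outputs (WTA)\n")
  cat("  dynamics:", x$rule$dynamics$family,
      " threshold:", signif(x$config$threshold, 4),
      " weights in [", signif(min(x$weights), 3), ",",
      signif(max(x$weights), 3), "]\n")
  invisible(x)
}

#' Calibrate the LIF firing threshold
#'
#' The firing threshold is not a free biological constant: it must scale
#' with the input drive so that a typical image elicits a handful of
#' output spikes per presentation at the initial weights. The calibration
#' rule sets
#' `threshold = c * w_init * mean(sum of pixel rates) * tau_leak`,
#' i.e. a fraction `c` of the steady-state membrane level an average
#' image would sustain through untrained synapses. With the default
#' `c = 0.5` an average-intensity image drives roughly 2-5 winner spikes
#' within a 350 microsecond presentation.
#'
#' @param images List of images (or a dataset tibble with an `image`
#'   column) used to estimate the mean total input rate.
#' @param enc An [encoding_spec()].
#' @param config A [neuron_config()] (for `tau_leak`).
#' @param c Threshold fraction of the steady-state drive (default 0.5).
#' @param w_init Initial synaptic weight the calibration assumes.
#' @return The threshold, a positive scalar.
#' @export
calibrate_threshold <- function(images, enc = encoding_spec(),
                                config = neuron_config(), c = 0.5,
                                w_init = 0.8) {
  if (is.data.frame(images)) images <- images$image
  stopifnot(length(images) > 0, c > 0)
  total_rate <- vapply(images, function(img) sum(pixel_rates(img, enc)),
                       numeric(1))
  c * w_init * mean(total_rate) * config$tau_leak
}

#' Present one spike-train set to the network
#'
#' Runs the event-driven simulation of a single presentation: input
#' spikes and scheduled output fires are processed in global time order;
#' membranes decay exponentially and integrate weighted input spikes
#' outside refractory/inhibition windows; a neuron crossing threshold
#' fires after its `t_emit` delay, resets its membrane, enters its
#' refractory period, and inhibits all other neurons for `t_inhibit`
#' (losing a tied race cancels the fire). With `stdp_on = TRUE` each
#' output spike triggers one plasticity event per input synapse.
#'
#' Neuron state (membranes, windows, pre-spike history) is local to a
#' presentation; only weights persist between presentations.
#'
#' @param network An [snn_network()].
#' @param spikes A tibble from [encode_image()] (`pixel`, `time`), sorted
#'   by time.
#' @param stdp_on Apply plasticity? (`FALSE` = inference mode.)
#' @return A list with `spikes` (tibble of output `neuron`, `time`) and
#'   `network` (the network, with updated weights when `stdp_on`).
#' @export
present <- function(network, spikes, stdp_on = FALSE) {
  stopifnot(inherits(network, "snn_network"))
  if (is.unsorted(spikes$time)) {
    stop("input spikes must be ordered in time", call. = FALSE)
  }
  dyn <- network$rule$dynamics
  res <- present_cpp(
    network$weights, spikes$time, spikes$pixel, network$t_emit,
    tau_leak = network$config$tau_leak,
    t_refrac = network$config$t_refrac,
    t_inhibit = network$config$t_inhibit,
    threshold = network$config$threshold,
    t_stdp = network$rule$t_stdp, stdp_on = stdp_on,
    family = match(dyn$family, c("L_HB", "NL_SB", "NL_HB")) - 1L,
    a_plus = dyn$alpha_plus, a_minus = dyn$alpha_minus,
    g_plus = dyn$gamma_plus %||% 0, g_minus = dyn$gamma_minus %||% 0,
    ws_plus = dyn$w_stop_plus %||% 1, ws_minus = dyn$w_stop_minus %||% 1
  )
  if (stdp_on) network$weights <- res$weights
  list(spikes = tibble::tibble(neuron = res$neuron, time = res$time),
       network = network)
}

#' Save / load a network snapshot
#'
#' Serializes the weights, configuration, STDP rule and seeds to a single
#' JSON file with named arrays; `read_network()` rebuilds the network,
#' re-deriving any normalization constants rather than trusting them from
#' the file. `export_weights_csv()` writes the weight matrix alone as CSV
#' for external inspection.
#'
#' @param network An [snn_network()].
#' @param path Output file.
#' @return `read_network()`: an `snn_network`. Writers return the path,
#'   invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "snn_network"))
  payload <- list(
    n_input = network$n_input, n_output = network$n_output,
    weights = as.vector(network$weights),
    t_emit = network$t_emit, seed = network$seed,
    config = unclass(network$config),
    t_stdp = network$rule$t_stdp,
    dynamics = as.list(network$rule$dynamics)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(neuron_config, p$config)
  dyn <- as_dynamics_spec(p$dynamics)  # w_stop re-derived, never trusted
  net <- snn_network(p$n_input, p$n_output, cfg, stdp_rule(dyn, p$t_stdp),
                     seed = p$seed)
  net$weights <- matrix(p$weights, p$n_input, p$n_output)
  net$t_emit <- p$t_emit
  net
}

#' @rdname write_network
#' @export
export_weights_csv <- function(network, path) {
  stopifnot(inherits(network, "snn_network"))
  utils::write.csv(network$weights, path, row.names = FALSE)
  invisible(path)
}
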