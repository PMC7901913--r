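#' @keywords internal
#' Per-image presentation summary: spike counts and first-spike times
present_summary <- function(network, image, enc, stdp_on = FALSE) {
  spikes <- encode_image(image, enc)
  res <- present(network, spikes, stdp_on = stdp_on)
  out <- res$spikes
  counts <- tabulate(out$neuron, nbins = network$n_output)
  first <- rep(Inf, network$n_output)
  if (nrow(out) > 0) {
    agg <- tapply(out$time, out$neuron, min)
    first[as.integer(names(agg))] <- agg
  }
  list(counts = counts, first = first, network = res$network)
}

# class with the highest spike count; ties -> lowest class label;
# silent -> NA (unassigned)
assign_from_counts <- function(counts, classes) {
  apply(counts, 1, function(row) {
    if (sum(row) == 0) return(NA_integer_)
    classes[which.max(row)]  # which.max takes the first (lowest label) tie
  })
}

# most active neuron; ties -> earliest first spike, then lowest index
response_neuron <- function(counts, first) {
  if (sum(counts) == 0) return(NA_integer_)
  cand <- which(counts == max(counts))
  if (length(cand) > 1) {
    cand <- cand[first[cand] == min(first[cand])]
  }
  cand[1]
}

#' Assign a class to each output neuron
#'
#' Presents a labeled image subset with plasticity frozen and associates
#' each output neuron with the class it spikes most for. Neurons that
#' never spike remain unassigned (`NA`); count ties resolve to the lowest
#' class label.
#'
#' @param network An [snn_network()].
#' @param data Dataset tibble (`image` list-column, integer `label`).
#' @param enc An [encoding_spec()].
#' @param seed Optional seed for the presentation encodings.
#' @return Integer vector of length `n_output` with class labels
#'   (`NA` = unassigned).
#' @export
assign_classes <- function(network, data, enc = encoding_spec(), seed = NULL) {
  stopifnot(inherits(network, "snn_network"))
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("`data` must be a non-empty dataset tibble", call. = FALSE)
  }
  run <- function() {
    classes <- sort(unique(data$label))
    counts <- matrix(0, network$n_output, length(classes))
    for (k in seq_len(nrow(data))) {
      s <- present_summary(network, data$image[[k]], enc, stdp_on = FALSE)
      col <- match(data$label[k], classes)
      counts[, col] <- counts[, col] + s$counts
    }
    assign_from_counts(counts, classes)
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Classification accuracy of a trained network
#'
#' Presents each test image with plasticity frozen; the network's
#' response is the most active output neuron within the presentation
#' window (ties: earliest first spike, then lowest index). A digit is
#' classified correctly when the responding neuron's class equals the
#' label; images eliciting no output spikes count as misclassified.
#'
#' @inheritParams assign_classes
#' @param class_map Integer class per neuron from [assign_classes()].
#' @return Fraction of correctly classified digits in \[0, 1\].
#' @export
evaluate_ca <- function(network, class_map, data, enc = encoding_spec(),
                        seed = NULL) {
  stopifnot(inherits(network, "snn_network"),
            length(class_map) == network$n_output)
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("`data` must be a non-empty dataset tibble", call. = FALSE)
  }
  run <- function() {
    good <- 0L
    for (k in seq_len(nrow(data))) {
      s <- present_summary(network, data$image[[k]], enc, stdp_on = FALSE)
      win <- response_neuron(s$counts, s$first)
      if (!is.na(win) && !is.na(class_map[win]) &&
          class_map[win] == data$label[k]) {
        good <- good + 1L
      }
    }
    good / nrow(data)
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Weight contrast: 2-means separation of the pooled weights
#'
#' Pools all synaptic weights and clusters them into two groups with
#' k-means (Lloyd iterations); the contrast is the absolute distance
#' between the two cluster centers — a measure of how much of the
#' available weight range the trained network exploits. Initialization is
#' deterministic by default (centers at the 10th and 90th percentiles) so
#' the statistic is reproducible; a random-restart mode is available.
#'
#' @param weights An [snn_network()] or a numeric weight matrix/vector.
#' @param init `"percentile"` (deterministic) or `"random"` restarts.
#' @param seed Seed for `init = "random"`.
#' @return Contrast in \[0, 1\]; 0 when all weights are identical.
#' @examples
#' weight_contrast(c(rep(0.1, 50), rep(0.9, 50)))  # 0.8
#' @export
weight_contrast <- function(weights, init = c("percentile", "random"),
                            seed = NULL) {
  init <- match.arg(init)
  if (inherits(weights, "snn_network")) weights <- weights$weights
  x <- as.numeric(weights)
  if (length(x) == 0) stop("empty weight matrix", call. = FALSE)
  if (length(unique(x)) < 2) return(0)
  fit <- if (init == "percentile") {
    ctr <- unname(stats::quantile(x, c(0.1, 0.9)))
    if (diff(ctr) == 0) ctr <- range(x)
    stats::kmeans(x, centers = matrix(ctr, 2, 1), algorithm = "Lloyd",
                  iter.max = 100)
  } else {
    run <- function() stats::kmeans(x, centers = 2, nstart = 10,
                                    algorithm = "Lloyd", iter.max = 100)
    if (is.null(seed)) run() else with_preserved_seed(seed, run())
  }
  abs(diff(as.vector(fit$centers)))
}

#' Training duration from an evaluation trace
#'
#' The fraction of the training stream needed to reach 99% of the
#' maximum classification accuracy: the first checkpoint whose CA meets
#' `0.99 * max(CA)` (no interpolation between checkpoints), divided by
#' the total stream length.
#'
#' @param trace Tibble with `images_seen` (strictly increasing) and `ca`.
#' @param n_tot Total number of training images the fraction refers to.
#' @return `delta_train` in \[0, 1\].
#' @examples
#' tr <- tibble::tibble(images_seen = c(6000, 30000, 60000),
#'                      ca = c(0.84, 0.846, 0.848))
#' training_duration(tr, 60000)  # 0.1
#' @export
training_duration <- function(trace, n_tot) {
  if (!is.data.frame(trace) || nrow(trace) == 0) {
    stop("`trace` must be a non-empty evaluation trace", call. = FALSE)
  }
  stopifnot(n_tot > 0)
  ca_max <- max(trace$ca)
  idx <- which(trace$ca >= 0.99 * ca_max)[1]  # ca_max = 0: trivially row 1
  trace$images_seen[idx] / n_tot
}

#' Training efficiency
#'
#' The mean of the classification accuracy and the saved training
#' fraction, `(ca + (1 - delta_train)) / 2`, normalized to \[0, 1\]:
#' it is maximal for a network that classifies perfectly after seeing
#' almost none of the training stream.
#'
#' @param ca Classification accuracy in \[0, 1\].
#' @param delta_train Training-duration fraction in \[0, 1\].
#' @return Efficiency in \[0, 1\].
#' @examples
#' efficiency(0.8, 0.2)  # 0.8
#' @export
efficiency <- function(ca, delta_train) {
  if (any(ca < 0 | ca > 1) || any(delta_train < 0 | delta_train > 1)) {
    stop("`ca` and `delta_train` must lie in [0, 1]", call. = FALSE)
  }
  (ca + (1 - delta_train)) / 2
}

#' Train the network with unsupervised STDP and track its learning
#'
#' Presents each training image once with plasticity on. At a set of
#' checkpoints the plasticity is frozen and the network is evaluated:
#' output neurons are (re-)assigned classes on a dedicated labeled
#' subset, the classification accuracy is measured, and the weight
#' contrast recorded. Evaluations use fixed dedicated seeds so the
#' checkpoint cadence does not perturb the training spike streams, and
#' they never mutate the weights.
#'
#' @param network An [snn_network()].
#' @param train_data Dataset tibble (`image`, `label`); each row is
#'   presented once, in order.
#' @param eval_data Held-out dataset for the CA trace; defaults to the
#'   assignment subset.
#' @param assign_data Labeled subset used for class assignment; defaults
#'   to a random fraction `assign_frac` of the training stream.
#' @param assign_frac Fraction of `train_data` sampled for assignment
#'   when `assign_data` is not given (default 0.1).
#' @param checkpoints Number of evaluation checkpoints spread evenly over
#'   the stream (default 10, i.e. every 10%).
#' @param enc An [encoding_spec()].
#' @param seed Integer seed governing every stochastic element of the run
#'   (training encodings, assignment sampling, evaluation encodings).
#' @return An object of class `snn_fit`: the evaluation trace, the final
#'   class map, summary scalars (`ca_final`, `ca_max`, `delta_train`,
#'   `efficiency`) and the trained network. See [tidy()] / [glance()].
#' @export
train_snn <- function(network, train_data, eval_data = NULL,
                      assign_data = NULL, assign_frac = 0.1,
                      checkpoints = 10, enc = encoding_spec(), seed = 1L) {
  stopifnot(inherits(network, "snn_network"))
  if (!is.data.frame(train_data) || nrow(train_data) == 0) {
    stop("`train_data` must be a non-empty dataset tibble", call. = FALSE)
  }
  n <- nrow(train_data)
  eval_seed <- seed + 10000L
  if (is.null(assign_data)) {
    assign_data <- with_preserved_seed(eval_seed, {
      train_data[sample(n, max(1L, round(assign_frac * n))), ]
    })
  }
  if (is.null(eval_data)) eval_data <- assign_data

  cps <- unique(pmin(n, round(seq_len(checkpoints) * n / checkpoints)))
  trace <- vector("list", length(cps))
  class_map <- rep(NA_integer_, network$n_output)

  evaluate_now <- function(net, seen) {
    cm <- assign_classes(net, assign_data, enc, seed = eval_seed + 1L)
    ca <- evaluate_ca(net, cm, eval_data, enc, seed = eval_seed + 2L)
    ct <- weight_contrast(net$weights)
    list(cm = cm,
         row = tibble::tibble(images_seen = seen, ca = ca, contrast = ct))
  }

  net <- network
  with_preserved_seed(seed, {
    slot <- 1L
    for (k in seq_len(n)) {
      spikes <- encode_image(train_data$image[[k]], enc)
      net <- present(net, spikes, stdp_on = TRUE)$network
      if (slot <= length(cps) && k == cps[slot]) {
        ev <- evaluate_now(net, k)
        trace[[slot]] <- ev$row
        class_map <- ev$cm
        slot <- slot + 1L
      }
    }
  })

  trace <- dplyr::bind_rows(trace)
  ca_max <- max(trace$ca)
  delta <- training_duration(trace, n)
  structure(list(
    trace = trace, class_map = class_map, network = net,
    n_train = n, ca_final = trace$ca[nrow(trace)], ca_max = ca_max,
    delta_train = delta, efficiency = efficiency(ca_max, delta),
    seed = seed
  ), class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  cat("<snn_fit>", x$n_train, "training images,",
      nrow(x$trace), "checkpoints\n")
  cat(sprintf("  CA final %.3f (max %.3f), delta_train %.3f, efficiency %.3f\n",
              x$ca_final, x$ca_max, x$delta_train, x$efficiency))
  invisible(x)
}

#' @rdname train_snn
#' @param x An `snn_fit` object.
#' @param ... Unused.
#' @export
tidy.snn_fit <- function(x, ...) {
  x$trace
}

#' @rdname train_snn
#' @export
glance.snn_fit <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, ca_final = x$ca_final, ca_max = x$ca_max,
    delta_train = x$delta_train, efficiency = x$efficiency,
    contrast_final = x$trace$contrast[nrow(x$trace)],
    n_assigned = sum(!is.na(x$class_map))
  )
}

#' Sweep a grid of synapse dynamics through the full study
#'
#' For each dynamics parameterization: computes the device figures of
#' merit and runs a complete train/evaluate cycle on the supplied data,
#' returning one row per dynamics with resolution, non-linearity, final
#' classification accuracy, weight contrast, training duration and
#' efficiency.
#'
#' @param dynamics Parameter table as in [dynamics_grid()].
#' @param train_data,eval_data Datasets as in [train_snn()].
#' @param n_output Number of output neurons.
#' @param enc An [encoding_spec()].
#' @param config A [neuron_config()]; a NULL threshold is calibrated from
#'   the training images via [calibrate_threshold()].
#' @param t_stdp STDP window (microseconds).
#' @param checkpoints Evaluation checkpoints per run.
#' @param seed Integer seed (shared run conditions across rows).
#' @return A tibble with one row per dynamics: parameters, `eta`,
#'   `lambda`, `ca`, `contrast`, `delta_train`, `efficiency`.
#' @export
sweep_dynamics <- function(dynamics = dynamics_grid(), train_data,
                           eval_data = NULL, n_output = 50,
                           enc = encoding_spec(), config = neuron_config(),
                           t_stdp = 60, checkpoints = 4, seed = 1L) {
  if (nrow(dynamics) == 0) {
    return(tibble::tibble(
      family = character(), alpha = numeric(), gamma = numeric(),
      n_stop = numeric(), eta = numeric(), lambda = numeric(),
      ca = numeric(), contrast = numeric(), delta_train = numeric(),
      efficiency = numeric()
    ))
  }
  if (is.null(config$threshold)) {
    config$threshold <- calibrate_threshold(train_data, enc, config)
  }
  rows <- purrr::pmap(dynamics, function(family, alpha, gamma = NA,
                                         n_stop = NA, ...) {
    spec <- as_dynamics_spec(list(family = family, alpha = alpha,
                                  gamma = gamma, n_stop = n_stop))
    net <- snn_network(length(train_data$image[[1]]), n_output, config,
                       stdp_rule(spec, t_stdp), seed = seed)
    fit <- train_snn(net, train_data, eval_data = eval_data,
                     checkpoints = checkpoints, enc = enc, seed = seed)
    tibble::tibble(
      family = family, alpha = alpha, gamma = gamma, n_stop = n_stop,
      eta = resolution_eta(spec), lambda = nonlinearity_lambda(spec),
      ca = fit$ca_final,
      contrast = fit$trace$contrast[nrow(fit$trace)],
      delta_train = fit$delta_train, efficiency = fit$efficiency
    )
  })
  dplyr::bind_rows(rows)
}
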