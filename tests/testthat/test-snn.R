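test_that("membrane integrates with exponential leak and fires after t_emit", {
  # one synapse with weight 1; two pre-spikes one leak constant apart leave
  # the membrane at exp(-1) + 1 when the second arrives
  net <- tiny_network(1, 1, threshold = 1.35, w = matrix(1, 1, 1))
  s <- spike_train(c(1, 1), c(1, 121))
  out <- present(net, s)$spikes
  expect_equal(nrow(out), 1)
  expect_equal(out$time, 121 + 1e-4)  # fires t_emit after crossing

  # threshold just above exp(-1) + 1: no spike
  net$config$threshold <- 1.38
  expect_equal(nrow(present(net, s)$spikes), 0)
})

test_that("a firing neuron blocks the others' integration for t_inhibit", {
  w <- matrix(c(2, 0,
                0, 2), 2, 2, byrow = TRUE)  # input i drives output i only
  net <- tiny_network(2, 2, threshold = 1.5, w = w)
  # output 1 fires at ~10; input 2 arrives 5 us later, inside t_inhibit = 10
  out <- present(net, spike_train(c(1, 2), c(10, 15)))$spikes
  expect_equal(out$neuron, 1L)
  # arriving after the inhibition window, output 2 fires too
  out <- present(net, spike_train(c(1, 2), c(10, 25)))$spikes
  expect_equal(sort(out$neuron), c(1L, 2L))
})

test_that("winner-take-all: the smaller firing delay wins a tied race", {
  # both outputs cross on the same input spike; t_emit breaks the tie and
  # the winner cancels the loser's scheduled spike
  net <- tiny_network(1, 2, threshold = 1.5, w = matrix(2, 1, 2))
  out <- present(net, spike_train(1, 5))$spikes
  expect_equal(out$neuron, 1L)
  expect_equal(out$time, 5 + 1e-4)
})

test_that("a single-neuron layer fires without lateral interactions", {
  net <- tiny_network(1, 1, threshold = 0.5, w = matrix(1, 1, 1))
  out <- present(net, spike_train(1, 3))$spikes
  expect_equal(out$neuron, 1L)
})

test_that("STDP potentiates within the window and depresses otherwise", {
  dyn <- dynamics_spec("L_HB", alpha_plus = 0.1)
  w0 <- matrix(c(0.5, 0.5, 1.0), 3, 1)
  net <- tiny_network(3, 1, threshold = 0.9, dyn = dyn, w = w0)

  # pre 1 spikes 40 us before the post spike (inside the 60 us window);
  # pre 2 never spikes; pre 3 triggers the fire itself
  res <- present(net, spike_train(c(1, 3), c(10, 50)), stdp_on = TRUE)
  expect_equal(nrow(res$spikes), 1)
  expect_equal(as.vector(res$network$weights), c(0.6, 0.4, 1.0))

  # pre 1 spikes 70 us before the post spike: outside the window
  net$weights <- w0
  res <- present(net, spike_train(c(1, 3), c(0, 70)), stdp_on = TRUE)
  expect_equal(as.vector(res$network$weights), c(0.4, 0.4, 1.0))
})

test_that("inference mode and degenerate inputs leave weights untouched", {
  net <- tiny_network(4, 3, threshold = 1, w = matrix(0.8, 4, 3))
  w0 <- net$weights

  res <- present(net, spike_train(c(1, 2, 3), c(1, 2, 3)), stdp_on = FALSE)
  expect_identical(res$network$weights, w0)

  empty <- tibble::tibble(pixel = integer(), time = numeric())
  res <- present(net, empty, stdp_on = TRUE)
  expect_equal(nrow(res$spikes), 0)
  expect_identical(res$network$weights, w0)

  net$weights <- matrix(0, 4, 3)
  res <- present(net, spike_train(rep(1:4, 10), seq(1, 40)), stdp_on = TRUE)
  expect_equal(nrow(res$spikes), 0)

  unsorted <- tibble::tibble(pixel = c(1L, 2L), time = c(5, 3))
  expect_error(present(net, unsorted), "ordered")
})

test_that("identical seeds give identical spike output end to end", {
  ds <- small_dataset()
  th <- calibrate_threshold(ds$train[1:20, ])
  net <- snn_network(784, 10, neuron_config(threshold = th),
                     stdp_rule(dynamics_spec("L_HB", alpha_plus = 0.01)),
                     seed = 4)
  img <- ds$train$image[[1]]
  o1 <- present(net, encode_image(img, seed = 9))$spikes
  o2 <- present(net, encode_image(img, seed = 9))$spikes
  expect_identical(o1, o2)
})

test_that("output spike count is non-increasing in the threshold", {
  ds <- small_dataset()
  img <- ds$train$image[[1]]
  spikes <- encode_image(img, seed = 21)
  th0 <- calibrate_threshold(list(img))
  counts <- vapply(th0 * c(0.25, 0.5, 1, 2, 4), function(th) {
    net <- snn_network(784, 10, neuron_config(threshold = th),
                       stdp_rule(dynamics_spec("L_HB", alpha_plus = 0.01)),
                       seed = 4)
    nrow(present(net, spikes)$spikes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("without lateral inhibition, identical neurons fire identically", {
  ds <- small_dataset()
  img <- ds$train$image[[1]]
  spikes <- encode_image(img, seed = 33)
  th <- calibrate_threshold(list(img))
  net <- tiny_network(784, 4, threshold = th, t_inhibit = 0,
                      w = matrix(0.8, 784, 4))
  out <- present(net, spikes)$spikes
  counts <- tabulate(out$neuron, 4)
  expect_gt(counts[1], 0)
  expect_true(all(counts == counts[1]))
})

test_that("network snapshots round-trip through JSON and CSV export works", {
  dyn <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                       n_stop_plus = 500)
  net <- snn_network(16, 3, neuron_config(threshold = 5), stdp_rule(dyn),
                     seed = 12)
  net$weights[] <- runif(48)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$weights, net$weights)
  expect_equal(back$t_emit, net$t_emit)
  expect_equal(back$rule$dynamics$w_stop_plus, 2 / 3)

  g <- withr::local_tempfile(fileext = ".csv")
  export_weights_csv(net, g)
  expect_equal(unname(as.matrix(utils::read.csv(g))), net$weights,
               tolerance = 1e-12)
})
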