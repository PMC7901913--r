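test_that("spec construction validates parameters per family", {
  sp <- dynamics_spec("L_HB", alpha_plus = 0.1)
  expect_s3_class(sp, "dynamics_spec")
  expect_null(sp$gamma_plus)
  expect_null(sp$n_stop_plus)
  expect_null(sp$w_stop_plus)

  sp <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                      n_stop_plus = 500)
  expect_equal(sp$w_stop_plus, 2 / 3)
  expect_equal(sp$w_stop_minus, 2 / 3)

  expect_error(dynamics_spec("NL_SB", alpha_plus = 1.5, gamma_plus = 3),
               "alpha_plus")
  expect_error(dynamics_spec("NL_SB", alpha_plus = 0.1, gamma_plus = 0.5),
               "gamma_plus")
  expect_error(dynamics_spec("NL_SB", alpha_plus = 0.1, gamma_plus = 3,
                             n_stop_plus = 100), "n_stop")
  expect_error(dynamics_spec("L_HB", alpha_plus = 0.1, gamma_plus = 3),
               "gamma")
  expect_error(dynamics_spec("NL_SB", alpha_plus = 0.1), "gamma")
})

test_that("w_stop matches an independent ODE integration of the soft-bound dynamics", {
  # oracle: numerically integrate dw/dn = alpha (1 - w)^gamma from w = 0
  ode_w <- function(alpha, gamma, n_stop) {
    sol <- deSolve::ode(
      y = c(w = 0), times = c(0, n_stop),
      func = function(n, y, p) list(p$a * (1 - y)^p$g),
      parms = list(a = alpha, g = gamma),
      rtol = 1e-12, atol = 1e-12
    )
    unname(sol[2, "w"])
  }
  cases <- list(c(0.008, 3, 500), c(0.002, 3, 500), c(0.004, 1, 500),
                c(0.002, 4.57, 796))
  for (cs in cases) {
    expect_equal(derive_w_stop(cs[1], cs[2], cs[3]),
                 ode_w(cs[1], cs[2], cs[3]), tolerance = 1e-8)
  }
  # frozen closed-form values
  expect_equal(derive_w_stop(0.008, 3, 500), 2 / 3)
  expect_equal(derive_w_stop(0.002, 3, 500), 1 - 3^(-1 / 2))
  # asymptotic bound
  expect_gt(derive_w_stop(0.01, 2, 1e9), 1 - 1e-4)
})

test_that("slope reproduces the boundary step heights of each family", {
  nlsb <- dynamics_spec("NL_SB", alpha_plus = 0.02, gamma_plus = 9)
  expect_equal(dyn_slope(0, nlsb, "potentiation"), 0.02)
  expect_equal(dyn_slope(1, nlsb, "potentiation"), 0)
  expect_equal(dyn_slope(1, nlsb, "depression"), -0.02)

  nlhb <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                        n_stop_plus = 500)
  # first step height is alpha / w_stop
  expect_equal(dyn_slope(0, nlhb, "potentiation"), 0.008 / (2 / 3))
  # final step is finite and positive (hard bound)
  expect_gt(dyn_slope(1, nlhb, "potentiation"), 0)

  lhb <- dynamics_spec("L_HB", alpha_plus = 0.1)
  expect_equal(dyn_slope(c(0, 0.5, 1), lhb, "potentiation"),
               rep(0.1, 3))
  expect_error(dyn_slope(1.5, lhb, "potentiation"), "\\[0, 1\\]")
})

test_that("weight_step applies one forward-Euler event with clipping", {
  lhb <- dynamics_spec("L_HB", alpha_plus = 0.1)
  expect_equal(weight_step(0.5, lhb, "potentiation"), 0.6)
  expect_equal(weight_step(0.95, lhb, "potentiation"), 1.0)
  expect_equal(weight_step(0.05, lhb, "depression"), 0)

  nlsb <- dynamics_spec("NL_SB", alpha_plus = 0.004, gamma_plus = 1)
  expect_equal(weight_step(0.8, nlsb, "depression"), 0.8 - 0.004 * 0.8)
})

test_that("trajectories match their closed forms", {
  lhb <- dynamics_spec("L_HB", alpha_plus = 0.01)
  tr <- weight_trajectory(lhb, "potentiation", 0, 100, "discrete")
  expect_equal(tr$weight[101], 1.0)
  expect_equal(tr$weight, seq(0, 1, by = 0.01))

  nlsb <- dynamics_spec("NL_SB", alpha_plus = 0.004, gamma_plus = 1)
  n <- 0:2000
  tr <- weight_trajectory(nlsb, "potentiation", 0, 2000, "continuous")
  expect_equal(tr$weight, 1 - exp(-0.004 * n), tolerance = 1e-12)

  nlhb <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                        n_stop_plus = 500)
  tr <- weight_trajectory(nlhb, "potentiation", 0, 600, "continuous")
  expect_equal(tr$weight[tr$pulse == 500], 1.0, tolerance = 1e-9)
  expect_true(all(tr$weight[tr$pulse > 500] == 1.0))

  expect_error(weight_trajectory(lhb, "potentiation", 0, 10, "odeint"))
})

test_that("weights stay in [0, 1] and pure pulse trains are monotone", {
  withr::with_seed(11, {
    for (spec in grid_specs()) {
      # random mixed event sequence from a random start
      w <- runif(1)
      for (ev in sample(c("potentiation", "depression"), 300, replace = TRUE)) {
        w <- weight_step(w, spec, ev)
        expect_gte(w, 0)
        expect_lte(w, 1)
      }
      for (dir in c("potentiation", "depression")) {
        for (mode in c("discrete", "continuous")) {
          tr <- weight_trajectory(spec, dir, w0 = if (dir == "potentiation") 0 else 1,
                                  n_pulses = 400, mode = mode)
          expect_true(all(tr$weight >= 0 & tr$weight <= 1))
          d <- diff(tr$weight)
          if (dir == "potentiation") {
            expect_true(all(d >= -1e-12))
          } else {
            expect_true(all(d <= 1e-12))
          }
        }
      }
    }
  })
})

test_that("symmetric parameters give antisymmetric potentiation/depression slopes", {
  w <- seq(0, 1, length.out = 101)
  for (spec in grid_specs()) {
    expect_equal(dyn_slope(w, spec, "depression"),
                 -dyn_slope(1 - w, spec, "potentiation"),
                 tolerance = 1e-12, info = spec$family)
  }
})

test_that("discrete Euler iterate tracks the continuous solution to O(alpha)", {
  for (spec in grid_specs()) {
    n_pulses <- if (spec$family == "NL_HB") ceiling(spec$n_stop_plus) else 600
    dd <- weight_trajectory(spec, "potentiation", 0, n_pulses, "discrete")
    cc <- weight_trajectory(spec, "potentiation", 0, n_pulses, "continuous")
    dev <- max(abs(dd$weight - cc$weight))
    expect_lte(dev, 0.02)
  }
})

test_that("hard-bound slope converges to the soft-bound slope as n_stop grows", {
  w <- seq(0, 1, length.out = 51)
  nlsb <- dynamics_spec("NL_SB", alpha_plus = 0.008, gamma_plus = 3)
  target <- dyn_slope(w, nlsb, "potentiation")
  prev_err <- Inf
  for (ns in c(1e3, 1e4, 1e5, 1e6)) {
    nlhb <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                          n_stop_plus = ns)
    err <- max(abs(dyn_slope(w, nlhb, "potentiation") - target))
    expect_lt(err, prev_err)
    prev_err <- err
  }
  expect_lt(prev_err, 1e-3)
})

test_that("specs round-trip through the flat config mapping", {
  for (spec in grid_specs()) {
    back <- as_dynamics_spec(as.list(spec))
    expect_equal(back, spec)
  }
  # derived constants are recomputed, not trusted from the mapping
  lst <- as.list(dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3,
                               n_stop_plus = 500))
  lst$w_stop_plus <- 0.123  # ignored
  expect_equal(as_dynamics_spec(lst)$w_stop_plus, 2 / 3)
})
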