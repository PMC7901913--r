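#' Synaptic weight-dynamics specification
#'
#' Constructs a validated description of one memristive weight-update family.
#' Three families are supported:
#' \describe{
#'   \item{`"L_HB"`}{linear hard-bound: a constant step `dw/dn = +/- alpha`,
#'     truncated at the weight bounds 0 and 1.}
#'   \item{`"NL_SB"`}{non-linear soft-bound: `dw/dn = alpha (1 - w)^gamma`
#'     (potentiation) or `-alpha w^gamma` (depression); the update vanishes
#'     asymptotically at the bounds, which are never reached.}
#'   \item{`"NL_HB"`}{non-linear hard-bound: the soft-bound trajectory
#'     truncated after `n_stop` pulses and rescaled to span the full
#'     \[0, 1\] range, so the bound is reached after exactly `n_stop`
#'     consecutive updates. The rescaling constant `w_stop` is derived
#'     internally (see [derive_w_stop()]).}
#' }
#' Potentiation (`_plus`) and depression (`_minus`) parameters may differ,
#' although every configuration shipped with the package is symmetric.
#'
#' @param family One of `"L_HB"`, `"NL_SB"`, `"NL_HB"`.
#' @param alpha_plus,alpha_minus Step scale in (0, 1]: the update magnitude
#'   when the weight departs from a bound (for NL_HB, the first step is
#'   `alpha / w_stop`). `alpha_minus` defaults to `alpha_plus`.
#' @param gamma_plus,gamma_minus Non-linearity exponent, >= 1. Required for
#'   `NL_SB` and `NL_HB`, disallowed for `L_HB`. `gamma_minus` defaults to
#'   `gamma_plus`.
#' @param n_stop_plus,n_stop_minus Pulse count (> 0) after which the
#'   `NL_HB` trajectory reaches its bound. Only allowed for `NL_HB`.
#'   `n_stop_minus` defaults to `n_stop_plus`.
#'
#' @return An object of class `dynamics_spec`: a list with the supplied
#'   parameters plus, for `NL_HB`, the derived `w_stop_plus`/`w_stop_minus`.
#' @examples
#' dynamics_spec("L_HB", alpha_plus = 0.1)
#' dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3, n_stop_plus = 500)
#' @export
dynamics_spec <- function(family = c("L_HB", "NL_SB", "NL_HB"),
                          alpha_plus,
                          alpha_minus = alpha_plus,
                          gamma_plus = NULL,
                          gamma_minus = gamma_plus,
                          n_stop_plus = NULL,
                          n_stop_minus = n_stop_plus) {
  family <- match.arg(family)

  check_range <- function(x, name, lo, hi, lo_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
    }
    lo_ok <- if (lo_open) x > lo else x >= lo
    if (!lo_ok || x > hi) {
      stop(sprintf("`%s` = %g is outside its allowed range (%s%g, %g]",
                   name, x, if (lo_open) "" else "[", lo, hi), call. = FALSE)
    }
  }

  check_range(alpha_plus, "alpha_plus", 0, 1)
  check_range(alpha_minus, "alpha_minus", 0, 1)

  if (family == "L_HB") {
    if (!is.null(gamma_plus) || !is.null(gamma_minus)) {
      stop("`gamma` parameters are not defined for the L_HB family", call. = FALSE)
    }
    if (!is.null(n_stop_plus) || !is.null(n_stop_minus)) {
      stop("`n_stop` parameters are not defined for the L_HB family", call. = FALSE)
    }
  } else {
    if (is.null(gamma_plus) || is.null(gamma_minus)) {
      stop(sprintf("`gamma_plus`/`gamma_minus` are required for the %s family", family),
           call. = FALSE)
    }
    check_range(gamma_plus, "gamma_plus", 1, Inf, lo_open = FALSE)
    check_range(gamma_minus, "gamma_minus", 1, Inf, lo_open = FALSE)
  }

  if (family == "NL_HB") {
    if (is.null(n_stop_plus) || is.null(n_stop_minus)) {
      stop("`n_stop_plus`/`n_stop_minus` are required for the NL_HB family", call. = FALSE)
    }
    check_range(n_stop_plus, "n_stop_plus", 0, Inf)
    check_range(n_stop_minus, "n_stop_minus", 0, Inf)
  } else if (family != "L_HB" && (!is.null(n_stop_plus) || !is.null(n_stop_minus))) {
    stop("`n_stop` parameters are only defined for the NL_HB family", call. = FALSE)
  }

  spec <- list(
    family = family,
    alpha_plus = alpha_plus, alpha_minus = alpha_minus,
    gamma_plus = gamma_plus, gamma_minus = gamma_minus,
    n_stop_plus = n_stop_plus, n_stop_minus = n_stop_minus
  )
  if (family == "NL_HB") {
    spec$w_stop_plus <- derive_w_stop(alpha_plus, gamma_plus, n_stop_plus)
    spec$w_stop_minus <- derive_w_stop(alpha_minus, gamma_minus, n_stop_minus)
  }
  structure(spec, class = "dynamics_spec")
}

#' @export
print.dynamics_spec <- function(x, ...) {
  cat("<dynamics_spec> family:", x$family, "\n")
  cat("  alpha  (+/-):", x$alpha_plus, "/", x$alpha_minus, "\n")
  if (!is.null(x$gamma_plus)) {
    cat("  gamma  (+/-):", x$gamma_plus, "/", x$gamma_minus, "\n")
  }
  if (!is.null(x$n_stop_plus)) {
    cat("  n_stop (+/-):", x$n_stop_plus, "/", x$n_stop_minus, "\n")
    cat("  w_stop (+/-):", signif(x$w_stop_plus, 6), "/",
        signif(x$w_stop_minus, 6), "\n")
  }
  invisible(x)
}

#' Soft-bound normalization constant for hard-bound truncation
#'
#' The non-linear hard-bound family is a soft-bound trajectory truncated
#' after `n_stop` pulses and rescaled to cover \[0, 1\]. The rescaling
#' constant `w_stop` is the value the continuous soft-bound trajectory,
#' started at `w = 0`, attains after `n_stop` pulses:
#' \deqn{w_{SB}(n) = 1 - [1 + \alpha(\gamma-1)n]^{-1/(\gamma-1)}}{
#'   w_SB(n) = 1 - (1 + alpha (gamma-1) n)^(-1/(gamma-1))}
#' for `gamma > 1`, and the exponential limit
#' \eqn{1 - e^{-\alpha n}}{1 - exp(-alpha n)} for `gamma = 1`.
#'
#' @param alpha Step scale in (0, 1].
#' @param gamma Non-linearity exponent >= 1.
#' @param n_stop Pulse count > 0.
#' @return `w_stop` in (0, 1).
#' @examples
#' derive_w_stop(0.008, 3, 500)  # 2/3
#' @export
derive_w_stop <- function(alpha, gamma, n_stop) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 1, n_stop > 0)
  w <- soft_bound_w(n_stop, alpha, gamma)
  if (!is.finite(w) || w <= 0 || w >= 1) {
    stop("w_stop is not strictly inside (0, 1); check alpha/gamma/n_stop",
         call. = FALSE)
  }
  w
}

# continuous soft-bound potentiation trajectory from w = 0
soft_bound_w <- function(n, alpha, gamma) {
  if (gamma == 1) {
    1 - exp(-alpha * n)
  } else {
    1 - (1 + alpha * (gamma - 1) * n)^(-1 / (gamma - 1))
  }
}

# inverse: pulses to reach w on the soft-bound trajectory from 0
soft_bound_n <- function(w, alpha, gamma) {
  if (gamma == 1) {
    -log(1 - w) / alpha
  } else {
    ((1 - w)^(-(gamma - 1)) - 1) / (alpha * (gamma - 1))
  }
}

spec_branch <- function(spec, direction) {
  if (direction == "potentiation") {
    list(alpha = spec$alpha_plus, gamma = spec$gamma_plus,
         n_stop = spec$n_stop_plus, w_stop = spec$w_stop_plus)
  } else {
    list(alpha = spec$alpha_minus, gamma = spec$gamma_minus,
         n_stop = spec$n_stop_minus, w_stop = spec$w_stop_minus)
  }
}

match_direction <- function(direction) {
  match.arg(direction, c("potentiation", "depression"))
}

#' Continuous-domain weight-change rate
#'
#' Evaluates `dw/dn` for the given weight(s), family and pulse polarity:
#' the signed rate at which the weight moves under a train of identical
#' potentiation or depression pulses.
#'
#' @param w Weight value(s) in \[0, 1\] (vectorized).
#' @param spec A [dynamics_spec()].
#' @param direction `"potentiation"` or `"depression"`.
#' @return `dw/dn`, positive for potentiation and negative for depression.
#' @examples
#' sp <- dynamics_spec("NL_SB", alpha_plus = 0.02, gamma_plus = 9)
#' dyn_slope(0, sp, "potentiation")  # first step height: alpha
#' @export
dyn_slope <- function(w, spec, direction = c("potentiation", "depression")) {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "dynamics_spec"))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("`w` must lie in [0, 1]", call. = FALSE)
  }
  b <- spec_branch(spec, direction)
  pot <- direction == "potentiation"
  switch(spec$family,
    L_HB = if (pot) rep(b$alpha, length(w)) else rep(-b$alpha, length(w)),
    NL_SB = if (pot) b$alpha * (1 - w)^b$gamma else -b$alpha * w^b$gamma,
    NL_HB = if (pot) {
      (b$alpha / b$w_stop) * (1 - w * b$w_stop)^b$gamma
    } else {
      -(b$alpha / b$w_stop) * (w * b$w_stop + 1 - b$w_stop)^b$gamma
    }
  )
}

#' One discrete STDP weight update
#'
#' Applies a single potentiation or depression event as a forward-Euler
#' step of the continuous dynamics with `dn = 1`, clipped to \[0, 1\]
#' (the rate is zero outside the bounds).
#'
#' @inheritParams dyn_slope
#' @return Updated weight(s) in \[0, 1\].
#' @examples
#' sp <- dynamics_spec("L_HB", alpha_plus = 0.1)
#' weight_step(0.95, sp, "potentiation")  # clipped at 1
#' @export
weight_step <- function(w, spec, direction = c("potentiation", "depression")) {
  direction <- match.arg(direction)
  pmin(1, pmax(0, w + dyn_slope(w, spec, direction)))
}

#' Weight trajectory under a pulse train
#'
#' Evolution of a synaptic weight under `n_pulses` identical pulses,
#' either as the discrete per-event iteration actually used during
#' learning (`mode = "discrete"`, forward-Euler with `dn = 1`) or as the
#' continuous-domain reference solution (`mode = "continuous"`), which is
#' the basis for the device figures of merit.
#'
#' The continuous solution is closed form: affine in `n` for `L_HB`;
#' the soft-bound power-law/exponential solution for `NL_SB`; the
#' truncated and rescaled soft-bound solution for `NL_HB` (pinned at the
#' bound for `n > n_stop`). All values are clipped to \[0, 1\].
#'
#' @inheritParams dyn_slope
#' @param w0 Starting weight in \[0, 1\].
#' @param n_pulses Number of pulses (>= 0).
#' @param mode `"discrete"` or `"continuous"`.
#' @return A tibble with columns `pulse` (0..n_pulses), `weight`, `mode`.
#' @examples
#' sp <- dynamics_spec("NL_SB", alpha_plus = 0.004, gamma_plus = 1)
#' weight_trajectory(sp, "potentiation", w0 = 0, n_pulses = 10)
#' @export
weight_trajectory <- function(spec, direction = c("potentiation", "depression"),
                              w0 = 0, n_pulses = 100,
                              mode = c("discrete", "continuous")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "dynamics_spec"),
            is.numeric(w0), length(w0) == 1L, w0 >= 0, w0 <= 1,
            n_pulses >= 0)
  n <- 0:n_pulses

  if (mode == "discrete") {
    w <- numeric(n_pulses + 1L)
    w[1L] <- w0
    if (n_pulses > 0) {
      for (k in seq_len(n_pulses)) {
        w[k + 1L] <- weight_step(w[k], spec, direction)
      }
    }
  } else {
    w <- continuous_w(n, spec, direction, w0)
  }

  tibble::tibble(
    pulse = n,
    weight = pmin(1, pmax(0, w)),
    mode = mode
  )
}

# closed-form continuous trajectory w(n) from w0
continuous_w <- function(n, spec, direction, w0) {
  b <- spec_branch(spec, direction)
  pot <- direction == "potentiation"
  fam <- spec$family

  if (fam == "L_HB") {
    return(w0 + (if (pot) b$alpha else -b$alpha) * n)
  }

  # map both dynamics onto the soft-bound potentiation trajectory from 0:
  # NL_SB depression of w is potentiation of (1 - w); NL_HB is the
  # soft-bound trajectory of v = w * w_stop (pot) or mirrored (dep).
  if (fam == "NL_SB") {
    x0 <- if (pot) w0 else 1 - w0
    n0 <- soft_bound_n(x0, b$alpha, b$gamma)
    x <- soft_bound_w(n0 + n, b$alpha, b$gamma)
    return(if (pot) x else 1 - x)
  }

  # NL_HB: v = w * w_stop (pot) follows dv/dn = alpha (1 - v)^gamma;
  # depression mirrors through v = (1 - w) * w_stop.
  v0 <- if (pot) w0 * b$w_stop else (1 - w0) * b$w_stop
  n0 <- soft_bound_n(v0, b$alpha, b$gamma)
  v <- soft_bound_w(n0 + n, b$alpha, b$gamma)
  w <- pmin(v / b$w_stop, 1)       # pinned at the bound beyond n_stop
  if (pot) w else 1 - w
}

#' Serialize / deserialize a dynamics spec
#'
#' `as.list()` flattens a spec to the plain key-value mapping used in
#' config files; [as_dynamics_spec()] rebuilds a validated spec from such
#' a mapping (or a one-row data frame). Derived `w_stop` values are always
#' re-computed, never trusted from the input.
#'
#' @param x A named list or one-row data frame with keys `family`,
#'   `alpha_plus`, `alpha_minus`, `gamma_plus`, `gamma_minus`,
#'   `n_stop_plus`, `n_stop_minus` (missing/NA entries are treated as
#'   absent).
#' @return A `dynamics_spec`.
#' @export
as_dynamics_spec <- function(x) {
  if (inherits(x, "dynamics_spec")) return(x)
  x <- as.list(x)
  pick <- function(key, fallback = NULL) {
    v <- x[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      if (is.null(fallback)) NULL else fallback
    } else {
      v
    }
  }
  alpha_plus <- pick("alpha_plus", pick("alpha"))
  dynamics_spec(
    family = as.character(x$family),
    alpha_plus = alpha_plus,
    alpha_minus = pick("alpha_minus", alpha_plus),
    gamma_plus = pick("gamma_plus", pick("gamma")),
    gamma_minus = pick("gamma_minus", pick("gamma_plus", pick("gamma"))),
    n_stop_plus = pick("n_stop_plus", pick("n_stop")),
    n_stop_minus = pick("n_stop_minus", pick("n_stop_plus", pick("n_stop")))
  )
}

#' @export
as.list.dynamics_spec <- function(x, ...) {
  list(
    family = x$family,
    alpha_plus = x$alpha_plus, alpha_minus = x$alpha_minus,
    gamma_plus = x$gamma_plus, gamma_minus = x$gamma_minus,
    n_stop_plus = x$n_stop_plus, n_stop_minus = x$n_stop_minus
  )
}

#' The shipped grid of investigated dynamics
#'
#' The fifteen symmetric parameterizations studied throughout the package:
#' five linear hard-bound step sizes, four soft-bound cases sharing one
#' resolution, and six hard-bound truncations of non-linear dynamics
#' (three sharing `n_stop`, three sharing the resolution).
#'
#' @return A tibble with columns `family`, `alpha`, `gamma`, `n_stop`
#'   (NA where a parameter is not defined for the family).
#' @examples
#' dynamics_grid()
#' @export
dynamics_grid <- function() {
  tibble::tribble(
    ~family, ~alpha, ~gamma, ~n_stop,
    "L_HB",  0.1,    NA,     NA,
    "L_HB",  0.02,   NA,     NA,
    "L_HB",  0.01,   NA,     NA,
    "L_HB",  0.005,  NA,     NA,
    "L_HB",  0.002,  NA,     NA,
    "NL_SB", 0.02,   9,      NA,
    "NL_SB", 0.016,  7,      NA,
    "NL_SB", 0.008,  3,      NA,
    "NL_SB", 0.004,  1,      NA,
    "NL_HB", 0.002,  3,      500,
    "NL_HB", 0.008,  3,      500,
    "NL_HB", 0.03,   3,      500,
    "NL_HB", 0.002,  1.16,   559,
    "NL_HB", 0.002,  4.57,   796,
    "NL_HB", 0.002,  9.88,   1281
  )
}
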