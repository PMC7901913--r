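#' Device resolution (effective number of weight levels)
#'
#' The resolution of a weight dynamics is defined as the inverse of the
#' integral of the squared continuous weight-change rate along the
#' trajectory from one bound to the other:
#' \deqn{\eta = \left\{\int_0^{\infty} [w'(n)]^2\, dn\right\}^{-1}}{
#'   eta = 1 / integral of w'(n)^2 dn}
#' For the linear hard-bound family this equals the pulse count `1/alpha`
#' between the bounds; for the non-linear families it generalizes the
#' notion of "number of distinguishable levels" to unevenly spaced
#' trajectories.
#'
#' Two evaluation routes are provided. `"closed_form"` uses the exact
#' expressions obtained by substituting `dn = dw / w'`:
#' `1/alpha` (L_HB), `(gamma+1)/alpha` (NL_SB), and
#' `(gamma+1)/alpha * w_stop^2 / (1 - (1-w_stop)^(gamma+1))` (NL_HB).
#' `"quadrature"` integrates the squared slope along the continuous
#' trajectory numerically (adaptive quadrature, absolute tolerance 1e-12;
#' domain `[0, Inf)` for soft bounds, `[0, n_stop]` for NL_HB, `[0, 1/alpha]`
#' for L_HB). The two routes agree to well below 1e-6 relative error.
#'
#' @param spec A [dynamics_spec()].
#' @param direction `"potentiation"` or `"depression"` (equal for the
#'   symmetric parameterizations shipped with the package).
#' @param method `"closed_form"` or `"quadrature"`.
#' @return The resolution, a positive scalar.
#' @examples
#' resolution_eta(dynamics_spec("L_HB", alpha_plus = 0.01))  # 100
#' @export
resolution_eta <- function(spec, direction = c("potentiation", "depression"),
                           method = c("closed_form", "quadrature")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  stopifnot(inherits(spec, "dynamics_spec"))
  b <- spec_branch(spec, direction)

  if (method == "closed_form") {
    eta <- switch(spec$family,
      L_HB = 1 / b$alpha,
      NL_SB = (b$gamma + 1) / b$alpha,
      NL_HB = {
        u <- 1 - b$w_stop
        (b$gamma + 1) / b$alpha * b$w_stop^2 / (1 - u^(b$gamma + 1))
      }
    )
    return(eta)
  }

  # quadrature along the continuous trajectory from the starting bound
  w0 <- if (direction == "potentiation") 0 else 1
  sq_slope <- function(n) {
    w <- pmin(1, pmax(0, continuous_w(n, spec, direction, w0)))
    dyn_slope(w, spec, direction)^2
  }
  upper <- switch(spec$family,
    L_HB = 1 / b$alpha,
    NL_SB = Inf,
    NL_HB = b$n_stop
  )
  val <- stats::integrate(sq_slope, 0, upper, abs.tol = 1e-12,
                          rel.tol = 1e-10, subdivisions = 2000L)$value
  if (!is.finite(val) || val <= 0) {
    stop("squared-slope integral is not finite and positive", call. = FALSE)
  }
  1 / val
}

#' Device non-linearity (average trajectory curvature)
#'
#' The non-linearity of a weight dynamics is the average curvature of the
#' continuous weight-versus-pulse-number trajectory `w(n)`:
#' \deqn{\lambda = \frac{4}{\pi}\int_0^{\infty}
#'   \frac{|w''(n)|}{\{1 + [w'(n)]^2\}^{3/2}}\, dn}{
#'   lambda = (4/pi) * integral of |w''| / (1 + w'^2)^(3/2) dn}
#' A linear trajectory has `lambda = 0` exactly.
#'
#' `"closed_form"` exploits that the slope `p = w'(n)` decreases
#' monotonically along the trajectory, so the integrand is an exact
#' differential of `p / sqrt(1 + p^2)`:
#' `lambda = (4/pi) * (s0/sqrt(1+s0^2) - sN/sqrt(1+sN^2))`
#' with initial slope `s0` (`alpha` for NL_SB, `alpha/w_stop` for NL_HB)
#' and final slope `sN` (0 for NL_SB, `(alpha/w_stop) (1-w_stop)^gamma`
#' for NL_HB). Note that for NL_SB the value depends on `alpha` only.
#' `"quadrature"` integrates the curvature expression numerically with
#' analytic first and second derivatives of the closed-form trajectory.
#'
#' @inheritParams resolution_eta
#' @return The non-linearity, a non-negative scalar (0 for L_HB).
#' @examples
#' nonlinearity_lambda(dynamics_spec("NL_SB", alpha_plus = 0.016, gamma_plus = 7))
#' @export
nonlinearity_lambda <- function(spec, direction = c("potentiation", "depression"),
                                method = c("closed_form", "quadrature")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  stopifnot(inherits(spec, "dynamics_spec"))
  if (spec$family == "L_HB") return(0)
  b <- spec_branch(spec, direction)

  proj <- function(p) p / sqrt(1 + p^2)

  if (method == "closed_form") {
    if (spec$family == "NL_SB") {
      s0 <- b$alpha
      sN <- 0
    } else {
      s0 <- b$alpha / b$w_stop
      sN <- (b$alpha / b$w_stop) * (1 - b$w_stop)^b$gamma
    }
    return((4 / pi) * (proj(s0) - proj(sN)))
  }

  w0 <- if (direction == "potentiation") 0 else 1
  # |w''| = |f'(w)| * |f(w)| with f the slope function; the slope magnitude
  # decreases along the trajectory for both non-linear families.
  curvature <- function(n) {
    w <- pmin(1, pmax(0, continuous_w(n, spec, direction, w0)))
    p <- dyn_slope(w, spec, direction)
    dfdw <- if (spec$family == "NL_SB") {
      if (direction == "potentiation") {
        -b$alpha * b$gamma * (1 - w)^(b$gamma - 1)
      } else {
        -b$alpha * b$gamma * w^(b$gamma - 1)
      }
    } else {
      ws <- b$w_stop
      if (direction == "potentiation") {
        -b$alpha * b$gamma * (1 - w * ws)^(b$gamma - 1)
      } else {
        -b$alpha * b$gamma * (w * ws + 1 - ws)^(b$gamma - 1)
      }
    }
    abs(dfdw * p) / (1 + p^2)^1.5
  }
  upper <- if (spec$family == "NL_SB") Inf else b$n_stop
  val <- stats::integrate(curvature, 0, upper, abs.tol = 1e-12,
                          rel.tol = 1e-10, subdivisions = 2000L)$value
  (4 / pi) * val
}

#' Figures of merit for a table of dynamics parameterizations
#'
#' Computes resolution and non-linearity for each row of a parameter
#' table, mirroring the package's reference grid layout.
#'
#' @param dynamics A tibble/data frame with columns `family`, `alpha`,
#'   `gamma`, `n_stop` (NA where absent), e.g. [dynamics_grid()], or a
#'   list of [dynamics_spec()] objects.
#' @param method Passed to [resolution_eta()] and [nonlinearity_lambda()].
#' @param round If `TRUE`, round `eta` to the nearest integer and
#'   `lambda` to three decimals (the conventional reporting precision);
#'   raw values otherwise.
#' @return The input parameter table with `eta` and `lambda` columns
#'   appended.
#' @examples
#' device_metrics(dynamics_grid(), round = TRUE)
#' @export
device_metrics <- function(dynamics = dynamics_grid(),
                           method = c("closed_form", "quadrature"),
                           round = FALSE) {
  method <- match.arg(method)
  if (is.data.frame(dynamics)) {
    specs <- purrr::pmap(dynamics, function(family, alpha, gamma = NA,
                                            n_stop = NA, ...) {
      as_dynamics_spec(list(family = family, alpha = alpha,
                            gamma = gamma, n_stop = n_stop))
    })
    out <- tibble::as_tibble(dynamics)
  } else {
    specs <- lapply(dynamics, as_dynamics_spec)
    out <- tibble::tibble(
      family = purrr::map_chr(specs, "family"),
      alpha = purrr::map_dbl(specs, "alpha_plus"),
      gamma = purrr::map_dbl(specs, ~ .x$gamma_plus %||% NA_real_),
      n_stop = purrr::map_dbl(specs, ~ .x$n_stop_plus %||% NA_real_)
    )
  }
  out$eta <- purrr::map_dbl(specs, resolution_eta, method = method)
  out$lambda <- purrr::map_dbl(specs, nonlinearity_lambda, method = method)
  if (round) {
    out$eta <- round(out$eta)
    out$lambda <- round(out$lambda, 3)
  }
  out
}
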