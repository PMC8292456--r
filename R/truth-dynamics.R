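#' Ground-truth marker dynamics
#'
#' Describes the closed-form dynamic used to simulate one marker in a
#' synthetic cohort. Three families are available:
#'
#' * `exponential_approach`: `dX/dt = -k (X - P)`, so
#'   `X(t) = P + (X0 - P) exp(-k t)` approaches the plateau `P`
#'   monotonically. This emulates markers that decline (or rise) toward a
#'   plateau, such as CSF amyloid-beta 1-42 and alpha-synuclein.
#' * `logistic`: `dX/dt = k X (1 - X/K)`, sigmoid growth toward the
#'   carrying capacity `K`, emulating markers with a sigmoid rise such as
#'   serum neurofilament light chain.
#' * `constant`: `dX/dt = 0`, a steady level, the default for controls.
#'
#' @param family One of `"exponential_approach"`, `"logistic"`,
#'   `"constant"`.
#' @param x0 Level at motor onset (marker units). For controls the onset
#'   axis is read as time from baseline.
#' @param k Rate constant (1/year), must be >= 0. Ignored by `constant`.
#' @param plateau Plateau `P` (marker units), required for
#'   `exponential_approach`.
#' @param capacity Carrying capacity `K` (marker units, > 0), required
#'   for `logistic`.
#' @return An object of class `truth_dynamics`.
#' @seealso [true_level()], [true_rate()], [true_trajectory()]
#' @examples
#' dyn <- truth_dynamics("exponential_approach", x0 = 1000, k = 0.1,
#'                       plateau = 600)
#' true_level(dyn, c(0, 10))
#' @export
truth_dynamics <- function(family = c("exponential_approach", "logistic", "constant"),
                           x0, k = 0, plateau = NA_real_, capacity = NA_real_) {
  family <- match.arg(family)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("'x0' must be a single finite number")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("rate constant 'k' must be a single number >= 0")
  if (family == "exponential_approach" && !is.finite(plateau))
    stop("'exponential_approach' requires a finite 'plateau'")
  if (family == "logistic") {
    if (!is.finite(capacity) || capacity <= 0)
      stop("'logistic' requires a positive 'capacity'")
    if (x0 <= 0)
      stop("'logistic' requires a positive onset level 'x0'")
  }
  structure(
    list(family = family, x0 = x0, k = k, plateau = plateau,
         capacity = capacity),
    class = "truth_dynamics"
  )
}

#' Evaluate the closed-form truth level
#'
#' @param dynamics A [truth_dynamics()] object.
#' @param t Numeric vector of times (years from onset).
#' @return Numeric vector of marker levels.
#' @export
true_level <- function(dynamics, t) {
  stopifnot(inherits(dynamics, "truth_dynamics"))
  with(dynamics, switch(
    family,
    exponential_approach = plateau + (x0 - plateau) * exp(-k * t),
    logistic = capacity * x0 / (x0 + (capacity - x0) * exp(-k * t)),
    constant = rep(x0, length(t)),
    stop("unknown dynamics family: ", family)
  ))
}

#' Evaluate the truth rate dX/dt at a level
#'
#' @param dynamics A [truth_dynamics()] object.
#' @param x Numeric vector of marker levels.
#' @return Numeric vector of instantaneous annual change rates.
#' @export
true_rate <- function(dynamics, x) {
  stopifnot(inherits(dynamics, "truth_dynamics"))
  with(dynamics, switch(
    family,
    exponential_approach = -k * (x - plateau),
    logistic = k * x * (1 - x / capacity),
    constant = rep(0, length(x)),
    stop("unknown dynamics family: ", family)
  ))
}

#' Exact truth trajectory on a time grid
#'
#' Closed-form evaluation of a [truth_dynamics()] object over a grid in
#' years from motor onset; the oracle that recovery tests compare
#' estimated trajectories against.
#'
#' @param dynamics A [truth_dynamics()] object.
#' @param grid Numeric vector of times within the estimation window
#'   \[-5, 30\] years.
#' @return A data.frame with columns `time` and `level`, classed as a
#'   `biotraj_trajectory`.
#' @export
true_trajectory <- function(dynamics, grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (any(grid < -5 - 1e-9) || any(grid > 30 + 1e-9))
    stop("trajectory grid must lie within [-5, 30] years from onset")
  out <- data.frame(time = grid, level = true_level(dynamics, grid))
  structure(out,
            class = c("biotraj_trajectory", "data.frame"),
            marker = NA_character_, stratum = "truth",
            anchor = list(time = 0, level = dynamics$x0),
            h = NA_real_, method = "closed_form",
            diagnostics = list())
}

#' @export
print.truth_dynamics <- function(x, ...) {
  cat("<truth_dynamics>", x$family, "\n")
  cat("  x0 =", x$x0, " k =", x$k)
  if (x$family == "exponential_approach") cat("  plateau =", x$plateau)
  if (x$family == "logistic") cat("  capacity =", x$capacity)
  cat("\n")
  invisible(x)
}
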