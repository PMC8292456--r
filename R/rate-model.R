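# Rate-versus-level model: restricted cubic spline regression of annual
# change rate on baseline level. The fitted curve is the right-hand side
# f(X) of the autonomous ODE dX/dt = f(X).

#' Place restricted-cubic-spline knots at baseline-level percentiles
#'
#' Four knots at the 5/35/65/95th percentiles of the baseline levels
#' when the sample size is at least 100; three knots at the 5/50/95th
#' percentiles when it is under 100. Percentiles use linear
#' interpolation between order statistics by default
#' (`quantile_type = 7`). If the 4-knot placement yields coincident
#' knots (heavy ties) the 3-knot rule is tried; if that is still
#' degenerate an error is raised.
#'
#' @param x Numeric vector of baseline levels (>= 10 distinct values).
#' @param n_subjects Sample size driving the 4-vs-3 knot rule
#'   (default `length(x)`).
#' @param quantile_type Quantile convention (see [stats::quantile()]).
#' @return Sorted numeric vector of 3 or 4 knots.
#' @export
place_knots <- function(x, n_subjects = length(x), quantile_type = 7L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 10L)
    stop("need at least 10 distinct baseline levels to place knots")
  probs4 <- c(0.05, 0.35, 0.65, 0.95)
  probs3 <- c(0.05, 0.50, 0.95)
  probs <- if (n_subjects >= 100L) probs4 else probs3
  k <- quantile(x, probs, type = quantile_type, names = FALSE)
  if (anyDuplicated(k) && identical(probs, probs4)) {
    k <- quantile(x, probs3, type = quantile_type, names = FALSE)
  }
  if (anyDuplicated(k))
    stop_biotraj("degenerate_knots: coincident knot locations",
                 "biotraj_degenerate_knots")
  unname(k)
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural-spline basis with K knots: `b1(x) = x` and,
#' for `j = 1..K-2`,
#' `b_{j+1}(x) = (x-t_j)+^3 - (x-t_{K-1})+^3 (t_K-t_j)/(t_K-t_{K-1})
#'  + (x-t_K)+^3 (t_{K-1}-t_j)/(t_K-t_{K-1})`.
#' Every basis function has a continuous second derivative and is
#' exactly linear outside `[t_1, t_K]` (and the nonlinear terms vanish
#' below `t_1`). With `scale = TRUE` the nonlinear columns are divided
#' by `(t_K - t_1)^2` for numerical conditioning; the column span, and
#' hence any least-squares fit, is unchanged.
#'
#' @param x Numeric vector of levels.
#' @param knots Strictly increasing knot vector (length >= 3).
#' @param scale Divide nonlinear columns by `(t_K - t_1)^2`.
#' @return Matrix with `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots, scale = TRUE) {
  K <- length(knots)
  if (K < 3L || is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be strictly increasing with at least 3 entries")
  p3 <- function(u) pmax(u, 0)^3
  tK <- knots[K]; tK1 <- knots[K - 1L]
  denom <- tK - tK1
  B <- matrix(0, length(x), K - 1L)
  B[, 1L] <- x
  for (j in seq_len(K - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- p3(x - tj) -
      p3(x - tK1) * (tK - tj) / denom +
      p3(x - tK)  * (tK1 - tj) / denom
  }
  if (scale)
    B[, -1L] <- B[, -1L, drop = FALSE] / (knots[K] - knots[1L])^2
  colnames(B) <- c("level", paste0("nl", seq_len(K - 2L)))
  B
}

#' Fit the population rate-versus-level model
#'
#' Ordinary least squares of per-subject annual change rate on an
#' intercept plus the restricted cubic spline basis of baseline level.
#' Deterministic; the design must be full rank.
#'
#' @param baseline_level Numeric vector of baseline levels.
#' @param rate Numeric vector of annual change rates (units/year).
#' @param knots Knot vector; placed by [place_knots()] when `NULL`.
#' @param n_subjects Sample size driving the knot rule.
#' @param quantile_type Quantile convention for knot placement.
#' @param scale_basis Conditioning scale for the nonlinear columns (does
#'   not change fitted values).
#' @param marker,stratum Optional labels stored in the model.
#' @return An object of class `rate_model`: knots, coefficients,
#'   `fit_range` (range of observed baseline levels), `n`, residual SD.
#' @export
fit_rate_model <- function(baseline_level, rate, knots = NULL,
                           n_subjects = NULL, quantile_type = 7L,
                           scale_basis = TRUE,
                           marker = NA_character_,
                           stratum = NA_character_) {
  ok <- is.finite(baseline_level) & is.finite(rate)
  x <- baseline_level[ok]; y <- rate[ok]
  n <- length(x)
  if (is.null(n_subjects)) n_subjects <- n
  if (is.null(knots))
    knots <- place_knots(x, n_subjects, quantile_type)
  if (n < length(knots) + 1L)
    stop("need at least K+1 subjects to fit a K-knot rate model")
  X <- cbind(`(Intercept)` = 1, rcs_basis(x, knots, scale_basis))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop(sprintf(
      "rank-deficient rate-model design (rank %d < %d columns, condition number %.3g)",
      qrX$rank, ncol(X), kappa(X)))
  }
  coef <- qr.coef(qrX, y)
  resid <- y - drop(X %*% coef)
  structure(
    list(marker = marker, stratum = stratum, knots = knots,
         coefficients = coef, scale_basis = isTRUE(scale_basis),
         fit_range = range(x), n = n,
         sigma = if (n > ncol(X)) sqrt(sum(resid^2) / (n - ncol(X))) else NA_real_),
    class = "rate_model"
  )
}

#' Evaluate a fitted rate model
#'
#' `f(x) = b0 + sum_j b_j B_j(x)`. Outside the boundary knots the
#' natural-spline linear tails apply; the extrapolation corridor used
#' during integration is handled by [integrate_trajectory()].
#'
#' @param model A `rate_model`.
#' @param x Numeric vector of levels.
#' @return Numeric vector of annual change rates (units/year).
#' @export
evaluate_rate <- function(model, x) {
  stopifnot(inherits(model, "rate_model"))
  B <- cbind(1, rcs_basis(x, model$knots, model$scale_basis))
  drop(B %*% model$coefficients)
}

#' @export
predict.rate_model <- function(object, newdata, ...) {
  evaluate_rate(object, newdata)
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model>", x$marker, "/", x$stratum, "\n")
  cat("  knots:", paste(signif(x$knots, 6), collapse = ", "), "\n")
  cat("  fit range: [", signif(x$fit_range[1], 6), ",",
      signif(x$fit_range[2], 6), "]  n =", x$n, "\n")
  invisible(x)
}

#' Roots of the fitted rate curve
#'
#' Locates every level inside the fitting range where the fitted annual
#' change is zero: these are the equilibria of `dX/dt = f(X)`. Sign
#' changes on a dense grid are refined by bisection until `|f| < tol`;
#' each root is labelled `stable` (f' < 0, a trajectory plateau) or
#' `unstable` (f' > 0).
#'
#' @param model A `rate_model`.
#' @param n_grid Grid resolution across the search interval.
#' @param tol Target |f| at the refined root.
#' @param interval Search interval; defaults to the fitting range.
#'   Because the spline tails are exactly linear, widening the interval
#'   (e.g. to the integrator's extrapolation corridor) adds at most one
#'   well-defined root per tail.
#' @return Data.frame `level`, `stability`; zero rows when the curve
#'   does not change sign.
#' @export
rate_roots <- function(model, n_grid = 2001L, tol = 1e-9,
                       interval = model$fit_range) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  fr <- interval
  g <- seq(fr[1], fr[2], length.out = n_grid)
  fv <- evaluate_rate(model, g)
  f1 <- function(x) evaluate_rate(model, x)
  roots <- numeric()
  exact <- which(fv == 0)
  roots <- c(roots, g[exact])
  chg <- which(fv[-n_grid] * fv[-1] < 0)
  for (i in chg) {
    lo <- g[i]; hi <- g[i + 1]
    flo <- fv[i]
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f1(mid)
      if (abs(fm) < tol || (hi - lo) < .Machine$double.eps * max(abs(fr)))
        break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, mid)
  }
  if (!length(roots))
    return(data.frame(level = numeric(), stability = character(),
                      stringsAsFactors = FALSE))
  roots <- sort(roots)
  # merge near-duplicates (grid hit + refined neighbour)
  keep <- c(TRUE, diff(roots) > diff(fr) / n_grid)
  roots <- roots[keep]
  d <- diff(fr) * 1e-6
  fp <- (f1(roots + d) - f1(roots - d)) / (2 * d)
  data.frame(level = roots,
             stability = ifelse(fp < 0, "stable",
                                ifelse(fp > 0, "unstable", "neutral")),
             stringsAsFactors = FALSE)
}
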