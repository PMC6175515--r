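#' Parameters of the flush-distance risk model
#'
#' The model describes the risk that a ground-nesting bird's departure
#' ("flush") from its nest reveals the nest to an approaching predator. It has
#' two components, both functions of the bird's threshold flush distance
#' \eqn{d}:
#' \itemize{
#'   \item \emph{detection probability}: the chance that a predator that
#'     witnesses the flush locates the nest. It is 1 at or below
#'     \code{f_close} (a flush at very close range pinpoints the nest), 0 at or
#'     beyond \code{f_long} (a distant flush carries no information), and
#'     declines monotonically in between following \code{detection_shape}.
#'   \item \emph{flush probability}: the chance the bird flushes at all, given
#'     a predator somewhere within \code{r_ref} metres of the nest. A bird
#'     flushes when the predator enters the circle of radius \eqn{d}, so this
#'     probability grows with the area of that circle: \eqn{(d/r_{ref})^2},
#'     capped at 1.
#' }
#' The risk of nest detection attributable to the flush is the product of the
#' two, which is maximised at intermediate flush distances.
#'
#' @param f_close Distance (m) at or below which a flush guarantees nest
#'   detection. Default 5 m.
#' @param f_long Distance (m) at or beyond which a flush carries no detection
#'   risk. Default 100 m.
#' @param r_ref Reference radius (m): the flush probability is conditioned on a
#'   predator being somewhere within this distance of the nest. Default 125 m.
#' @param detection_shape Shape of the detection decline between \code{f_close}
#'   and \code{f_long}: \code{"linear"} (default), \code{"smoothstep"} (cubic
#'   easing), or \code{"logistic"} (logistic in distance, rescaled to hit 1 and
#'   0 exactly at the endpoints).
#'
#' @return An object of class \code{"risk_params"}.
#' @examples
#' p <- risk_params()
#' detection_probability(c(5, 52.5, 100), p)
#' argmax_risk(p)
#' @export
risk_params <- function(f_close = 5, f_long = 100, r_ref = 125,
                        detection_shape = c("linear", "smoothstep", "logistic")) {
  detection_shape <- match.arg(detection_shape)
  stopifnot(is.numeric(f_close), length(f_close) == 1L, is.finite(f_close),
            is.numeric(f_long), length(f_long) == 1L, is.finite(f_long),
            is.numeric(r_ref), length(r_ref) == 1L, is.finite(r_ref))
  if (!(0 < f_close && f_close < f_long && f_long <= r_ref))
    stop("need 0 < f_close < f_long <= r_ref")
  structure(list(f_close = f_close, f_long = f_long, r_ref = r_ref,
                 detection_shape = detection_shape),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat("Flush-distance risk model parameters\n")
  cat(sprintf("  f_close: %g m   f_long: %g m   r_ref: %g m\n",
              x$f_close, x$f_long, x$r_ref))
  cat(sprintf("  detection decline: %s\n", x$detection_shape))
  invisible(x)
}

as_risk_params <- function(params) {
  if (inherits(params, "risk_params")) return(params)
  stop("'params' must be a risk_params object")
}

#' Probability that a flush at distance d reveals the nest
#'
#' Equals 1 for \code{d <= f_close}, 0 for \code{d >= f_long}, and declines
#' strictly and continuously in between according to the chosen shape.
#'
#' @param d Flush distance(s) in metres, non-negative.
#' @param params A [risk_params()] object.
#' @return Probabilities in \eqn{[0, 1]}, same length as \code{d}.
#' @export
detection_probability <- function(d, params = risk_params()) {
  params <- as_risk_params(params)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("'d' must be finite and >= 0")
  s <- (d - params$f_close) / (params$f_long - params$f_close)
  s <- pmin(pmax(s, 0), 1)
  p <- switch(params$detection_shape,
    linear = 1 - s,
    smoothstep = 1 - s^2 * (3 - 2 * s),
    logistic = {
      k <- 10 / (params$f_long - params$f_close)
      mid <- (params$f_close + params$f_long) / 2
      fl <- function(t) stats::plogis(-k * (t - mid))
      dd <- pmin(pmax(d, params$f_close), params$f_long)
      (fl(dd) - fl(params$f_long)) / (fl(params$f_close) - fl(params$f_long))
    })
  unname(p)
}

#' Probability that a bird with flush threshold r is flushed
#'
#' Given a predator somewhere within \code{r_ref} of the nest, the bird
#' flushes when the predator enters its threshold circle, so the probability
#' scales with the circle's area: \eqn{(r/r_{ref})^2}, capped at 1.
#'
#' @param r Threshold flush distance(s) in metres, non-negative.
#' @inheritParams detection_probability
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
flush_probability <- function(r, params = risk_params()) {
  params <- as_risk_params(params)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and >= 0")
  unname(pmin((r / params$r_ref)^2, 1))
}

#' Risk of nest detection attributable to flushing
#'
#' The product of [detection_probability()] and [flush_probability()] at the
#' same threshold distance.
#'
#' @inheritParams detection_probability
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
flush_risk <- function(d, params = risk_params()) {
  detection_probability(d, params) * flush_probability(d, params)
}

#' Tabulate the risk model on a distance grid
#'
#' @inheritParams detection_probability
#' @param grid_step Grid spacing in metres (> 0).
#' @return A data frame of class \code{"risk_curve"} with columns
#'   \code{distance}, \code{p_detect}, \code{p_flush}, \code{risk}, evaluated
#'   on \code{seq(0, r_ref, by = grid_step)} (the endpoint \code{r_ref} is
#'   always included). The parameters are attached as attribute
#'   \code{"params"}.
#' @export
risk_curve <- function(params = risk_params(), grid_step = 1) {
  params <- as_risk_params(params)
  stopifnot(is.numeric(grid_step), length(grid_step) == 1L, grid_step > 0)
  d <- seq(0, params$r_ref, by = grid_step)
  if (d[length(d)] < params$r_ref) d <- c(d, params$r_ref)
  out <- data.frame(distance = d,
                    p_detect = detection_probability(d, params),
                    p_flush = flush_probability(d, params),
                    risk = flush_risk(d, params))
  attr(out, "params") <- params
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Flush distance of maximum risk
#'
#' Locates the flush distance maximising [flush_risk()] by a deterministic
#' fine-grid search over \eqn{[0, r_{ref}]} followed by golden-section
#' refinement. For the linear detection shape the maximum has the closed form
#' \eqn{2 f_{long} / 3} whenever \eqn{f_{close} \le 2 f_{long} / 3}.
#'
#' @inheritParams detection_probability
#' @param tolerance Location tolerance in metres (> 0). Default 0.01 m.
#' @return The maximising distance in metres.
#' @export
argmax_risk <- function(params = risk_params(), tolerance = 0.01) {
  params <- as_risk_params(params)
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L, tolerance > 0)
  grid <- seq(0, params$r_ref, length.out = 2048L)
  i <- which.max(flush_risk(grid, params))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  # golden-section refinement on the bracketing interval
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - phi * (b - a); d_ <- a + phi * (b - a)
  fc <- flush_risk(c_, params); fd <- flush_risk(d_, params)
  while (b - a > tolerance / 2) {
    if (fc >= fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - phi * (b - a); fc <- flush_risk(c_, params)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + phi * (b - a); fd <- flush_risk(d_, params)
    }
  }
  (a + b) / 2
}

#' Interval of distances with near-maximal risk
#'
#' Returns the connected interval around the risk maximum on which
#' \code{flush_risk >= fraction * max(flush_risk)}. For the linear detection
#' shape the risk restricted to \eqn{[f_{close}, f_{long}]} is unimodal, so
#' this set is a single interval.
#'
#' @inheritParams detection_probability
#' @param fraction Proportion of the maximum risk, in \eqn{(0, 1]}.
#' @param resolution Scan resolution in metres. Default 0.01 m.
#' @return Numeric vector \code{c(lower, upper)} in metres.
#' @export
high_risk_band <- function(params = risk_params(), fraction = 0.5,
                           resolution = 0.01) {
  params <- as_risk_params(params)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      !(fraction > 0 && fraction <= 1))
    stop("'fraction' must be in (0, 1]")
  dstar <- argmax_risk(params, tolerance = resolution)
  target <- fraction * flush_risk(dstar, params)
  d <- seq(0, params$r_ref, by = resolution)
  ok <- flush_risk(d, params) >= target - 1e-12
  # connected run containing the argmax
  i0 <- which.min(abs(d - dstar))
  lo <- i0; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(d) && ok[hi + 1L]) hi <- hi + 1L
  c(lower = d[lo], upper = d[hi])
}
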