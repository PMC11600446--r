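#' Saturating sigmoid relationship
#'
#' The four-parameter logistic curve used throughout the cardiorenal model to
#' express saturating physiological couplings (hormone secretion, vascular
#' tone, tubular feedback).  An increasing curve is
#' \deqn{y = b + A / (1 + e^{-(x - m)/s})}
#' and a decreasing curve negates the exponent argument.  Output is bounded
#' between \code{b} and \code{b + A} for all finite inputs and is strictly
#' monotone in \code{x}.
#'
#' Most model sigmoids are written in "multiplier" form: the midpoint \code{m}
#' sits at the normal operating point of the input, and \code{b + A/2 = 1}, so
#' the curve evaluates to exactly 1 there.
#'
#' @param A amplitude (output units); total span of the curve.
#' @param b baseline offset (output units); lower asymptote.
#' @param m midpoint (input units); input at which output is \code{b + A/2}.
#' @param s slope scale (input units); must be strictly positive.  Local slope
#'   at the midpoint is \code{A/(4 s)} (sign per \code{direction}).
#' @param direction \code{"increasing"} or \code{"decreasing"}.
#' @return An object of class \code{"sigmoid"}.
#' @examples
#' f <- sigmoid(A = 2, b = 0, m = 0, s = 1)
#' eval_sigmoid(f, 0)   # midpoint: b + A/2 = 1
#' eval_sigmoid(f, 1)   # 2 / (1 + exp(-1))
#' @export
sigmoid <- function(A, b, m, s, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.finite(s) || s <= 0) {
    stop("sigmoid slope scale 's' must be strictly positive", call. = FALSE)
  }
  structure(list(A = A, b = b, m = m, s = s, direction = direction),
            class = "sigmoid")
}

#' Evaluate a sigmoid relationship
#'
#' @param f a \code{\link{sigmoid}} object.
#' @param x numeric vector of input values.
#' @return numeric vector of outputs, bounded in \code{[b, b + A]}.
#' @export
eval_sigmoid <- function(f, x) {
  stopifnot(inherits(f, "sigmoid"))
  sig_eval(x, f$A, f$b, f$m, f$s, decreasing = f$direction == "decreasing")
}

# Bare numeric kernel used by the vectorised engine (parameters may be
# per-patient vectors).
sig_eval <- function(x, A, b, m, s, decreasing = FALSE) {
  z <- (x - m) / s
  if (decreasing) z <- -z
  b + A / (1 + exp(-z))
}

#' @export
print.sigmoid <- function(x, ...) {
  cat(sprintf("sigmoid (%s): y = %g + %g / (1 + exp(%s(x - %g)/%g))\n",
              x$direction, x$b, x$A,
              if (x$direction == "increasing") "-" else "+", x$m, x$s))
  invisible(x)
}
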