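# Attractor taxonomy from an ordered Lyapunov spectrum: topological
# dimension, Kaplan-Yorke dimension and the four-dimensional-chaos test
# (a single positive exponent with lambda_1 > |lambda_3|, which forces
# topological dimension 3 and Kaplan-Yorke dimension > 3).

checkSorted <- function(lambdas, tol = 1e-9) {
  if (length(lambdas) < 1) stop("empty Lyapunov spectrum")
  if (any(!is.finite(lambdas))) stop("non-finite Lyapunov exponent(s)")
  if (any(diff(lambdas) > tol))
    stop("exponents must be sorted in descending order")
  lambdas
}

#' Topological dimension of an attractor
#'
#' The largest integer D for which the partial sum
#' \eqn{\lambda_1 + \cdots + \lambda_D \ge 0} of the ordered Lyapunov
#' exponents is non-negative.  D + 1 is the minimum integer dimension in
#' which the attractor can exist.  Returns 0 when \eqn{\lambda_1 < 0}
#' (point attractor convention).
#'
#' @param lambdas Lyapunov exponents (1/s), sorted descending
#' @return integer D >= 0
#' @examples
#' topologicalDimension(c(9.6, 0, -6.4, -11.5))  # 3
#' @export
topologicalDimension <- function(lambdas) {
  checkSorted(lambdas)
  cs <- cumsum(lambdas)
  if (all(cs < 0)) return(0L)
  max(which(cs >= 0))
}

#' Kaplan-Yorke (Lyapunov) dimension
#'
#' \deqn{D_{KY} = D + \frac{\lambda_1 + \cdots + \lambda_D}{|\lambda_{D+1}|}}
#' with D the topological dimension.  For D = 3 this reduces to
#' \eqn{3 - (\lambda_1+\lambda_2+\lambda_3)/\lambda_4}.  Returns 0 for a
#' point attractor (D = 0) and `NA` with an attribute
#' `undefined = TRUE` when every supplied partial sum is non-negative
#' (no converged dissipation: \eqn{\lambda_{D+1}} is not available).
#'
#' @param lambdas Lyapunov exponents (1/s), sorted descending; at least
#'   D + 1 values must be supplied for a finite answer
#' @return real dimension >= 0, or `NA`
#' @examples
#' kaplanYorke(c(9.6, 0, -6.4, -11.5))  # 3 - 3.2 / (-11.5)
#' @export
kaplanYorke <- function(lambdas) {
  checkSorted(lambdas)
  D <- topologicalDimension(lambdas)
  if (D == 0L) return(0)
  if (D >= length(lambdas)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cs <- cumsum(lambdas)
  D + cs[D] / abs(lambdas[D + 1])
}

#' Classify an attractor from its leading Lyapunov exponents
#'
#' Labels:
#' \describe{
#'   \item{point}{\eqn{\lambda_1 < -}`zeroTol`: contraction in every
#'     direction.}
#'   \item{periodic}{\eqn{\lambda_1} within `zeroTol` of zero, or below
#'     `chaosThreshold` (slowly converging near-zero exponents are
#'     treated as periodic; the raw exponents are retained so relabeling
#'     is lossless).}
#'   \item{chaotic}{\eqn{\lambda_1 \ge} `chaosThreshold`.}
#'   \item{chaotic_4d}{chaotic with \eqn{|\lambda_2| \le} `zeroTol` and
#'     \eqn{\lambda_1 > |\lambda_3|}: the attractor has topological
#'     dimension at least 3 and Kaplan-Yorke dimension above 3, i.e.
#'     four-dimensional chaos with a single positive exponent.}
#' }
#' `hyperchaosFlag` is set (diagnostic only) when a second exponent
#' exceeds `zeroTol`, which is hyperchaos rather than four-dimensional
#' chaos.
#'
#' @param lambdas Lyapunov exponents (1/s), sorted descending; at least
#'   3 are required for any chaotic verdict
#' @param chaosThreshold positive rate (1/s) above which \eqn{\lambda_1}
#'   counts as chaotic (default 1/s, which sidesteps exponents that
#'   converge slowly to zero on periodic orbits)
#' @param zeroTol tolerance (1/s) for treating an exponent as zero
#' @return an object of class `"attractorClass"`: list with `label`,
#'   `D`, `D_KY`, `hyperchaosFlag`, the thresholds used and the input
#'   spectrum
#' @examples
#' classifySpectrum(c(9.6, 0, -6.4, -11.5))$label  # "chaotic_4d"
#' @export
classifySpectrum <- function(lambdas, chaosThreshold = 1, zeroTol = 0.5) {
  checkSorted(lambdas)
  if (chaosThreshold <= 0 || zeroTol < 0)
    stop("invalid thresholds")
  l1 <- lambdas[1]
  if (l1 >= chaosThreshold && length(lambdas) < 3)
    stop("at least 3 exponents are required to test four-dimensional chaos")
  label <- if (l1 < -zeroTol) "point"
           else if (l1 < chaosThreshold) "periodic"
           else "chaotic"
  hyper <- FALSE
  if (label == "chaotic") {
    hyper <- lambdas[2] > zeroTol
    if (!hyper && abs(lambdas[2]) <= zeroTol && l1 > abs(lambdas[3]))
      label <- "chaotic_4d"
  }
  structure(list(label = label,
                 D = topologicalDimension(lambdas),
                 D_KY = kaplanYorke(lambdas),
                 hyperchaosFlag = hyper,
                 chaosThreshold = chaosThreshold,
                 zeroTol = zeroTol,
                 lambdas = lambdas),
            class = "attractorClass")
}

#' @export
print.attractorClass <- function(x, ...) {
  cat(sprintf("attractor: %s (D = %d, D_KY = %s%s)\n", x$label, x$D,
              if (is.na(x$D_KY)) "undefined" else signif(x$D_KY, 6),
              if (x$hyperchaosFlag) ", hyperchaotic" else ""))
  cat("  exponents (1/s):", paste(signif(x$lambdas, 4), collapse = ", "),
      "\n")
  cat(sprintf("  thresholds: chaos >= %g, zero tolerance %g (1/s)\n",
              x$chaosThreshold, x$zeroTol))
  invisible(x)
}
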