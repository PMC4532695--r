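# Dynamical-system wrappers: a common S3 contract ("dynSystem") shared by
# the Liley model and the benchmark systems, carrying both pure-R
# rhs/jacobian callables (reference implementations, used in tests and
# small computations) and the parameter block for the compiled backend.

PARMS_LEN <- 64L

newDynSystem <- function(name, n, rhs, jac, sysId, sysPars,
                         knownSpectrum = NULL, y0 = NULL,
                         tTransient = 1000, tRun = 10000,
                         dtRenorm = 10) {
  if (!is.null(knownSpectrum)) {
    stopifnot(length(knownSpectrum) <= n,
              !is.unsorted(rev(knownSpectrum)))
  }
  structure(list(name = name, n = as.integer(n), rhs = rhs, jac = jac,
                 sysId = as.integer(sysId), sysPars = as.numeric(sysPars),
                 knownSpectrum = knownSpectrum, y0 = y0,
                 tTransient = tTransient, tRun = tRun,
                 dtRenorm = dtRenorm),
            class = "dynSystem")
}

#' @export
print.dynSystem <- function(x, ...) {
  cat(sprintf("dynSystem '%s' (n = %d)\n", x$name, x$n))
  if (!is.null(x$knownSpectrum))
    cat("  known spectrum (1/s):",
        paste(signif(x$knownSpectrum, 6), collapse = ", "), "\n")
  invisible(x)
}

# parameter vector handed to the compiled code, padded to PARMS_LEN
systemParms <- function(system, k = 0L, method = 0L) {
  pars <- c(system$sysId, system$n, k, method, system$sysPars)
  if (length(pars) > PARMS_LEN) stop("parameter block too long")
  c(pars, numeric(PARMS_LEN - length(pars)))
}

#' Wrap a Liley parameter set as a dynamical system
#'
#' @param params a [lileyParameters()] object
#' @param seed seed for the default initial state
#' @return a `dynSystem` usable with [computeSpectrum()] and friends
#' @export
lileySystem <- function(params, seed = 1) {
  validateLileyParameters(params)
  newDynSystem(
    name = "liley", n = 10L,
    rhs = function(t, y) unname(lileyRHS(y, params)),
    jac = function(t, y) unname(lileyJacobian(y, params)),
    sysId = 1L, sysPars = lileyParVector(params),
    y0 = unname(defaultInitialState(params, seed = seed)),
    tTransient = 10000, tRun = 100000, dtRenorm = 10)
}

#' Diagonal linear benchmark system
#'
#' \eqn{\dot x = \mathrm{diag}(a) x} with exactly known Lyapunov spectrum:
#' the rates themselves (converted to 1/s).
#'
#' @param rates decay/growth rates, per ms
#' @return a `dynSystem` with `knownSpectrum` in 1/s
#' @export
diagonalLinear <- function(rates) {
  n <- length(rates)
  if (n < 1 || n > 10) stop("1 to 10 rates supported")
  newDynSystem(
    name = "diagonal", n = n,
    rhs = function(t, y) rates * y,
    jac = function(t, y) diag(rates, n, n),
    sysId = 2L, sysPars = rates,
    knownSpectrum = sort(rates, decreasing = TRUE) * 1000,
    y0 = rep(1, n), tTransient = 0, tRun = 100,
    dtRenorm = min(0.5, 1 / max(abs(rates))))
}

#' Hopf normal form benchmark (limit cycle)
#'
#' \eqn{\dot r = \mu r - r^3}, \eqn{\dot\theta = \omega} in Cartesian
#' coordinates.  For \eqn{\mu > 0} the attractor is the circle
#' \eqn{r = \sqrt\mu} with exact spectrum \eqn{(0, -2\mu)} per ms.
#'
#' @param mu bifurcation parameter (1/ms), must be positive here
#' @param omega angular frequency (rad/ms)
#' @return a `dynSystem` with `knownSpectrum` in 1/s
#' @export
hopfNormalForm <- function(mu = 1, omega = 1) {
  if (mu <= 0) stop("mu must be positive for a limit cycle")
  newDynSystem(
    name = "hopf", n = 2L,
    rhs = function(t, y) {
      r2 <- sum(y^2)
      c(mu * y[1] - omega * y[2] - r2 * y[1],
        omega * y[1] + mu * y[2] - r2 * y[2])
    },
    jac = function(t, y) {
      matrix(c(mu - 3 * y[1]^2 - y[2]^2, -omega - 2 * y[1] * y[2],
               omega - 2 * y[1] * y[2], mu - y[1]^2 - 3 * y[2]^2),
             2, 2, byrow = TRUE)
    },
    sysId = 3L, sysPars = c(mu, omega),
    knownSpectrum = c(0, -2 * mu) * 1000,
    y0 = c(sqrt(mu), 0), tTransient = 200 / mu, tRun = 5000,
    dtRenorm = min(1, 0.5 / mu))
}

#' Lorenz-63 benchmark (chaotic)
#'
#' The classic Lorenz system, integrated here in ms time units.  No
#' external truth is claimed for its spectrum; it serves the
#' cross-method agreement and trace-identity checks.  Its Jacobian trace
#' is the constant \eqn{-(\sigma + 1 + \beta)}, so the sum of all three
#' exponents has a closed form.
#'
#' @param sigma,rho,beta standard Lorenz parameters (rates per ms)
#' @return a `dynSystem`
#' @export
lorenz63 <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  newDynSystem(
    name = "lorenz63", n = 3L,
    rhs = function(t, y) {
      c(sigma * (y[2] - y[1]),
        y[1] * (rho - y[3]) - y[2],
        y[1] * y[2] - beta * y[3])
    },
    jac = function(t, y) {
      matrix(c(-sigma, sigma, 0,
               rho - y[3], -1, -y[1],
               y[2], y[1], -beta),
             3, 3, byrow = TRUE)
    },
    sysId = 4L, sysPars = c(sigma, rho, beta),
    y0 = c(1, 1, 1), tTransient = 50, tRun = 2000,
    dtRenorm = 0.25)
}

#' Look up a benchmark system by name
#'
#' @param name one of `"diagonal"`, `"hopf"`, `"lorenz63"`
#' @param ... passed to the constructor
#' @return a `dynSystem`
#' @export
benchmarkSystem <- function(name = c("diagonal", "hopf", "lorenz63"), ...) {
  name <- match.arg(name)
  switch(name,
         diagonal = diagonalLinear(...),
         hopf = hopfNormalForm(...),
         lorenz63 = lorenz63(...))
}
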