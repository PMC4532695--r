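#' @useDynLib lileyChaos, .registration = TRUE
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.table read.csv packageVersion
"_PACKAGE"

#' Names of the ten state variables, in the fixed ordering used everywhere
#'
#' The macrocolumn state is the ordered 10-tuple
#' (h_e, h_i, I_ee, J_ee, I_ei, J_ei, I_ie, J_ie, I_ii, J_ii):
#' two mean soma potentials (mV) and, for each of the four synaptic
#' pathways jk, the PSP activity I_jk (mV) and its rate of change
#' J_jk = dI_jk/dt (mV/ms).  Subscripts follow Liley's target-source
#' convention: jk means "at population j, from synapse type k", so
#' I_ei is the inhibitory PSP activity felt by the excitatory
#' population.  The same ordering is used by the tangent dynamics and
#' by all file formats.
#'
#' @return character vector of length 10
#' @export
lileyStateNames <- function() {
  c("h_e", "h_i", "I_ee", "J_ee", "I_ei", "J_ei", "I_ie", "J_ie",
    "I_ii", "J_ii")
}

#' Sigmoidal population firing rate
#'
#' \deqn{S_q(h) = S_q^{max} / (1 + \exp(-\sqrt{2}\,(h - \mu_q)/\sigma_q))}
#' for population q in \{e, i\}: the mean firing rate (1/ms) of a neural
#' population whose mean soma potential is h, with thresholds normally
#' distributed around \eqn{\mu_q} with spread \eqn{\sigma_q}.
#'
#' @param h mean soma potential (mV); may be a vector
#' @param pop `"e"` or `"i"`
#' @param params a [lileyParameters()] object
#' @param deriv if `TRUE`, return dS/dh instead
#' @return firing rate(s) in 1/ms (or its derivative, 1/(ms mV))
#' @export
sigmoidRate <- function(h, pop = c("e", "i"), params, deriv = FALSE) {
  pop <- match.arg(pop)
  if (any(!is.finite(h))) stop("non-finite membrane potential")
  smax <- params[[paste0("S_", pop, "_max")]]
  mu <- params[[paste0("mu_", pop)]]
  sg <- params[[paste0("sigma_", pop)]]
  s <- smax / (1 + exp(-sqrt(2) * (h - mu) / sg))
  if (deriv) sqrt(2) / sg * s * (1 - s / smax) else s
}

#' Dimensionless synaptic reversal weighting
#'
#' \deqn{\psi_{jk}(h) = (h_j^{eq} - h) / |h_j^{eq} - h_k^{rest}|}
#' for synapse type j acting on population k, evaluated at the target
#' population's soma potential.  It is +1 (excitatory) or -1 (inhibitory)
#' at the target's resting potential and changes sign exactly at the
#' reversal potential of the synapse type.
#'
#' @param h target population's soma potential (mV); may be a vector
#' @param syn synapse source type, `"e"` or `"i"`
#' @param target target population, `"e"` or `"i"`
#' @param params a [lileyParameters()] object
#' @return dimensionless weight(s)
#' @export
synapticWeight <- function(h, syn = c("e", "i"), target = c("e", "i"),
                           params) {
  syn <- match.arg(syn)
  target <- match.arg(target)
  heq <- params[[paste0("h_", syn, "_eq")]]
  hrest <- params[[paste0("h_", target, "_rest")]]
  denom <- abs(heq - hrest)
  if (denom == 0)
    stop("degenerate parameters: reversal potential h_", syn,
         "_eq equals resting potential h_", target, "_rest")
  (heq - h) / denom
}

#' Right-hand side of the ten-equation macrocolumnar Liley model
#'
#' The mean soma potentials relax towards rest, driven by the
#' excitatory and inhibitory PSP activities at each population weighted
#' by [synapticWeight()]; each PSP activity obeys a critically damped
#' second-order ("alpha function") response driven by presynaptic
#' firing of its source population \eqn{N_{jk} S_k(h_k)} plus the
#' extracortical pulse density \eqn{p_{jk}} (subscripts jk =
#' target j, source k):
#' \deqn{\tau_e \dot h_e = (h_e^{rest} - h_e) + \psi_{ee}(h_e) I_{ee} +
#'   \psi_{ei}(h_e) I_{ei}}
#' \deqn{\tau_i \dot h_i = (h_i^{rest} - h_i) + \psi_{ie}(h_i) I_{ie} +
#'   \psi_{ii}(h_i) I_{ii}}
#' \deqn{\ddot I_{jk} = -2\gamma_{jk}\dot I_{jk} - \gamma_{jk}^2 I_{jk} +
#'   e\,\Gamma_{jk}\gamma_{jk}\,(N_{jk} S_k(h_k) + p_{jk})}
#' The factor \eqn{e = \exp(1)} normalizes the impulse response so that
#' an isolated PSP peaks at exactly \eqn{\Gamma_{jk}} after
#' \eqn{1/\gamma_{jk}} ms.
#'
#' @param y state vector of length 10 in the order of [lileyStateNames()]
#' @param params a [lileyParameters()] object
#' @return named derivative vector (units per ms)
#' @export
lileyRHS <- function(y, params) {
  if (length(y) != 10) stop("Liley state must have length 10")
  if (any(!is.finite(y))) stop("non-finite state passed to lileyRHS")
  p <- params
  he <- y[1]; hi <- y[2]
  se <- sigmoidRate(he, "e", p)
  si <- sigmoidRate(hi, "i", p)
  dy <- numeric(10)
  dy[1] <- (p$h_e_rest - he +
              synapticWeight(he, "e", "e", p) * y[3] +
              synapticWeight(he, "i", "e", p) * y[5]) / p$tau_e
  dy[2] <- (p$h_i_rest - hi +
              synapticWeight(hi, "e", "i", p) * y[7] +
              synapticWeight(hi, "i", "i", p) * y[9]) / p$tau_i
  drive <- c(p$N_ee * se + p$p_ee, p$N_ei * si + p$p_ei,
             p$N_ie * se + p$p_ie, p$N_ii * si + p$p_ii)
  G <- c(p$Gamma_ee, p$Gamma_ei, p$Gamma_ie, p$Gamma_ii)
  g <- c(p$gamma_ee, p$gamma_ei, p$gamma_ie, p$gamma_ii)
  for (s in 1:4) {
    iI <- 1 + 2 * s; iJ <- 2 + 2 * s
    dy[iI] <- y[iJ]
    dy[iJ] <- -2 * g[s] * y[iJ] - g[s]^2 * y[iI] +
      exp(1) * G[s] * g[s] * drive[s]
  }
  if (any(!is.finite(dy)))
    stop("divergence: non-finite derivative at state (",
         paste(signif(y, 6), collapse = ", "), ")")
  setNames(dy, lileyStateNames())
}

#' Analytic Jacobian of the Liley right-hand side
#'
#' Exact partial derivatives of [lileyRHS()] with respect to the state.
#' The eight synaptic rows are constant except for the columns through
#' the firing-rate nonlinearities \eqn{S_e(h_e)} and \eqn{S_i(h_i)}.
#'
#' @inheritParams lileyRHS
#' @return a 10 x 10 matrix (units per ms), dimnames from
#'   [lileyStateNames()]
#' @export
lileyJacobian <- function(y, params) {
  if (length(y) != 10) stop("Liley state must have length 10")
  p <- params
  he <- y[1]; hi <- y[2]
  J <- matrix(0, 10, 10, dimnames = list(lileyStateNames(),
                                         lileyStateNames()))
  dee <- abs(p$h_e_eq - p$h_e_rest); die <- abs(p$h_i_eq - p$h_e_rest)
  dei <- abs(p$h_e_eq - p$h_i_rest); dii <- abs(p$h_i_eq - p$h_i_rest)
  J[1, 1] <- (-1 - y[3] / dee - y[5] / die) / p$tau_e
  J[1, 3] <- synapticWeight(he, "e", "e", p) / p$tau_e
  J[1, 5] <- synapticWeight(he, "i", "e", p) / p$tau_e
  J[2, 2] <- (-1 - y[7] / dei - y[9] / dii) / p$tau_i
  J[2, 7] <- synapticWeight(hi, "e", "i", p) / p$tau_i
  J[2, 9] <- synapticWeight(hi, "i", "i", p) / p$tau_i
  sde <- sigmoidRate(he, "e", p, deriv = TRUE)
  sdi <- sigmoidRate(hi, "i", p, deriv = TRUE)
  G <- c(p$Gamma_ee, p$Gamma_ei, p$Gamma_ie, p$Gamma_ii)
  g <- c(p$gamma_ee, p$gamma_ei, p$gamma_ie, p$gamma_ii)
  N <- c(p$N_ee, p$N_ei, p$N_ie, p$N_ii)
  sd <- c(sde, sdi, sde, sdi)
  hcol <- c(1, 2, 1, 2)
  for (s in 1:4) {
    iI <- 1 + 2 * s; iJ <- 2 + 2 * s
    J[iI, iJ] <- 1
    J[iJ, iI] <- -g[s]^2
    J[iJ, iJ] <- -2 * g[s]
    J[iJ, hcol[s]] <- exp(1) * G[s] * g[s] * N[s] * sd[s]
  }
  J
}

# At a fixed point J_jk = 0 and I_jk is closed-form in (h_e, h_i); this
# computes those synaptic levels.
equilibriumSynapticLevels <- function(he, hi, p) {
  se <- sigmoidRate(he, "e", p)
  si <- sigmoidRate(hi, "i", p)
  c(I_ee = exp(1) * p$Gamma_ee * (p$N_ee * se + p$p_ee) / p$gamma_ee,
    I_ei = exp(1) * p$Gamma_ei * (p$N_ei * si + p$p_ei) / p$gamma_ei,
    I_ie = exp(1) * p$Gamma_ie * (p$N_ie * se + p$p_ie) / p$gamma_ie,
    I_ii = exp(1) * p$Gamma_ii * (p$N_ii * si + p$p_ii) / p$gamma_ii)
}

#' Locate an equilibrium of the macrocolumn model
#'
#' At a fixed point the eight synaptic states are closed-form functions of
#' the two soma potentials, so the root problem reduces exactly to two
#' equations in (h_e, h_i).  These are solved with a damped Newton
#' iteration using the analytic 2 x 2 Jacobian, then the full ten-state
#' equilibrium is assembled and checked against the residual tolerance.
#' The model can be multistable: the equilibrium returned is the one
#' reached from `guess`.
#'
#' @param params a [lileyParameters()] object
#' @param guess initial state (length 10, or a length-2 vector
#'   (h_e, h_i)); defaults to the resting potentials
#' @param tol max-norm residual tolerance on the full right-hand side
#'   (per ms)
#' @param maxit iteration budget
#' @return named equilibrium state vector of length 10
#' @export
findEquilibrium <- function(params, guess = NULL, tol = 1e-10,
                            maxit = 200) {
  p <- params
  h <- if (is.null(guess)) c(p$h_e_rest, p$h_i_rest)
       else if (length(guess) >= 2) as.numeric(guess[1:2])
       else stop("guess must contain at least (h_e, h_i)")
  if (any(!is.finite(h))) stop("non-finite guess")
  dee <- abs(p$h_e_eq - p$h_e_rest); die <- abs(p$h_i_eq - p$h_e_rest)
  dei <- abs(p$h_e_eq - p$h_i_rest); dii <- abs(p$h_i_eq - p$h_i_rest)
  Ffun <- function(h) {
    I <- equilibriumSynapticLevels(h[1], h[2], p)
    c(p$h_e_rest - h[1] + synapticWeight(h[1], "e", "e", p) * I["I_ee"] +
        synapticWeight(h[1], "i", "e", p) * I["I_ei"],
      p$h_i_rest - h[2] + synapticWeight(h[2], "e", "i", p) * I["I_ie"] +
        synapticWeight(h[2], "i", "i", p) * I["I_ii"])
  }
  Jfun <- function(h) {
    I <- equilibriumSynapticLevels(h[1], h[2], p)
    sde <- sigmoidRate(h[1], "e", p, deriv = TRUE)
    sdi <- sigmoidRate(h[2], "i", p, deriv = TRUE)
    dIee <- exp(1) * p$Gamma_ee * p$N_ee * sde / p$gamma_ee
    dIei <- exp(1) * p$Gamma_ei * p$N_ei * sdi / p$gamma_ei
    dIie <- exp(1) * p$Gamma_ie * p$N_ie * sde / p$gamma_ie
    dIii <- exp(1) * p$Gamma_ii * p$N_ii * sdi / p$gamma_ii
    matrix(c(
      -1 - I["I_ee"] / dee - I["I_ei"] / die +
        synapticWeight(h[1], "e", "e", p) * dIee,
      synapticWeight(h[1], "i", "e", p) * dIei,
      synapticWeight(h[2], "e", "i", p) * dIie,
      -1 - I["I_ie"] / dei - I["I_ii"] / dii +
        synapticWeight(h[2], "i", "i", p) * dIii
    ), 2, 2, byrow = TRUE)
  }
  newton <- function(h) {
    f <- Ffun(h)
    for (it in seq_len(maxit)) {
      if (max(abs(f)) < tol / 10) break
      step <- tryCatch(solve(Jfun(h), -f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      improved <- FALSE
      while (lam >= 1e-10) {
        hNew <- h + lam * step
        fNew <- tryCatch(Ffun(hNew), error = function(e) rep(Inf, 2))
        if (all(is.finite(fNew)) && sum(fNew^2) < sum(f^2)) {
          improved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (!improved) return(NULL)
      h <- hNew; f <- fNew
    }
    if (max(abs(f)) < tol / 10) h else NULL
  }
  root <- newton(h)
  if (is.null(root)) {
    # multistart fallback: the reduced system can have several roots and
    # steep sigmoidal walls; scan a coarse grid of soma potentials
    grid <- as.matrix(expand.grid(seq(-90, -30, by = 10),
                                  seq(-90, -30, by = 10)))
    for (g in seq_len(nrow(grid))) {
      root <- newton(grid[g, ])
      if (!is.null(root)) break
    }
  }
  if (is.null(root))
    stop("equilibrium search did not converge from any starting point")
  I <- equilibriumSynapticLevels(root[1], root[2], p)
  y <- setNames(c(root[1], root[2], I["I_ee"], 0, I["I_ei"], 0,
                  I["I_ie"], 0, I["I_ii"], 0), lileyStateNames())
  res <- max(abs(lileyRHS(y, p)))
  if (res >= tol)
    stop(sprintf("equilibrium residual too large: max |rhs| = %.3e", res))
  y
}

#' Default initial condition: perturbed equilibrium
#'
#' The numerically found equilibrium reached from the resting potentials,
#' plus a seeded random perturbation of magnitude `mag` (mV) on the two
#' soma potentials, so that runs off an attractor are reproducible.
#'
#' @param params a [lileyParameters()] object
#' @param seed integer seed for the perturbation
#' @param mag perturbation magnitude (mV)
#' @return named state vector of length 10
#' @export
defaultInitialState <- function(params, seed = 1, mag = 0.1) {
  y <- tryCatch(findEquilibrium(params), error = function(e) NULL)
  if (is.null(y)) {
    # no locatable equilibrium: start from the decoupled resting state
    y <- setNames(c(params$h_e_rest, params$h_i_rest, rep(0, 8)),
                  lileyStateNames())
  }
  d <- withSeed(seed, stats::runif(2, -1, 1)) * mag
  y[1:2] <- y[1:2] + d
  y
}

#' Simulate the macrocolumn model
#'
#' Adaptive integration (deSolve, compiled right-hand side) with
#' user-set tolerances.  Any state component exceeding `divergenceBound`
#' in magnitude, or a solver failure, flags the returned trajectory as
#' diverged and truncates it at the last healthy sample rather than
#' erroring, so parameter sweeps survive exploding orbits.
#'
#' @param params a [lileyParameters()] object
#' @param y0 initial state (length 10); default [defaultInitialState()]
#' @param tEnd end time (ms)
#' @param times explicit output times (ms, strictly increasing, from 0);
#'   overrides `tEnd`/`by`
#' @param by output sampling interval (ms)
#' @param rtol,atol relative/absolute solver tolerances
#' @param method a `deSolve` integration method (default `"lsoda"`,
#'   which switches to a stiff solver when needed)
#' @param seed seed used only when `y0` is `NULL`
#' @param divergenceBound state magnitude that marks divergence
#' @return an object of class `"lileyTrajectory"`: list with `times`,
#'   `states` (matrix, columns [lileyStateNames()]), `params`, `solver`
#'   metadata and a `diverged` flag
#' @export
simulateLiley <- function(params, y0 = NULL, tEnd = 1000, times = NULL,
                          by = 1, rtol = 1e-8, atol = 1e-10,
                          method = "lsoda", seed = 1,
                          divergenceBound = 1e6) {
  validateLileyParameters(params)
  if (is.null(y0)) y0 <- defaultInitialState(params, seed = seed)
  if (length(y0) != 10) stop("y0 must have length 10")
  if (is.null(times)) {
    if (tEnd <= 0) stop("tEnd must be positive")
    times <- seq(0, tEnd, by = by)
  }
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  out <- solveCompiled(y = unname(y0), times = times, aug = FALSE,
                       parms = systemParms(lileySystem(params)),
                       rtol = rtol, atol = atol, method = method)
  st <- out$y
  colnames(st) <- lileyStateNames()
  diverged <- out$diverged || any(abs(st) > divergenceBound)
  if (any(abs(st) > divergenceBound)) {
    bad <- which(apply(abs(st) > divergenceBound, 1, any))[1]
    st <- st[seq_len(bad - 1), , drop = FALSE]
    out$t <- out$t[seq_len(bad - 1)]
    diverged <- TRUE
  }
  structure(list(times = out$t, states = st, params = params,
                 solver = list(method = method, rtol = rtol, atol = atol),
                 diverged = diverged),
            class = "lileyTrajectory")
}

#' @export
print.lileyTrajectory <- function(x, ...) {
  cat(sprintf("Liley trajectory: %d samples over %.6g ms (%s, rtol %.1e)%s\n",
              length(x$times), diff(range(x$times)), x$solver$method,
              x$solver$rtol, if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' @export
as.data.frame.lileyTrajectory <- function(x, ...) {
  data.frame(t_ms = x$times, x$states, check.names = FALSE)
}

#' Export a trajectory as CSV
#'
#' Header: `t_ms,h_e,h_i,I_ee,J_ee,I_ei,J_ei,I_ie,J_ie,I_ii,J_ii`.
#'
#' @param traj a `lileyTrajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
exportTrajectoryCSV <- function(traj, path) {
  df <- as.data.frame(traj)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
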