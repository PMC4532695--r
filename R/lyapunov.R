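# Partial Lyapunov spectra from the augmented tangent system.
#
# Two backends share one engine:
#  * "continuous": Gram-Schmidt orthonormalization built into the tangent
#    ODEs, so the k tangent directions stay (near-)orthonormal along the
#    flow and the accumulators nu_i integrate the local expansion rates
#    e_i . J e_i directly.
#  * "discrete": the classic tangent-map method; raw tangent vectors are
#    integrated and a QR (modified Gram-Schmidt) renormalization at fixed
#    intervals folds log growth factors into nu_i.
# Both apply a hard renormalization event every dtRenorm ms (numerical
# insurance for the continuous form on long runs).  Exponents are
# reported in 1/s, base e: per-ms rates multiplied by 1000.

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Dimension of the augmented tangent system
#'
#' Tracking the k leading Lyapunov exponents of an n-dimensional flow
#' requires the base system, k tangent vectors of length n, and k scalar
#' accumulators: n + k n + k equations in total (43 for n = 10, k = 3;
#' 120 for k = n = 10).
#'
#' @param n base-system dimension
#' @param k number of exponents tracked
#' @return integer equation count
#' @export
augmentedDimension <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1 || k > n) stop("need 1 <= k <= n")
  n + k * n + k
}

#' Assemble an augmented state vector
#'
#' @param y base state (length n)
#' @param E n x k matrix of tangent vectors (columns)
#' @param nu k exponent accumulators (default 0)
#' @return numeric vector of length [augmentedDimension()]
#' @export
makeAugmentedState <- function(y, E, nu = rep(0, ncol(E))) {
  stopifnot(nrow(E) == length(y), length(nu) == ncol(E))
  c(y, as.vector(E), nu)
}

# seeded random orthonormal frame (n x k), via QR of a Gaussian matrix
randomOrthonormalFrame <- function(n, k, seed) {
  M <- withSeed(seed, matrix(stats::rnorm(n * k), n, k))
  qr.Q(qr(M))[, seq_len(k), drop = FALSE]
}

#' Reference (pure-R) augmented right-hand side
#'
#' The same vector field the compiled backend integrates, spelled out in
#' R: with J the Jacobian at the base state and u_i = J e_i,
#' \deqn{\dot e_i = u_i - (e_i \cdot u_i) e_i -
#'   \sum_{j<i} [(e_j \cdot u_i) + (e_i \cdot u_j)] e_j, \qquad
#'   \dot\nu_i = e_i \cdot u_i}
#' for the continuous method; the discrete method integrates
#' \eqn{\dot e_i = u_i} with \eqn{\dot\nu_i = 0} (growth is harvested at
#' QR renormalization instead).
#'
#' @param z augmented state, length n + k n + k
#' @param system a `dynSystem`
#' @param k number of tangent vectors
#' @param method `"continuous"` or `"discrete"`
#' @param t time passed to the system callables
#' @param orthoTol orthonormality drift beyond which the input is
#'   rejected (signals that a hard renormalization was missed)
#' @return derivative vector of the same length
#' @export
augmentedRHS <- function(z, system, k, method = c("continuous", "discrete"),
                         t = 0, orthoTol = 1e-6) {
  method <- match.arg(method)
  n <- system$n
  if (length(z) != augmentedDimension(n, k))
    stop("augmented state has wrong length")
  y <- z[seq_len(n)]
  E <- matrix(z[n + seq_len(n * k)], n, k)
  G <- crossprod(E)
  if (max(abs(G - diag(k))) > orthoTol)
    stop("tangent frame has drifted from orthonormality beyond tolerance; ",
         "re-orthonormalize before evaluating")
  J <- system$jac(t, y)
  U <- J %*% E
  dE <- matrix(0, n, k)
  dnu <- numeric(k)
  if (method == "continuous") {
    for (i in seq_len(k)) {
      aii <- sum(E[, i] * U[, i])
      dnu[i] <- aii
      dE[, i] <- U[, i] - aii * E[, i]
      for (j in seq_len(i - 1)) {
        dE[, i] <- dE[, i] -
          (sum(E[, j] * U[, i]) + sum(E[, i] * U[, j])) * E[, j]
      }
    }
  } else {
    dE <- U
  }
  c(system$rhs(t, y), as.vector(dE), dnu)
}

# --- compiled-solver plumbing ----------------------------------------

solveCompiled <- function(y, times, parms, aug = FALSE, rtol = 1e-8,
                          atol = 1e-10, method = "lsoda",
                          eventTimes = NULL, maxsteps = 100000) {
  args <- list(y = as.numeric(y), times = times,
               func = if (aug) "lc_derivs_aug" else "lc_derivs",
               parms = parms, dllname = "lileyChaos",
               initfunc = "lc_initmod", rtol = rtol, atol = atol,
               method = method, maxsteps = maxsteps)
  if (!is.null(eventTimes))
    args$events <- list(func = "lc_event_renorm", time = eventTimes)
  diverged <- FALSE
  out <- withCallingHandlers(
    tryCatch(do.call(deSolve::ode, args),
             error = function(e) NULL),
    warning = function(w) {
      diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(out))
    return(list(t = times[1], y = matrix(y, 1), diverged = TRUE))
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) diverged <- TRUE
  t <- out[, 1]
  m <- out[, -1, drop = FALSE]
  ok <- rowSums(!is.finite(m)) == 0
  if (!all(ok)) {
    diverged <- TRUE
    last <- if (any(!ok)) which(!ok)[1] - 1L else nrow(m)
    if (last < 1) last <- 1L
    t <- t[seq_len(last)]
    m <- m[seq_len(last), , drop = FALSE]
  }
  list(t = t, y = m, diverged = diverged)
}

# --- the engine -------------------------------------------------------

# R-side modified Gram-Schmidt on the tangent block of an augmented
# state; mirrors the compiled event.  For the discrete method the log
# norms are folded into the accumulators (harvest = TRUE).
renormAugmented <- function(z, n, k, harvest) {
  E <- matrix(z[n + seq_len(n * k)], n, k)
  logs <- numeric(k)
  for (i in seq_len(k)) {
    v <- E[, i]
    for (j in seq_len(i - 1)) v <- v - sum(E[, j] * v) * E[, j]
    r <- sqrt(sum(v * v))
    if (r <= 0 || !is.finite(r)) stop("degenerate tangent frame")
    E[, i] <- v / r
    logs[i] <- log(r)
  }
  z[n + seq_len(n * k)] <- as.vector(E)
  if (harvest) z[n + k * n + seq_len(k)] <- z[n + k * n + seq_len(k)] + logs
  z
}

# deSolve reports each output row *before* the event scheduled at that
# time, so for the discrete method the accumulators of the row at time t
# cover growth only up to t - dtRenorm.  The engine therefore (a) uses
# the shifted time base for the discrete running estimates and (b)
# applies the boundary renormalization itself, in R, at the end of every
# chunk, which completes the accumulators at the chunk boundary.
lyapEngine <- function(system, k, tTransient, tRun, dtRenorm, seed,
                       method, rtol, atol, y0, maxTRun = NULL,
                       tAlign = NULL, convTol = 0.02, nHistory = 200,
                       odeMethod = "lsoda") {
  stopifnot(inherits(system, "dynSystem"))
  n <- system$n
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("k exceeds the system dimension n = ", n)
  dtRenorm <- dtRenorm %||% system$dtRenorm
  if (tRun <= 0 || dtRenorm <= 0) stop("tRun and dtRenorm must be positive")
  y0 <- y0 %||% system$y0
  if (is.null(y0)) stop("no initial state available for system ", system$name)
  maxTRun <- maxTRun %||% tRun
  discrete <- method == "discrete"

  failed <- function(t) {
    structure(list(k = k, exponents = rep(NA_real_, k),
                   exponentsRaw = rep(NA_real_, k),
                   tRun = t, tTransient = tTransient,
                   dtRenorm = dtRenorm, seed = seed, method = method,
                   diverged = TRUE, converged = FALSE,
                   orthoDrift = NA_real_, system = system$name,
                   history = data.frame()),
              class = "lyapunovResult")
  }

  # transient on the base system only
  if (tTransient > 0) {
    tr <- solveCompiled(y0, c(0, tTransient), systemParms(system),
                        rtol = rtol, atol = atol, method = odeMethod)
    if (tr$diverged || length(tr$t) < 2) return(failed(0))
    y0 <- tr$y[nrow(tr$y), ]
  }

  E <- randomOrthonormalFrame(n, k, seed)
  z <- makeAugmentedState(y0, E)
  mcode <- if (method == "continuous") 0L else 1L
  parms <- systemParms(system, k = k, method = mcode)

  # tangent alignment phase: let the random frame rotate into the local
  # Oseledec directions, then reset the accumulators, removing the O(1)
  # log-projection offset that otherwise decays only as 1/T
  tAlign <- tAlign %||% min(20 * dtRenorm, 0.2 * tRun)
  if (tAlign > 0) {
    na <- max(1L, ceiling(tAlign / dtRenorm))
    times <- seq(0, na * dtRenorm, length.out = na + 1)
    sol <- solveCompiled(z, times, parms, aug = TRUE, rtol = rtol,
                         atol = atol, method = odeMethod,
                         eventTimes = times[-1])
    if (sol$diverged || length(sol$t) < na + 1) return(failed(0))
    z <- renormAugmented(sol$y[nrow(sol$y), ], n, k, harvest = FALSE)
    z[n + k * n + seq_len(k)] <- 0
  }

  nSteps <- max(1L, ceiling(tRun / dtRenorm))
  chunkT <- nSteps * dtRenorm
  tAcc <- numeric(0)
  nuAcc <- NULL
  driftAcc <- numeric(0)
  driftPre <- 0
  tDone <- 0
  converged <- FALSE

  repeat {
    times <- tDone + seq(0, chunkT, length.out = nSteps + 1)
    sol <- solveCompiled(z, times, parms, aug = TRUE, rtol = rtol,
                         atol = atol, method = odeMethod,
                         eventTimes = times[-1])
    if (sol$diverged || length(sol$t) < nSteps + 1) return(failed(tDone))
    tAcc <- c(tAcc, sol$t[-1])
    nuAcc <- rbind(nuAcc, sol$y[-1, n + k * n + seq_len(k), drop = FALSE])
    lastRow <- sol$y[nrow(sol$y), ]
    if (!discrete) {
      Epre <- matrix(lastRow[n + seq_len(n * k)], n, k)
      driftPre <- max(driftPre, max(abs(crossprod(Epre) - diag(k))))
    }
    # complete the boundary renormalization the solver reported before
    z <- renormAugmented(lastRow, n, k, harvest = discrete)
    Efin <- matrix(z[n + seq_len(n * k)], n, k)
    driftAcc <- c(driftAcc, max(abs(crossprod(Efin) - diag(k))))
    tDone <- tDone + chunkT

    tEff <- if (discrete) tAcc - dtRenorm else tAcc
    keep <- tEff > 0
    lam <- sweep(nuAcc[keep, , drop = FALSE], 1, tEff[keep], "/") * 1000
    finalNu <- unname(z[n + k * n + seq_len(k)])
    final <- finalNu / tDone * 1000
    tail <- tEff[keep] >= 0.8 * tDone
    spread <- apply(rbind(lam[tail, , drop = FALSE], final), 2,
                    function(x) diff(range(x)))
    converged <- all(spread <= convTol * pmax(abs(final), 1))
    if (converged || tDone >= maxTRun) break
  }

  ord <- order(final, decreasing = TRUE)
  tHist <- (if (discrete) tAcc - dtRenorm else tAcc)
  keep <- which(tHist > 0)
  idx <- keep[unique(round(seq(1, length(keep),
                               length.out = min(nHistory, length(keep)))))]
  hist <- data.frame(t_ms = tHist[idx])
  for (i in seq_len(k))
    hist[[paste0("lambda", i)]] <-
      nuAcc[idx, ord[i]] / tHist[idx] * 1000

  structure(list(k = k,
                 exponents = final[ord],
                 exponentsRaw = final,
                 tRun = tDone, tTransient = tTransient,
                 dtRenorm = dtRenorm, seed = seed, method = method,
                 diverged = FALSE, converged = converged,
                 orthoDrift = max(driftAcc),
                 orthoDriftPre = if (discrete) NA_real_ else driftPre,
                 system = system$name,
                 history = hist),
            class = "lyapunovResult")
}

#' Leading Lyapunov exponents via the augmented tangent system
#'
#' Integrates a transient on the base system, then the reduced augmented
#' system (n + k n + k equations) from a seeded random orthonormal
#' tangent frame, with hard Gram-Schmidt renormalization every
#' `dtRenorm` ms.  The continuous method keeps the orthonormalization
#' inside the tangent ODEs; `method = "discrete"` gives the classic
#' QR-renormalization backend (see [benettinSpectrum()]).  If `maxTRun`
#' exceeds `tRun`, integration continues in chunks of `tRun` until the
#' running estimates vary by less than `convTol` (relative, floored at
#' 1/s absolute) over the trailing 20 % of the run, or the cap is hit.
#'
#' @param system a `dynSystem`, or a [lileyParameters()] object (wrapped
#'   via [lileySystem()])
#' @param k number of leading exponents (1..n)
#' @param tTransient,tRun transient and accumulation times (ms);
#'   defaults are the system's suggested lengths
#' @param dtRenorm hard renormalization interval (ms); default is the
#'   system's suggested interval, chosen so that orthonormality drift
#'   cannot amplify across an interval at the system's own rates
#' @param seed seed for the initial tangent frame (and default initial
#'   state of a Liley system)
#' @param method `"continuous"` or `"discrete"`
#' @param rtol,atol solver tolerances
#' @param y0 optional initial base state
#' @param maxTRun optional cap for convergence-driven extension (ms)
#' @param tAlign tangent-alignment discard (ms): the augmented system is
#'   integrated for this long and the accumulators are then reset, so
#'   the random initial frame's projection offset does not bias the
#'   estimates; default 20 renormalization intervals (capped at 20 % of
#'   `tRun`)
#' @param convTol relative convergence tolerance of the running estimates
#' @return an object of class `"lyapunovResult"`: exponents in 1/s
#'   (base e), sorted descending, with convergence history, diagnostics
#'   and a `diverged` flag
#' @examples
#' computeSpectrum(diagonalLinear(c(-1, -2, -3)), k = 3, tRun = 50)
#' @export
computeSpectrum <- function(system, k = 3, tTransient = NULL, tRun = NULL,
                            dtRenorm = NULL, seed = 1,
                            method = c("continuous", "discrete"),
                            rtol = 1e-8, atol = 1e-10, y0 = NULL,
                            maxTRun = NULL, tAlign = NULL,
                            convTol = 0.02) {
  method <- match.arg(method)
  if (inherits(system, "lileyParameters"))
    system <- lileySystem(system, seed = seed)
  lyapEngine(system, k,
             tTransient %||% system$tTransient,
             tRun %||% system$tRun,
             dtRenorm, seed, method, rtol, atol, y0, maxTRun, tAlign,
             convTol)
}

#' Discrete (QR renormalization) Lyapunov backend
#'
#' Classic tangent-map integration: raw tangent vectors evolve under the
#' linearized flow and a modified Gram-Schmidt QR step at fixed intervals
#' re-orthonormalizes them, accumulating the logs of the diagonal norms.
#' Serves as the independent oracle for [computeSpectrum()].
#'
#' @inheritParams computeSpectrum
#' @return a `"lyapunovResult"` with method tag `"discrete"`
#' @export
benettinSpectrum <- function(system, k = 3, tTransient = NULL, tRun = NULL,
                             dtRenorm = NULL, seed = 1, rtol = 1e-8,
                             atol = 1e-10, y0 = NULL, maxTRun = NULL,
                             tAlign = NULL, convTol = 0.02) {
  computeSpectrum(system, k, tTransient, tRun, dtRenorm, seed,
                  method = "discrete", rtol = rtol, atol = atol, y0 = y0,
                  maxTRun = maxTRun, tAlign = tAlign, convTol = convTol)
}

#' @export
print.lyapunovResult <- function(x, ...) {
  cat(sprintf("Lyapunov spectrum (%s method, system '%s')\n",
              x$method, x$system))
  if (x$diverged) {
    cat("  DIVERGED after", x$tRun, "ms\n")
  } else {
    cat("  exponents (1/s, base e):",
        paste(signif(x$exponents, 4), collapse = ", "), "\n")
    cat(sprintf("  t_run %g ms after %g ms transient; renorm every %g ms; seed %d\n",
                x$tRun, x$tTransient, x$dtRenorm, x$seed))
    cat(sprintf("  converged: %s; orthonormality drift %.2e\n",
                x$converged, x$orthoDrift))
  }
  invisible(x)
}

#' Serialize a Lyapunov result as JSON
#'
#' Fields: `k`, `exponents_per_s`, `t_transient_ms`, `t_run_ms`, `seed`,
#' `method`, `diverged`, and `history` as records of `t_ms` plus running
#' estimates.
#'
#' @param x a `lyapunovResult`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeLyapunovJSON <- function(x, path) {
  obj <- list(k = x$k, exponents_per_s = x$exponents,
              t_transient_ms = x$tTransient, t_run_ms = x$tRun,
              seed = x$seed, method = x$method, diverged = x$diverged,
              history = x$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
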