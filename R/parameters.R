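#' Physiological parameter set for the macrocolumnar Liley model
#'
#' Constructs and validates the full parameterization of the spatially
#' homogeneous Liley mean-field model: membrane constants, synaptic
#' (PSP) kinetics, sigmoidal firing-rate parameters, intracortical
#' connectivity counts, and extracortical (thalamo-cortical) input pulse
#' densities.  All times are in ms, rates in 1/ms, potentials in mV.
#'
#' The defaults form the package's plausible-demo set: physiologically
#' ordered values that satisfy every model invariant but are not tied to
#' any published operating point.  Published sets are shipped as TOML
#' fixtures; see [lileyFixture()].
#'
#' @param h_e_rest,h_i_rest resting mean soma potentials (mV)
#' @param h_e_eq,h_i_eq excitatory/inhibitory synaptic reversal potentials
#'   (mV); the excitatory reversal must lie above both resting potentials,
#'   the inhibitory reversal below both
#' @param tau_e,tau_i passive membrane time constants (ms)
#' @param Gamma_ee,Gamma_ei,Gamma_ie,Gamma_ii peak PSP amplitudes (mV);
#'   subscripts jk are target-source (at population j, from synapse
#'   type k), so `Gamma_ei` is the inhibitory PSP peak at e-cells
#' @param gamma_ee,gamma_ei,gamma_ie,gamma_ii PSP rate constants (1/ms)
#' @param N_ee,N_ei,N_ie,N_ii mean local (intracortical) synaptic
#'   connection counts (dimensionless), target-source subscripts
#' @param S_e_max,S_i_max maximal mean firing rates (1/ms)
#' @param mu_e,mu_i firing thresholds (mV)
#' @param sigma_e,sigma_i threshold spreads (mV)
#' @param p_ee,p_ei,p_ie,p_ii extracortical input pulse densities
#'   (1/ms): excitatory (`p_ee`) and inhibitory (`p_ei`) drive onto the
#'   excitatory population, and likewise (`p_ie`, `p_ii`) onto the
#'   inhibitory population.  Only the drives onto the excitatory
#'   population are normally varied; `p_ie` and `p_ii` default to 0.
#' @return A named list of class `"lileyParameters"`.
#' @examples
#' p <- lileyParameters()
#' p$tau_e
#' @export
lileyParameters <- function(h_e_rest = -68, h_i_rest = -68,
                            h_e_eq = 40, h_i_eq = -85,
                            tau_e = 10, tau_i = 40,
                            Gamma_ee = 0.3, Gamma_ei = 0.6,
                            Gamma_ie = 0.3, Gamma_ii = 0.6,
                            gamma_ee = 0.25, gamma_ei = 0.07,
                            gamma_ie = 0.25, gamma_ii = 0.07,
                            N_ee = 3000, N_ei = 500,
                            N_ie = 3000, N_ii = 500,
                            S_e_max = 0.25, S_i_max = 0.25,
                            mu_e = -46, mu_i = -46,
                            sigma_e = 5, sigma_i = 5,
                            p_ee = 2, p_ei = 1, p_ie = 0, p_ii = 0) {
  p <- mget(lileyParameterNames())
  p <- lapply(p, function(x) {
    stopifnot(is.numeric(x), length(x) == 1L)
    as.numeric(x)
  })
  out <- structure(p, class = "lileyParameters")
  validateLileyParameters(out)
  out
}

#' Canonical field names of a Liley parameter set, in storage order
#' @return Character vector of the 28 parameter names.
#' @export
lileyParameterNames <- function() {
  c("h_e_rest", "h_i_rest", "h_e_eq", "h_i_eq", "tau_e", "tau_i",
    "Gamma_ee", "Gamma_ei", "Gamma_ie", "Gamma_ii",
    "gamma_ee", "gamma_ei", "gamma_ie", "gamma_ii",
    "N_ee", "N_ei", "N_ie", "N_ii",
    "S_e_max", "S_i_max", "mu_e", "mu_i", "sigma_e", "sigma_i",
    "p_ee", "p_ei", "p_ie", "p_ii")
}

#' Validate a Liley parameter set
#'
#' Checks positivity of time constants, rate constants, threshold spreads,
#' maximal firing rates and PSP amplitudes, the ordering of the reversal
#' potentials relative to rest, and non-negativity of connection counts
#' and input densities.
#'
#' @param p a `lileyParameters` object (or named list with the same fields)
#' @return `p`, invisibly; stops with an informative error on violation.
#' @export
validateLileyParameters <- function(p) {
  need <- lileyParameterNames()
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing Liley parameters: ", paste(missing, collapse = ", "))
  v <- unlist(p[need])
  if (any(!is.finite(v)))
    stop("non-finite Liley parameter value(s)")
  pos <- c("tau_e", "tau_i", "gamma_ee", "gamma_ei", "gamma_ie", "gamma_ii",
           "sigma_e", "sigma_i", "S_e_max", "S_i_max",
           "Gamma_ee", "Gamma_ei", "Gamma_ie", "Gamma_ii")
  bad <- pos[v[pos] <= 0]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (!(p$h_e_eq > p$h_e_rest && p$h_e_eq > p$h_i_rest))
    stop("excitatory reversal potential h_e_eq must exceed both resting potentials")
  if (!(p$h_i_eq < p$h_e_rest && p$h_i_eq < p$h_i_rest))
    stop("inhibitory reversal potential h_i_eq must lie below both resting potentials")
  nn <- c("N_ee", "N_ei", "N_ie", "N_ii", "p_ee", "p_ei", "p_ie", "p_ii")
  bad <- nn[v[nn] < 0]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p a `lileyParameters` object
#' @param ... named replacements, e.g. `p_ee = 24.2453`
#' @return a new `lileyParameters` object
#' @export
setLileyParameters <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), lileyParameterNames())
  if (length(unknown))
    stop("unknown Liley parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- lapply(repl, as.numeric)
  validateLileyParameters(p)
  p
}

#' @export
print.lileyParameters <- function(x, ...) {
  cat("Liley macrocolumn parameter set (units: mV, ms, 1/ms)\n")
  v <- unlist(x[lileyParameterNames()])
  print(v)
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled code.
lileyParVector <- function(p) {
  validateLileyParameters(p)
  unlist(p[lileyParameterNames()], use.names = FALSE)
}

# group -> fields map used by the TOML interface
.lileyGroups <- list(
  membrane     = c("h_e_rest", "h_i_rest", "tau_e", "tau_i"),
  synaptic     = c("h_e_eq", "h_i_eq",
                   "Gamma_ee", "Gamma_ei", "Gamma_ie", "Gamma_ii",
                   "gamma_ee", "gamma_ei", "gamma_ie", "gamma_ii"),
  sigmoid      = c("S_e_max", "S_i_max", "mu_e", "mu_i", "sigma_e", "sigma_i"),
  connectivity = c("N_ee", "N_ei", "N_ie", "N_ii"),
  inputs       = c("p_ee", "p_ei", "p_ie", "p_ii")
)

#' Read a Liley parameter set from a TOML file
#'
#' The file must contain the tables `membrane`, `synaptic`, `sigmoid`,
#' `connectivity` and `inputs` with keys named exactly as the fields of
#' [lileyParameters()].  Unknown tables or keys are an error, so typos
#' cannot silently fall back to defaults.
#'
#' @param path path to a TOML file
#' @return a validated `lileyParameters` object
#' @seealso [writeLileyParameters()], [lileyFixture()]
#' @export
readLileyParameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tl <- RcppTOML::parseTOML(path)
  unknownTab <- setdiff(names(tl), names(.lileyGroups))
  if (length(unknownTab))
    stop("unknown table(s) in parameter file: ", paste(unknownTab, collapse = ", "))
  vals <- list()
  for (g in names(.lileyGroups)) {
    tab <- tl[[g]]
    if (is.null(tab)) stop("missing table [", g, "] in ", path)
    unknown <- setdiff(names(tab), .lileyGroups[[g]])
    if (length(unknown))
      stop("unknown key(s) in [", g, "]: ", paste(unknown, collapse = ", "))
    vals <- c(vals, tab)
  }
  do.call(lileyParameters, vals)
}

#' Write a Liley parameter set as TOML
#'
#' Emits the same five-table layout that [readLileyParameters()] accepts.
#'
#' @param p a `lileyParameters` object
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeLileyParameters <- function(p, path) {
  validateLileyParameters(p)
  lines <- character(0)
  for (g in names(.lileyGroups)) {
    lines <- c(lines, sprintf("[%s]", g))
    for (f in .lileyGroups[[g]])
      lines <- c(lines, sprintf("%s = %s", f, format(p[[f]], digits = 17)))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a named parameter fixture shipped with the package
#'
#' Two fixtures are installed under `extdata/`:
#' \describe{
#'   \item{`"chaos2013"`}{a transcription of the macrocolumn set of
#'     Dafilis, Frascoli, Cadusch and Liley (Chaos 23:023111, 2013), at
#'     its published operating point \eqn{p_{ee} = 24.2453},
#'     \eqn{p_{ei} = 2.299} ms\eqn{^{-1}} (reported there to carry
#'     four-dimensional chaos).  The transcription is from the secondary
#'     literature and is not validated against the published exponents;
#'     see the methods vignette.}
#'   \item{`"plausible-demo"`}{a synthetic, physiologically ordered set
#'     used by examples and tests that must not depend on any
#'     transcription from the literature.}
#' }
#'
#' @param name fixture name
#' @return a validated `lileyParameters` object
#' @export
lileyFixture <- function(name = c("chaos2013", "plausible-demo")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".toml"), package = "lileyChaos")
  if (!nzchar(path)) stop("fixture not installed: ", name)
  readLileyParameters(path)
}
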