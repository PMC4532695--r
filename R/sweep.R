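# Parameter-plane experiment: uniform random sampling of the thalamic
# input plane (p_ee, p_ei), a Lyapunov spectrum and attractor class per
# point, and summary fractions of chaos and four-dimensional chaos.

# Stable per-point seed mixing (documented contract, reproducible under
# any execution order): a Lehmer-style step on the sweep seed combined
# linearly with the point index, reduced modulo the Mersenne prime
# 2^31 - 149 (2147483499... use 2147483563, a classic L'Ecuyer modulus).
# All intermediates stay below 2^53, so the arithmetic is exact in
# doubles.
mixSeed <- function(sweepSeed, idx) {
  m <- 2147483563
  s <- ((sweepSeed %% m) * 48271 + (idx %% m) * 30269 + 17) %% m
  as.integer(s)
}

# small FNV-1a hash of a config's deparsed form, for output provenance
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Specify a (p_ee, p_ei) plane sweep
#'
#' @param nPoints number of random points
#' @param seed sweep master seed; per-point seeds are derived from it
#'   deterministically
#' @param pEeRange,pEiRange rectangle bounds (1/ms), sampled uniformly on
#'   the open-closed interval (lower, upper]
#' @param k leading exponents per point (>= 3; 3 suffices for the
#'   four-dimensional-chaos test, 4 additionally resolves D_KY there)
#' @param params base parameter set: a fixture name for [lileyFixture()]
#'   or a [lileyParameters()] object
#' @param spectrum list of options passed to [computeSpectrum()]
#'   (`tTransient`, `tRun`, `dtRenorm`, `rtol`, `atol`, `maxTRun`,
#'   `method`)
#' @param chaosThreshold,zeroTol classification thresholds (1/s), see
#'   [classifySpectrum()]
#' @return an object of class `"sweepSpec"`
#' @export
sweepSpec <- function(nPoints, seed = 1,
                      pEeRange = c(0, 30), pEiRange = c(0, 10),
                      k = 3, params = "chaos2013",
                      spectrum = list(), chaosThreshold = 1,
                      zeroTol = 0.5) {
  stopifnot(nPoints >= 0, length(pEeRange) == 2, length(pEiRange) == 2,
            diff(pEeRange) > 0, diff(pEiRange) > 0,
            pEeRange[1] >= 0, pEiRange[1] >= 0, k >= 3)
  base <- if (is.character(params)) lileyFixture(params)
          else validateLileyParameters(params)
  defaults <- list(tTransient = 5000, tRun = 30000, dtRenorm = NULL,
                   rtol = 1e-8, atol = 1e-10, maxTRun = NULL,
                   method = "continuous")
  unknown <- setdiff(names(spectrum), names(defaults))
  if (length(unknown))
    stop("unknown spectrum option(s): ", paste(unknown, collapse = ", "))
  defaults[names(spectrum)] <- spectrum
  structure(list(nPoints = as.integer(nPoints), seed = as.integer(seed),
                 pEeRange = pEeRange, pEiRange = pEiRange,
                 k = as.integer(k),
                 fixture = if (is.character(params)) params else "custom",
                 params = base, spectrum = defaults,
                 chaosThreshold = chaosThreshold, zeroTol = zeroTol),
            class = "sweepSpec")
}

#' Sample the input plane of a sweep
#'
#' Draws `nPoints` i.i.d. uniform points from the open-closed rectangle
#' (deterministic given the sweep seed; the lower bounds are excluded).
#'
#' @param spec a [sweepSpec()]
#' @return data.frame with columns `idx`, `p_ee`, `p_ei`, `seed`
#' @export
samplePlane <- function(spec) {
  stopifnot(inherits(spec, "sweepSpec"))
  n <- spec$nPoints
  if (n == 0)
    return(data.frame(idx = integer(0), p_ee = numeric(0),
                      p_ei = numeric(0), seed = integer(0)))
  u <- withSeed(spec$seed, matrix(stats::runif(2 * n), n, 2))
  data.frame(
    idx = seq_len(n),
    p_ee = spec$pEeRange[1] + u[, 1] * diff(spec$pEeRange),
    p_ei = spec$pEiRange[1] + u[, 2] * diff(spec$pEiRange),
    seed = vapply(seq_len(n), function(i) mixSeed(spec$seed, i),
                  integer(1)))
}

sweepColumns <- function(k) {
  c("idx", "p_ee", "p_ei", "seed",
    paste0("lambda", seq_len(k)), "label", "D", "D_KY",
    "diverged", "t_run_ms")
}

fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

formatSweepRow <- function(row, k) {
  paste(c(sprintf("%d", row$idx),
          fmtNum(row$p_ee), fmtNum(row$p_ei), sprintf("%d", row$seed),
          vapply(seq_len(k), function(i) fmtNum(row[[paste0("lambda", i)]]),
                 character(1)),
          row$label,
          ifelse(is.na(row$D), "NA", sprintf("%d", row$D)),
          fmtNum(row$D_KY),
          ifelse(row$diverged, "TRUE", "FALSE"),
          fmtNum(row$t_run_ms)),
        collapse = ",")
}

evaluateSweepPoint <- function(spec, p_ee, p_ei, idx, pointSeed) {
  params <- setLileyParameters(spec$params, p_ee = p_ee, p_ei = p_ei)
  so <- spec$spectrum
  res <- computeSpectrum(lileySystem(params, seed = pointSeed),
                         k = spec$k,
                         tTransient = so$tTransient, tRun = so$tRun,
                         dtRenorm = so$dtRenorm, seed = pointSeed,
                         method = so$method, rtol = so$rtol,
                         atol = so$atol, maxTRun = so$maxTRun)
  row <- list(idx = idx, p_ee = p_ee, p_ei = p_ei, seed = pointSeed)
  for (i in seq_len(spec$k))
    row[[paste0("lambda", i)]] <- res$exponents[i]
  if (res$diverged) {
    row$label <- "diverged"; row$D <- NA_integer_; row$D_KY <- NA_real_
  } else {
    cls <- classifySpectrum(res$exponents,
                            chaosThreshold = spec$chaosThreshold,
                            zeroTol = spec$zeroTol)
    row$label <- cls$label
    row$D <- cls$D
    row$D_KY <- as.numeric(cls$D_KY)
  }
  row$diverged <- res$diverged
  row$t_run_ms <- res$tRun
  row
}

#' Run a (p_ee, p_ei) plane sweep
#'
#' Evaluates every sampled point independently (results do not depend on
#' execution order: each point's spectrum uses a seed derived only from
#' the sweep seed and the point index).  Diverged integrations are
#' recorded with a flag and excluded from the denominators of the
#' summary fractions.  With a `checkpoint` path, finished points are
#' appended to disk as they complete and a rerun resumes from them,
#' yielding records identical to an uninterrupted run.
#'
#' @param spec a [sweepSpec()]
#' @param checkpoint optional path to an append-only checkpoint file
#' @param verbose print per-point progress lines
#' @return an object of class `"lileySweep"`: the sweep specification, a
#'   `points` data.frame and the [summarizeSweep()] summary
#' @export
runSweep <- function(spec, checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweepSpec"))
  plan <- samplePlane(spec)
  hash <- configHash(spec[c("nPoints", "seed", "pEeRange", "pEiRange",
                            "k", "fixture", "spectrum",
                            "chaosThreshold", "zeroTol")])
  header <- sprintf("# lileyChaos %s config %s",
                    as.character(utils::packageVersion("lileyChaos")), hash)
  done <- character(0)
  doneIdx <- integer(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    lines <- readLines(checkpoint)
    if (length(lines) && lines[1] != header)
      stop("checkpoint was written under a different configuration")
    body <- lines[-(1:2)]
    doneIdx <- as.integer(sub(",.*", "", body))
    done <- body
  } else if (!is.null(checkpoint)) {
    writeLines(c(header, paste(sweepColumns(spec$k), collapse = ",")),
               checkpoint)
  }
  rowsTxt <- character(spec$nPoints)
  rowsTxt[doneIdx] <- done
  for (i in seq_len(spec$nPoints)) {
    if (i %in% doneIdx) next
    row <- evaluateSweepPoint(spec, plan$p_ee[i], plan$p_ei[i], i,
                              plan$seed[i])
    txt <- formatSweepRow(row, spec$k)
    rowsTxt[i] <- txt
    if (!is.null(checkpoint))
      cat(txt, "\n", sep = "", file = checkpoint, append = TRUE)
    if (verbose)
      message(sprintf("point %d/%d: (%.3f, %.3f) -> %s", i, spec$nPoints,
                      plan$p_ee[i], plan$p_ei[i], row$label))
  }
  points <- parseSweepRows(rowsTxt, spec$k)
  structure(list(spec = spec, configHash = hash, points = points,
                 summary = summarizeSweep(points,
                                          chaosThreshold =
                                            spec$chaosThreshold)),
            class = "lileySweep")
}

parseSweepRows <- function(rowsTxt, k) {
  if (!length(rowsTxt))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(sweepColumns(k)))),
      sweepColumns(k)))
  con <- textConnection(c(paste(sweepColumns(k), collapse = ","), rowsTxt))
  on.exit(close(con))
  df <- utils::read.csv(con, stringsAsFactors = FALSE)
  df$diverged <- as.logical(df$diverged)
  df[order(df$idx), , drop = FALSE]
}

#' Summarize a sweep's points
#'
#' Counts and fractions of chaotic (largest exponent at or above the
#' chaos threshold) and four-dimensional chaotic points among the
#' non-diverged integrations, each with an exact (Clopper-Pearson) 95 %
#' binomial confidence interval — needed when a scaled-down sweep is
#' compared against fractions measured on much larger samples.  The
#' fraction of four-dimensional chaos among chaotic points is flagged
#' undefined (`NA`) when no point is chaotic.
#'
#' @param points a sweep `points` data.frame
#' @param chaosThreshold threshold used for the `n_chaotic` count (1/s)
#' @return list with counts, fractions and `ci_*` intervals
#' @export
summarizeSweep <- function(points, chaosThreshold = 1) {
  if (nrow(points) == 0) stop("no points to summarize")
  ok <- !points$diverged
  if (!any(ok)) stop("all points diverged; nothing to summarize")
  nTotal <- sum(ok)
  chaotic <- ok & points$label %in% c("chaotic", "chaotic_4d")
  fdc <- ok & points$label == "chaotic_4d"
  nChaotic <- sum(chaotic)
  nFdc <- sum(fdc)
  ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(x, n)$conf.int)
  }
  list(n_total = nTotal,
       n_diverged = sum(!ok),
       n_chaotic = nChaotic,
       n_fdc = nFdc,
       frac_chaotic = nChaotic / nTotal,
       frac_fdc_of_chaotic = if (nChaotic > 0) nFdc / nChaotic else NA_real_,
       frac_fdc_of_total = nFdc / nTotal,
       ci_chaotic = ci(nChaotic, nTotal),
       ci_fdc_of_chaotic = ci(nFdc, nChaotic),
       ci_fdc_of_total = ci(nFdc, nTotal),
       chaosThreshold = chaosThreshold)
}

#' @export
print.lileySweep <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Liley (p_ee, p_ei) sweep: %d points, seed %d, fixture '%s'\n",
              x$spec$nPoints, x$spec$seed, x$spec$fixture))
  cat(sprintf("  non-diverged %d (diverged %d)\n", s$n_total, s$n_diverged))
  cat(sprintf("  chaotic (LLE >= %g/s): %d (%.1f%%)\n", s$chaosThreshold,
              s$n_chaotic, 100 * s$frac_chaotic))
  if (!is.na(s$frac_fdc_of_chaotic))
    cat(sprintf("  four-dimensional chaos: %d = %.1f%% of chaotic, %.1f%% of all\n",
                s$n_fdc, 100 * s$frac_fdc_of_chaotic,
                100 * s$frac_fdc_of_total))
  invisible(x)
}

#' Write sweep results as CSV
#'
#' Header `idx,p_ee,p_ei,seed,lambda1,lambda2,lambda3,label,D,D_KY,`
#' `diverged,t_run_ms`, preceded by a provenance comment line carrying
#' the package version and config hash.  Numbers are printed with 17
#' significant digits, so values round-trip exactly and identical
#' configurations reproduce the file bitwise.
#'
#' @param sweep a `lileySweep`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSweepCSV <- function(sweep, path) {
  stopifnot(inherits(sweep, "lileySweep"))
  k <- sweep$spec$k
  header <- sprintf("# lileyChaos %s config %s",
                    as.character(utils::packageVersion("lileyChaos")),
                    sweep$configHash)
  rows <- vapply(seq_len(nrow(sweep$points)), function(i)
    formatSweepRow(as.list(sweep$points[i, ]), k), character(1))
  writeLines(c(header, paste(sweepColumns(k), collapse = ","), rows), path)
  invisible(path)
}

#' Read a sweep CSV written by [writeSweepCSV()]
#'
#' @param path CSV path
#' @param k number of exponent columns (default 3)
#' @return the points data.frame
#' @export
readSweepCSV <- function(path, k = 3) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parseSweepRows(lines[-1], k)
}

#' Write a sweep summary as JSON
#'
#' @param sweep a `lileySweep`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSweepJSON <- function(sweep, path) {
  s <- sweep$summary
  s$config_hash <- sweep$configHash
  s$package_version <- as.character(utils::packageVersion("lileyChaos"))
  s$seed <- sweep$spec$seed
  s$zeroTol <- sweep$spec$zeroTol
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
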