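# fast spectrum options for sweep mechanics tests (the scientific
# content of per-point spectra is covered in test-tangent.R)
fastSpec <- list(tTransient = 500, tRun = 1500)

fastSweep <- function(n, seed = 1, ...) {
  sweepSpec(n, seed = seed, params = lileyParameters(),
            spectrum = fastSpec, ...)
}

test_that("plane sampling respects bounds, seed and moments", {
  spec <- fastSweep(0)
  expect_identical(nrow(samplePlane(spec)), 0L)
  spec <- sweepSpec(1e5, seed = 3, params = lileyParameters(),
                    spectrum = fastSpec)
  s <- samplePlane(spec)
  expect_true(all(s$p_ee > 0 & s$p_ee <= 30))
  expect_true(all(s$p_ei > 0 & s$p_ei <= 10))
  # uniform moments: mean 15 within 3 sigma/sqrt(n)
  expect_lt(abs(mean(s$p_ee) - 15), 3 * (30 / sqrt(12)) / sqrt(1e5))
  expect_lt(abs(mean(s$p_ei) - 5), 3 * (10 / sqrt(12)) / sqrt(1e5))
  expect_identical(samplePlane(spec), s)
  # different seed, different plan
  s2 <- samplePlane(sweepSpec(1e5, seed = 4, params = lileyParameters(),
                              spectrum = fastSpec))
  expect_false(identical(s$p_ee, s2$p_ee))
})

test_that("per-point seeds are a deterministic pure function", {
  s1 <- lileyChaos:::mixSeed(42, 7)
  expect_identical(s1, lileyChaos:::mixSeed(42, 7))
  expect_false(lileyChaos:::mixSeed(42, 8) == s1)
  expect_false(lileyChaos:::mixSeed(43, 7) == s1)
  seeds <- vapply(1:1000, function(i) lileyChaos:::mixSeed(1, i), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 990)
})

test_that("summaries count labels correctly and guard divisions", {
  pts <- data.frame(
    idx = 1:10,
    label = c(rep("chaotic", 4), "chaotic_4d", rep("periodic", 3),
              "point", "diverged"),
    diverged = c(rep(FALSE, 9), TRUE))
  s <- summarizeSweep(pts)
  expect_identical(s$n_total, 9L)
  expect_identical(s$n_diverged, 1L)
  expect_identical(s$n_chaotic, 5L)
  expect_identical(s$n_fdc, 1L)
  expect_equal(s$frac_fdc_of_chaotic, 0.2)
  expect_equal(s$frac_fdc_of_total, 1 / 9)
  # no chaotic points: undefined, not zero
  quiet <- data.frame(idx = 1:3, label = rep("periodic", 3),
                      diverged = FALSE)
  expect_true(is.na(summarizeSweep(quiet)$frac_fdc_of_chaotic))
  allDiv <- data.frame(idx = 1, label = "diverged", diverged = TRUE)
  expect_error(summarizeSweep(allDiv), "diverged")
  expect_error(summarizeSweep(pts[0, ]), "no points")
})

test_that("binomial intervals have close to nominal coverage", {
  set.seed(500)
  p <- 0.3
  hits <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    x <- rbinom(1, 60, p)
    ci <- as.numeric(stats::binom.test(x, 60)$conf.int)
    if (ci[1] <= p && p <= ci[2]) hits <- hits + 1
  }
  # Clopper-Pearson is conservative: coverage >= 0.95 up to MC noise
  expect_gt(hits / reps, 0.93)
})

test_that("sweeps are deterministic, order-independent and resumable", {
  spec <- fastSweep(4, seed = 9)
  sw1 <- runSweep(spec)
  sw2 <- runSweep(spec)
  expect_identical(sw1$points, sw2$points)
  expect_true(all(sw1$points$t_run_ms > 0))
  expect_true(sw1$summary$n_fdc <= sw1$summary$n_chaotic)
  expect_true(sw1$summary$n_chaotic <= sw1$summary$n_total)

  # order independence: evaluating point 3 in isolation reproduces row 3
  plan <- samplePlane(spec)
  solo <- lileyChaos:::evaluateSweepPoint(spec, plan$p_ee[3], plan$p_ei[3],
                                          3L, plan$seed[3])
  expect_equal(solo$lambda1, sw1$points$lambda1[3])
  expect_identical(solo$label, sw1$points$label[3])

  # checkpoint resume: interrupt after two points, resume, compare CSVs
  ck <- tempfile(fileext = ".csv")
  full <- tempfile(fileext = ".csv")
  res <- tempfile(fileext = ".csv")
  writeSweepCSV(sw1, full)
  runSweep(spec, checkpoint = ck)
  lines <- readLines(ck)
  writeLines(lines[1:4], ck)          # keep header + 2 finished points
  sw3 <- runSweep(spec, checkpoint = ck)
  writeSweepCSV(sw3, res)
  expect_identical(readLines(res), readLines(full))

  # a checkpoint from another config is refused
  other <- fastSweep(4, seed = 10)
  expect_error(runSweep(other, checkpoint = ck), "configuration")
})

test_that("sweep CSV round-trips with the documented header", {
  spec <- fastSweep(3, seed = 2)
  sw <- runSweep(spec)
  f <- tempfile(fileext = ".csv")
  writeSweepCSV(sw, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# lileyChaos .* config [0-9a-f]+$")
  expect_identical(lines[2],
    "idx,p_ee,p_ei,seed,lambda1,lambda2,lambda3,label,D,D_KY,diverged,t_run_ms")
  back <- readSweepCSV(f)
  expect_equal(back$lambda1, sw$points$lambda1)
  expect_identical(back$label, sw$points$label)
  j <- tempfile(fileext = ".json")
  writeSweepJSON(sw, j)
  parsed <- jsonlite::read_json(j)
  expect_true(all(c("n_total", "n_chaotic", "n_fdc", "frac_chaotic",
                    "config_hash", "seed") %in% names(parsed)))
})

test_that("classification in sweep rows is consistent with exponents", {
  spec <- fastSweep(4, seed = 5)
  sw <- runSweep(spec)
  for (i in seq_len(nrow(sw$points))) {
    r <- sw$points[i, ]
    if (r$diverged) next
    cls <- classifySpectrum(c(r$lambda1, r$lambda2, r$lambda3),
                            chaosThreshold = spec$chaosThreshold,
                            zeroTol = spec$zeroTol)
    expect_identical(r$label, cls$label)
    expect_identical(r$D, cls$D)
  }
})
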