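# lileyChaos

Lyapunov spectra and four-dimensional chaos in the Liley mean-field
model of the electroencephalogram.

## The problem

Mean-field ("neural mass") models describe the EEG through the averaged
dynamics of interacting excitatory and inhibitory cortical populations.
The macrocolumnar Liley model is ten coupled nonlinear ODEs: two mean
soma potentials (the excitatory one is the EEG proxy) and four
critically damped second-order postsynaptic-potential channels.  Chaos
that needs at least four dimensions to exist — *four-dimensional chaos*
(FDC), a single positive Lyapunov exponent on an attractor of
topological dimension three — has been reported in this model, and
mapping where it lives in the plane of thalamo-cortical input densities
$(p_{ee}, p_{ei})$ matters for how much structure one can honestly read
out of EEG time series.

This package is for computational neuroscientists and dynamical-systems
practitioners who want that analysis as a reusable, tested pipeline:
simulate the model, estimate partial Lyapunov spectra, classify
attractors, and map chaos over the input plane.

## The method

For an $n$-dimensional flow with ordered exponents
$\lambda_1 \ge \dots \ge \lambda_n$:

* the **topological dimension** $D$ is the largest integer with
  $\lambda_1 + \cdots + \lambda_D \ge 0$; the attractor needs at least
  $D + 1$ integer dimensions;
* the **Kaplan–Yorke dimension** is
  $D_{KY} = D + (\sum_{i \le D} \lambda_i)/|\lambda_{D+1}|$;
* **FDC test**: $\lambda_1 \ge 1\ \mathrm{s^{-1}}$, $\lambda_2 = 0$
  (within tolerance), $\lambda_1 > |\lambda_3|$ — then $D \ge 3$ and
  $D_{KY} > 3$ with only one positive exponent, so the top *three*
  exponents suffice and the tangent computation shrinks from
  $n + n^2 + n = 120$ to $n + 3n + 3 = 43$ equations.

Spectra come from two backends sharing one compiled engine: a
*continuous* method with Gram–Schmidt orthonormalization built into the
tangent ODEs, and a *discrete* QR-renormalization (Benettin-style)
method used as an independent oracle.  Both are validated against
benchmark systems with analytically known spectra.

## Worked example

```r
library(lileyChaos)

# top-3 Lyapunov exponents of the Lorenz-63 benchmark (rates per ms)
r <- computeSpectrum(lorenz63(), k = 3, seed = 1)
print(r)
#> Lyapunov spectrum (continuous method, system 'lorenz63')
#>   exponents (1/s, base e): 909.3, -0.5103, -14580
#>   t_run 2000 ms after 50 ms transient; renorm every 0.25 ms; seed 1

classifySpectrum(r$exponents)
#> attractor: chaotic (D = 2, D_KY = 2.06235)
```

The positive exponent (909 s⁻¹; the benchmark runs in ms units, so
this is the familiar Lorenz value ≈ 0.906 per time unit), the
near-zero flow exponent, and the strongly negative third give the
expected fractal dimension just above 2.

The published reference spectrum of the model's four-dimensional
chaotic attractor classifies as:

```r
classifySpectrum(c(9.6, 0, -6.4, -11.5))
#> attractor: chaotic_4d (D = 3, D_KY = 3.27826)
#>   exponents (1/s): 9.6, 0, -6.4, -11.5
```

Partial sums: $\lambda_1+\lambda_2+\lambda_3 = 3.2 > 0$ and
$\sum_{i\le4}\lambda_i = -8.3 < 0$, so $D = 3$, the attractor needs
four dimensions, and $D_{KY} = 3 - 3.2/(-11.5) = 3.278$.

A small input-plane sweep and its map:

```r
spec <- sweepSpec(100, seed = 42)         # (0,30] x (0,10], 1/ms
sw <- runSweep(spec, checkpoint = "sweep.ck")
print(sw)
writeSweepCSV(sw, "sweep.csv")
plotLLEMap(sw)                            # blue/green/red LLE map, FDC in black
```

A command-line front end with the same verbs (`simulate`, `lyap`,
`sweep`, `classify`, `plot`) is installed at `inst/cli/lileychaos.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lileychaos.R", package="lileyChaos"))')" \
    classify --lambdas 9.6,0,-6.4,-11.5
```

## Parameter fixtures

`lileyFixture("chaos2013")` loads a transcription of the macrocolumn
parameter set of the published four-dimensional-chaos studies, at its
published operating point; `lileyFixture("plausible-demo")` is a
synthetic set used by tests and examples.  The transcription could not
be validated against the published exponents in this implementation —
see the methods vignette (`vignettes/liley-chaos-methods.Rmd`) for the
full account and for every numerical choice (renormalization intervals,
alignment discards, thresholds, run lengths).

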