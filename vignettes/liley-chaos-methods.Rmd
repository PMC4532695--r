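---
title: "Methods: Lyapunov spectra and four-dimensional chaos in the Liley model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Lyapunov spectra and four-dimensional chaos in the Liley model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lileyChaos)
```

## The model

The macrocolumnar (spatially homogeneous) Liley model describes the mean
soma potentials $h_e, h_i$ (mV) of an excitatory and an inhibitory
cortical neural population, coupled through four postsynaptic-potential
(PSP) channels.  Each channel $jk$ — subscripts in Liley's
*target–source* convention, "at population $j$, from synapse type $k$" —
carries a critically damped second-order response $I_{jk}$ (mV) with
auxiliary rate $J_{jk} = \dot I_{jk}$, giving ten first-order ODEs:

$$\tau_e \dot h_e = (h_e^{rest} - h_e) + \psi_{ee}(h_e)\, I_{ee} +
  \psi_{ei}(h_e)\, I_{ei},$$
$$\tau_i \dot h_i = (h_i^{rest} - h_i) + \psi_{ie}(h_i)\, I_{ie} +
  \psi_{ii}(h_i)\, I_{ii},$$
$$\ddot I_{jk} = -2\gamma_{jk} \dot I_{jk} - \gamma_{jk}^2 I_{jk}
  + e\,\Gamma_{jk}\gamma_{jk}\,\bigl(N_{jk} S_k(h_k) + p_{jk}\bigr),$$

with the sigmoidal population firing rate
$S_q(h) = S_q^{max}\,[1 + \exp(-\sqrt2\,(h-\mu_q)/\sigma_q)]^{-1}$
and the reversal weighting
$\psi_{jk}(h) = (h^{eq}_k - h)/|h^{eq}_k - h^{rest}_j|$, which is $+1$
($-1$) for excitatory (inhibitory) synapses at the target's resting
potential and changes sign exactly at the reversal potential.  The
$e = \exp(1)$ factor normalizes the synaptic impulse response so an
isolated PSP peaks at exactly $\Gamma_{jk}$ mV a time $1/\gamma_{jk}$
after the impulse; this is verified to 0.1 % by the test suite.  The
excitatory soma potential $h_e$ is the model's EEG proxy.

Two conventions deserve emphasis, because the subscript order is a
recurrent source of confusion in this model family:

* $p_{ee}$ and $p_{ei}$ are the *excitatory and inhibitory
  extracortical (thalamic) pulse densities arriving at the excitatory
  population*.  The swept plane is therefore an excitation–inhibition
  balance axis for the e-population, with $p_{ie} = p_{ii} = 0$ by
  default.
* All integration is done in ms (parameters are per-ms), and Lyapunov
  exponents are reported in s$^{-1}$, base $e$, by multiplying per-ms
  rates by 1000.

Assumptions inherited from the macrocolumnar reduction: spatial
homogeneity (no long-range propagation or multi-column coupling), no
stochastic input, and instantaneous sigmoidal rate conversion.

## Parameter sets

`lileyParameters()` validates the full 28-value physiological
parameterization (positivity of time constants, rates, spreads and
amplitudes; reversal potentials ordered about rest; non-negative counts
and inputs).  Two TOML fixtures ship with the package:

* **chaos2013** — a transcription of the macrocolumn set used in the
  published four-dimensional-chaos studies of the Dafilis–Liley line
  (Chaos 11:474, 2001; Chaos 23:023111, 2013), at the published
  operating point $p_{ee} = 24.2453$, $p_{ei} = 2.299$ ms$^{-1}$.  The
  original tables were not machine-readable here, so the values were
  transcribed from the secondary literature and *could not be validated
  against the published exponents* $(9.6, 0, -6.4, -11.5)$ s$^{-1}$: in
  this implementation the fixture's operating point carries a stable
  large-amplitude limit cycle rather than chaos, and the conditional
  acceptance tests that compare against the published spectrum and
  plane fractions report this discrepancy rather than hide it.  Users
  with access to the original tables should correct the fixture file
  (`inst/extdata/chaos2013.toml`) and rerun those tests.
* **plausible-demo** — a synthetic, physiologically ordered set used by
  examples and by every test that must not depend on any transcription.

## Lyapunov spectra from the reduced augmented system

Tracking the $k$ leading exponents of an $n$-dimensional flow uses
$n + kn + k$ equations (43 for $n = 10, k = 3$; 120 for the full
spectrum): the base state, $k$ tangent vectors, and $k$ accumulators
$\nu_i$.  Two backends share one engine:

* **continuous** (`computeSpectrum()`, the default): Gram–Schmidt
  orthonormalization is built into the tangent ODEs,
  $\dot e_i = J e_i - (e_i^\top J e_i) e_i - \sum_{j<i}
  [(e_j^\top J e_i) + (e_i^\top J e_j)] e_j$, with
  $\dot\nu_i = e_i^\top J e_i$, so a partial spectrum follows from a
  single augmented integration.
* **discrete** (`benettinSpectrum()`): the classic tangent-map method —
  raw tangent vectors, QR (modified Gram–Schmidt) renormalization at
  fixed intervals, logs of the diagonal norms accumulated into
  $\nu_i$.  It serves as the independent oracle; the two backends are
  required to agree within 2 % (or 0.5 s$^{-1}$ near zero) on every
  benchmark and on seeded model points.

Numerical choices, each of which was genuinely open:

* **Hard renormalization for both methods.**  The continuous form
  preserves orthonormality only to first order; drift grows roughly
  like the local exponent spread, so both backends re-orthonormalize
  every $\Delta t_{renorm}$.  The default interval is system-specific:
  10 ms for the Liley model (exponent spreads of order 10 s$^{-1}$),
  but a few tenths of a ms for the benchmark systems whose rates are of
  order 1 ms$^{-1}$ — with a 10 ms interval the drift amplifies by
  $e^{20}$ between renormalizations and the integration fails, which is
  why the interval is a property of the system rather than a global
  constant.
* **Tangent alignment discard.**  A random initial frame carries an
  $O(1)$ log-projection offset onto the Oseledec directions that decays
  only as $1/T$.  The engine integrates the augmented system for
  `tAlign` (default 20 renormalization intervals, capped at 20 % of the
  run) and then resets the accumulators, which restores the expected
  $0.1\,\%$ recovery of analytic spectra on short runs.
* **Event timing.**  The ODE library reports each output row *before*
  applying the renormalization event scheduled at that time; the engine
  accounts for this by completing the final renormalization itself and
  shifting the discrete method's time base, so the invariant
  $\lambda_i = \nu_i(T)/T$ holds exactly at the reported $T$.
* **Solver.**  `lsoda` (automatic stiff/non-stiff switching) at
  `rtol = 1e-8`, `atol = 1e-10`; these tight defaults are needed for
  exponent estimates, not for casual trajectories.  Any solver failure,
  non-finite value, or state exceeding $10^6$ marks the result
  *diverged* instead of erroring, so sweeps survive exploding orbits.
* **No zero-forcing.**  Exponents are reported exactly as computed;
  zero-exponent accounting happens only in classification via
  tolerances.
* **Run lengths.**  Defaults for a single careful point are a 10 s
  transient and a 100 s accumulation with a convergence diagnostic
  (running estimates within 2 % over the trailing 20 %); `maxTRun`
  optionally extends the run in chunks until convergence.  Sweeps use
  shorter per-point runs (5 s transient, 30 s accumulation) — a
  precision/throughput trade-off adequate for classification against a
  1 s$^{-1}$ chaos threshold, chosen once and recorded in every output.

## Classification

From an ordered spectrum (s$^{-1}$): topological dimension $D$ =
largest $D$ with $\lambda_1 + \cdots + \lambda_D \ge 0$ (0 for
all-negative spectra); Kaplan–Yorke dimension
$D_{KY} = D + (\sum_{i\le D}\lambda_i)/|\lambda_{D+1}|$, which for
$D = 3$ reduces to $3 - (\lambda_1+\lambda_2+\lambda_3)/\lambda_4$; and
labels *point* / *periodic* / *chaotic* / *chaotic_4d*.  The
four-dimensional-chaos rule is $\lambda_1 \ge$ `chaosThreshold`,
$|\lambda_2| \le$ `zeroTol`, $\lambda_1 > |\lambda_3|$: with
$\lambda_2 = 0$ this forces $D \ge 3$ and $D_{KY} > 3$, i.e. an
attractor needing at least four dimensions while having a *single*
positive exponent (distinct from hyperchaos, which has two or more and
is flagged separately).  The package runs this argument as an
executable theorem over 10⁴ random qualifying spectra.  Note the
premise uses $\lambda_2 = 0$ *exactly*: with a finite tolerance band a
slightly negative $\lambda_2$ can tip a marginal partial sum negative,
so the tolerance belongs to measurement, not to the theorem.

Thresholds: `chaosThreshold = 1` s$^{-1}$ separates chaos from
slowly-converging near-zero exponents of periodic orbits;
`zeroTol = 0.5` s$^{-1}$ accepts an exponent as zero.  The literature
this package follows states no numeric value for the latter, so it is a
package default, configurable and echoed into every output; the raw
exponents are always retained so any relabeling is lossless.

## The input-plane sweep

`runSweep()` draws $(p_{ee}, p_{ei})$ uniformly from
$(0, 30] \times (0, 10]$ ms$^{-1}$, evaluates each point independently
(per-point seed $=$ a documented Lehmer-style mix of sweep seed and
index, so results are identical under any execution order or resume),
classifies each spectrum, and reports counts and fractions of chaotic
and four-dimensional-chaotic points with exact Clopper–Pearson 95 %
intervals — the intervals are what make a scaled-down sweep comparable
to fractions measured on much larger published samples.  Diverged
integrations are recorded, flagged, and excluded from denominators;
their rate is itself a diagnostic.  An append-only checkpoint file
(17-significant-digit rows, bit-exact on re-read) supports kill/resume
with identical output.

## Benchmarks: what the synthetic systems do and do not show

The three benchmark generators have analytically known or closed-form
constrained spectra: diagonal linear systems (spectrum = the rates),
the Hopf normal form (limit cycle, $(0, -2\mu)$), and Lorenz-63 (used
only for properties that need no external truth: cross-backend
agreement and the trace identity
$\sum_i \lambda_i = -(\sigma + 1 + \beta)$, exact because the Lorenz
Jacobian has constant trace).  They run in the same ms/s unit
convention as the model, so the unit-conversion path is exercised.
They validate the exponent machinery — linear algebra,
renormalization, accumulation, ordering, conversion — but not the
physiology: passing benchmarks says nothing about whether a given
parameter transcription reproduces published brain-model dynamics,
which is exactly why the fixture-dependent checks are kept separate and
conditional.

## Degenerate inputs and edge policies

Empty spectra, unsorted spectra, and non-finite values are errors;
fewer than three exponents with a chaotic $\lambda_1$ is an error
(the four-dimensional test needs $\lambda_3$).  $D_{KY}$ of an
all-negative spectrum is 0; if every partial sum is non-negative the
dissipation is unresolved and $D_{KY}$ is `NA` with an `undefined`
attribute, never silently 0.  A sweep in which every point diverged is
an error; a fraction with an empty denominator is `NA`, not 0.
Equilibrium location reduces exactly to two equations in
$(h_e, h_i)$ (the synaptic states are closed-form at a fixed point) and
uses a damped Newton iteration with analytic 2×2 Jacobian plus a coarse
multistart grid; the model can be multistable, so the root returned is
the one reached from the given start.

## Known limitations

* The spatiotemporal (PDE) Liley model, multi-column coupling, and
  stochastic variants are out of scope, as are covariant Lyapunov
  vectors and time-series (embedding) exponent estimators.
* The chaos2013 transcription is unvalidated (see above); every
  quantitative claim tied to it is conditional and tested as such.
* Near-degenerate exponents get no special treatment; ordering ties
  break by computation order.
* Exponent estimates at sweep precision carry
  $O(0.1\text{–}1\ \mathrm{s}^{-1})$ fluctuation; classification
  thresholds absorb this by design, but fractions near a threshold are
  sensitive to `zeroTol`, which is why the tolerance is echoed into
  every result rather than fixed silently.
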