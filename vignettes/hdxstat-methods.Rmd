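---
title: "Statistical methods for differential HDX-MS in hdxstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for differential HDX-MS in hdxstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxstat)
options(hdxstat.log_level = "none")
```

## Scope

`hdxstat` analyses peptide-level hydrogen–deuterium exchange mass
spectrometry (HDX-MS) of membrane proteins measured in two or more
functional states: uptake summarisation, back-exchange quality control,
normalized-uptake (butterfly) comparisons, a pooled-standard-deviation
confidence-interval significance framework with a hybrid decision rule,
residue-level consolidation, EX1 bimodal envelope deconvolution, and the
receptor–ligand occupancy and saturation-binding computations used to
design and validate labeling experiments. A forward simulator with known
ground truth makes every stage testable end to end.

## Uptake, back-exchange and normalisation

A peptide's deuterium uptake at exposure time $t$ is the centroid mass
shift relative to its undeuterated mass $m_0$, in Da-equivalent deuterons.
Replicates are summarised per peptide × state × time as mean, sample SD
($n-1$ denominator, reported only where $n \ge 2$) and count; absent cells
are never imputed.

Back-exchange is quantified against a maximally labelled control:

$$\mathrm{BE}\,(\%) = \left(1 - \frac{m_{max} - m_0}{N \, D_{frac}}\right)
\times 100,$$

where $N$ is the exchangeable-amide count and $D_{frac}$ the deuterium
fraction of the labeling buffer. BE serves quality control only: plotted
and tabulated uptake is never BE-corrected by default (an explicitly
labelled corrected view divides by $1-\mathrm{BE}$). Values outside
$[0, 100]\%$ are reported with a warning instead of clipped, because a
negative BE diagnoses an inconsistent control or $m_0$.

Two amide-count conventions are supported because published workflows
differ and rarely state which was used: the default excludes the
N-terminal residue and prolines (`len − 1 − prolines(2..len)`); the
alternative also excludes the second residue. The labeling deuterium
fraction defaults to 0.85; a 1:6.5 dilution is compatible with slightly
different fractions depending on how the ratio is read (additive volumes
would give 86.7%), so the value is a config input rather than derived.

Butterfly comparisons normalise uptake by the maximally labelled control
per peptide, order peptides N- to C-terminal by (start, end), and negate
the second state to produce the mirror layout. Normalised values above 1
are flagged, not clamped.

## The significance framework

Per-peptide replicate SDs from both states being compared are pooled into
a single comparison-wide threshold. With $\bar\sigma$ the mean of all
available per-peptide-time SDs, $n$ the nominal replicate count and
$t_{1-\alpha/2,\,n-1}$ the two-tailed Student critical value,

$$\sigma_{ave} = \sqrt{n\,\bar\sigma^2}, \qquad
\mathrm{CI} = \bar x \pm t \cdot \frac{\sigma_{ave}}{\sqrt{n}}, \quad
\bar x = 0,$$

which algebraically reduces to $\mathrm{CI} = t\,\bar\sigma$; the identity
is asserted in the test suite. At the default $n = 3$ (df = 2, 95%
two-tailed) $t = 4.303$, and a replicate noise SD of 0.079 D puts the
threshold at $\approx 0.34$ D. All SDs with $n \ge 2$ enter the pool —
including peptides outside any region of interest — because the threshold
models measurement noise, not biology.

A peptide is called significant by the first of three rules to fire:

1. **consecutive_CI** — $|\Delta D| > \mathrm{CI}$ at two consecutive time
   points;
2. **t_test** — a two-tailed pooled-variance two-sample t-test on
   replicate uptake rejects at $\alpha = 0.01$ at two consecutive time
   points where both states have $n \ge 2$. The consecutive-points
   requirement is applied here as well, keeping the two branches parallel
   and conservative (the rule's source phrasing is ambiguous on this
   point);
3. **last_point_2xCI** — the final time point alone shows
   $|\Delta D| \ge 2\,\mathrm{CI}$, indicating an expanding difference not
   fully sampled by the time course.

The sign convention is $\Delta D = \bar D_{ref} - \bar D_{test}$, so
positive differences mean decreased exchange in the test state; the
verdict (increase / decrease of exchange in the test state) is taken from
the sign at the triggering points. If the triggering points disagree in
sign, the verdict follows the larger $|\Delta D|$ and the call is flagged
direction-unstable. Peptides with no replicated time points still
participate through rules 1 and 3 using the comparison-wide threshold.

Residue-level consolidation paints each residue with the unanimous
verdict of covering significant peptides, `mixed` on conflict, `none`
when covered only by non-significant peptides, and `no_coverage`
otherwise. Coverage percent is the union of peptide intervals over the
supplied construct length (configurable denominator, since tag regions
may or may not be counted).

## EX1 detection

Under EX2 kinetics (fast H-bond reformation) the isotope envelope shifts
gradually as a single distribution; under EX1 (slow cooperative opening)
two resolvable populations appear. `fit_bimodal()` fits the envelope on
the deuteration axis as a weighted pair of Gaussian-shaped populations
with a *shared* width,

$$I(d) \propto w\,G(d; c_{hi}, s) + (1-w)\,G(d; c_{lo}, s),$$

initialised by a coarse grid (0.25 D centre resolution, a small set of
candidate widths, weights 0.1–0.9) and refined by Levenberg–Marquardt.
The Gaussian approximation is deliberately robust to the unknown
natural-isotope convolution of real spectra; exact Poisson-binomial
shapes are available from the generator to test that robustness. The
single-population fit is always computed alongside; because the models
are nested the bimodal residual can never exceed the unimodal one (a
degenerate equal-centre fit is returned if refinement lands worse), and
the labelling $c_{hi} \ge c_{lo}$ resolves the permutation tie. Fit
failures are flagged in the result, never raised.

A peptide is called EX1 when at two or more *consecutive* time points the
fit shows separation $\ge 2.0$ D, minority fraction $\ge 0.15$, and at
least a 3-fold residual improvement over the unimodal model. No numeric
criteria exist in the HDX literature's qualitative descriptions of
bimodality, so these defaults are config-exposed. The opening rate is
estimated by regressing $-\log(1 - w_{open})$ on time through the origin.

## Occupancy and binding

Labeling experiments aim for matched (≈90%) receptor occupancy across
ligands. At micromolar receptor concentrations free ligand is measurably
depleted, so occupancy uses the physical root of the binding quadratic

$$B = \frac{(L + R + K_d) - \sqrt{(L + R + K_d)^2 - 4LR}}{2}, \qquad
\theta = B/R,$$

with the textbook no-depletion form $L/(L+K_d)$ selectable for
comparison. Depletion is the default because printed experimental designs
for high-affinity ligands (e.g. 0.34 µM total ligand against a ~5 nM
dissociation constant, 0.31 µM receptor) are only explicable with
depletion — the no-depletion occupancy would be ≈98.6%, not 90%. The
inverse, `required_ligand()`, is the exact closed form
$L = \theta R + K_d\,\theta/(1-\theta)$; the round trip is tested to
1e-10. Occupancy computations work in µM, the saturation fit in nM, with
conversion responsibilities at the interface asserted in tests.

The saturation binding fit subtracts the paired nonspecific series
(linearly interpolated when grids differ) and fits
$\mathrm{specific} = B_{max} L/(K_d + L)$ by nonlinear least squares,
initialised at the concentration nearest half-saturation and
$1.2\times$ the maximal signal.

## The synthetic-data generator

The simulator emulates the statistical structure of a two-state
membrane-transporter study: 62 peptides tiled with overlaps and gaps over
a 630-residue construct (union coverage ≈ two thirds), exposure times
0.25, 1, 10, 60 and 480 min at 25 °C, labeling fraction 0.85, triplicates
at 0.25, 10 and 60 min and single measurements elsewhere, replicate noise
SD 0.079 D (which places the pooled CI threshold near 0.34 D), and a
uniform 25% back-exchange.

Per-amide kinetics follow the Linderstrøm-Lang parameterisation
$k_{obs} = k_{int}/pf$ with a single configurable intrinsic rate
(default 100 min⁻¹ — fast relative to the first time point at pH 8 /
25 °C; sequence-dependent intrinsic-rate tables are intentionally out of
scope, with protection factors log-uniform over $10^{[1,5]}$ as the free
lever). Observed uptake applies the labeling fraction and back-exchange
as independent thinning, so the maximally labelled control sits at
$N \, D_{frac} (1 - \mathrm{BE})$ plus noise and normalised uptake is
insensitive to BE, as in real data. Replicate noise is additive Gaussian
clamped at zero; the clamp slightly biases cells whose true uptake is
near zero, which the parameter-recovery test accounts for.

Designed between-state differences (e.g. a +1.5 D destabilised region)
are specified on the *observed* uptake scale — they model the measured
effect size a difference plot reports, and recovery tests can therefore
assert the designed magnitude directly. The generator rescales protection
factors where needed so designed shifts stay below the theoretical
ceiling.

The default EX1 designation mimics a short helix on an extracellular
gate: one peptide (residues 99–109) in the test state, three unprotected
amides giving the closed population a non-zero centre (~2 D), seven
strongly protected amides carrying a six-deuteron *observed* population
separation when the segment opens, and $k_{open} = 0.025$ min⁻¹, which
puts clear two-population mixtures at the 10 and 60 min points (open
fractions 0.22 and 0.78). Because mean back-exchange would cap observed
per-amide probabilities below what a six-deuteron separation requires,
the correlated amides are taken to retain their label through quench —
per-amide BE heterogeneity that real peptides also show. Envelopes are
emitted only for EX1-designated peptides, as centroided sticks with 1%
intensity noise.

What the generator does **not** emulate: chromatographic and ionisation
artifacts, overlapping-peptide interference, deuterium scrambling,
sequence-dependent intrinsic rates, per-peptide BE variation, and
correlated (non-independent) replicate error. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
noise model, not robustness to every failure mode of real spectra.

## Numerical choices and problem sizes

- Mass constants: D–H difference 1.00628 Da, proton 1.00728 Da.
- Peptide $m_0$ for synthetic data from monoisotopic residue masses.
- Bimodal grid: 0.25 D centre resolution; candidate shared widths from
  0.4 D up to the unimodal width; SSR minimised analytically over the
  amplitude via the Gram matrix of unit Gaussians before refinement.
- Degenerate inputs: empty uptake tables summarise to empty outputs;
  all-zero envelopes are rejected at construction; missing controls mark
  normalised uptake not-computable rather than failing the run.
- Validation suites use 50-seed replications for recovery claims (EX1
  separation, designed-region recall, null false-positive rate) and 200
  simulated assays for the binding-fit recovery, sizes chosen to keep the
  whole suite around a minute while leaving Monte-Carlo error far below
  the asserted margins.
- Every stochastic draw flows from a single top-level seed recorded in
  all output headers; identical seeds yield byte-identical files.

## Known limitations

The pooled threshold assumes comparable replicate noise across peptides
(one CI per comparison, matching the single dotted band of a difference
plot); strongly heteroscedastic data would call for per-peptide
thresholds the framework intentionally does not implement. Rule 2 is
disabled wherever either state lacks replication at consecutive points.
The bimodal model's shared width biases the fitted fraction slightly when
the two populations differ substantially in width; separation estimates
are much less affected. EX1 centroid uptake enters difference profiles
unchanged (the overall centroid), which mixes population means — a
documented convention, flagged in output, rather than a hidden choice.
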