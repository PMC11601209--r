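---
title: "Competition-binding models for electrically silent pLGICs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition-binding models for electrically silent pLGICs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plgicomp)
```

This vignette is the package's own account of the science it implements:
the receptor model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions taken where more than one reasonable
convention existed.

## The two-conformation receptor model

A pentameric ligand-gated ion channel is modeled as a single protein that
interconverts between exactly two conformations: a low-affinity,
nonconductive *closed* state and a high-affinity *open* state. The open
and desensitized states of real receptors are pooled into "open": at
equilibrium both bind agonists more tightly than the closed state, and
equilibrium binding assays cannot distinguish them. Whether their agonist
affinities actually differ is an open experimental question; the model is
deliberately agnostic and should not be over-interpreted as resolving it.

The receptor carries `n_ortho` orthosteric (neurotransmitter) sites and
`n_allo` allosteric (TMD modulator) sites, five of each by default — one
per subunit of a homopentamer. Sites within a class are *identical and
independent given the conformation*: no intra-conformation cooperativity
of any kind. All cooperativity observed in simulated curves is therefore
conformational, which is exactly the point of the framework — the Hill
coefficient of a competition curve becomes a readout of affinity switching
along the titration rather than of site–site interactions.

Each ligand is described by `kd_closed` and `kd_open` (molar) and a fixed
role (orthosteric or allosteric); a ligand cannot occupy both site
classes. The ratio `kd_closed/kd_open` is its conformational preference:
agonists exceed 1, inverse agonists (such as the labeling toxin) fall
below 1, and a neutral ligand at 1 cannot bias gating at any
concentration — an invariant the test suite checks directly.

With unliganded gating constant $K_{C\rightleftharpoons O}$ (dimensionless,
> 0; around $10^{-6}$–$10^{-4}$ for resting wild-type receptors), the
gating constant with $m$ orthosteric ligands bound is

$$K_{C_m \rightleftharpoons O_m} = K_{C\rightleftharpoons O}\left(\frac{K_{D,closed}}{K_{D,open}}\right)^{m}.$$

Equivalently, the conformational statistical weights are binding
polynomials — per class, $(1 + \sum_L [L]/K_{D,L})^{n}$ — multiplied by
the conformation's intrinsic weight. `equilibrium_occupancy()` evaluates
these exactly; `enumerate_microstates()` recomputes the same quantities by
summing over every per-site ligand assignment crossed with both
conformations (15,552 microstates for a 5+5-site receptor with two
orthosteric ligands and one modulator) and exists purely as an independent
check. The two routes agree to $10^{-10}$ relative error over randomized
parameter sweeps in the test suite.

Free concentrations are molar everywhere inside the package; nM/µM inputs
are converted at the config-file layer (`read_model_config()`).

## Competition curves

`simulate_competition_curve()` reproduces the assay design: the labeled
toxin's *free* concentration is clamped (default 1 × its `kd_closed`, the
`label_level` parameter), the unlabeled competitor is titrated over a
log-spaced grid, and an optional modulator is held at constant free
concentration along the whole curve. The signal is the mean number of
sites occupied by label, normalized to the zero-competitor point — a
fraction of control, matching how such curves are plotted; no plateau is
fitted at the normalization stage. The default grid is 17 log-spaced
points plus an exact zero anchor; 17 points resolve a single-component
curve over 5 decades to interpolation errors far below the noise level of
any realistic assay.

Clamped free ligand (no depletion) is the default regime because the
assays are deliberately run with receptor concentrations low enough to
make depletion negligible. `solve_free_concentrations()` is provided as an
opt-in correction: it solves the simultaneous mass balances
$free_L + R_{tot}\,occ_L(free) = total_L$ by cyclic per-ligand bisection.
Each single-ligand balance is monotone in its own free concentration, so
bisection on $[0, total_L]$ always brackets; the `uniroot()` x-tolerance
is left at the floating-point floor because the balance function can have
slope of order $R_{tot}\,n/K_D$ — for a tight binder this exceeds $10^9$,
and any coarser tolerance leaves a visible mass-balance residual. The
solver iterates sweeps until the relative residual falls below $10^{-10}$
and raises a classed convergence error (with residuals attached) at an
iteration cap.

`half_competition()` locates the 0.5-signal crossing by monotone
Fritsch–Carlson interpolation of signal against log concentration followed
by root bracketing to $10^{-6}$ relative. Monotone interpolation is
essential: an ordinary cubic spline can overshoot on steep curves and
produce spurious crossings. Degenerate inputs are first-class: a curve
that never reaches 0.5 raises a `pl_not_crossed_error` rather than
extrapolating.

Two model-level laws anchor the framework and the acceptance checks:

* an inverse-agonist competitor on a predominantly closed receptor
  half-competes at `kd_closed + [label]` — i.e. 2 × `kd_closed` under the
  1 × clamp — and fits with $n_H = 1$;
* a closed-stabilizing modulator (`kd_closed < kd_open`) can only
  right-shift an agonist curve, cannot shift an inverse-agonist curve on a
  closed receptor by more than a fraction of a percent, and has no effect
  at all when the competitor lacks an affinity switch. That last case —
  `kd_closed = kd_open` for the competitor, forcing $n_H = 1$ and
  modulator-blind curves — is the model analogue of a receptor whose
  extracellular and transmembrane domains have been uncoupled.

## Hill fitting

`fit_hill()` performs a weighted least-squares fit of
$\sum_k a_k/(1 + (c/IC50_k)^{n_{H,k}})$ to the pooled points of all
replicate curves of a condition. The lower plateau is fixed at 0 and the
amplitudes are shared across curves, because signals are normalized
fractions of control; fitted amplitude *fractions* ($a_k/\sum a$) sum to 1
by construction. Optimization runs on $\log a$, $\log_{10} IC50$ and
$\log n_H$ with the Levenberg–Marquardt solver of `minpack.lm`, an
analytic Jacobian (finite differences degenerate when a transformed
parameter sits at 0), and deterministic starting values: $IC50$ from the
half-signal crossing of the per-concentration means, $n_H = 1$, equal
amplitudes. There are no random restarts, so a fit is a pure function of
its data. Sub-unity Hill coefficients are reported as fitted, never
clamped — shallow curves are informative (slow equilibration or
heterogeneity in real data), and clamping would hide them.

Standard errors come from the inverse Gauss–Newton Hessian scaled by the
reduced chi-square, mapped back to the natural scale by the delta method.
Scaling by the reduced chi-square makes the errors robust to a
misspecified overall noise level, at the price of assuming the model shape
is adequate.

**Weights.** When a `weight` column is absent, weights default to inverse
per-concentration replicate variances — but *smoothed*, not raw. The raw
empirical variance of the handful of replicates at one concentration is an
extremely noisy quantity, and weighting points by the variance of the very
replicates being fitted both degrades the estimator and biases its
standard errors low (the points that happen to scatter tightly get
enormous weight). The package therefore regresses the per-concentration
variances on the per-concentration means — counting noise makes variance
close to linear in the mean — and uses the fitted variances, floored at
10% of their median so no weight can diverge. With this default, the
recovery simulations below show the ±2 SE interval covering the true
$IC50$ at close to its nominal rate. Noiseless or unreplicated data fall
back to unit weights, and unit weights reproduce an unweighted fit
exactly.

**Component selection.** `select_components()` fits 1..K components and
keeps the smallest model unless a larger one improves the small-sample
corrected AIC (AICc) by more than 2 *and* all of its parameter standard
errors stay below 50% of their estimates. AICc with the Δ > 2 convention
is used because no specific statistic is canonical for this assay; the SE
gate encodes the practice of rejecting components whose parameters are not
actually determined by the data. The full comparison trace is attached to
the returned fit and serialized in fit reports. Pure-noise or flat data
never reach the optimizer: a fit is refused (classed identifiability
error) when the per-concentration mean signal spans less than 0.2 — a
curve that competes away less than 20% of the signal cannot pin down a
component — and a singular covariance or non-finite standard error after
fitting raises the same error.

`fold_shift()` propagates the standard error of a ratio of two fitted
half-competition concentrations to first order (relative errors in
quadrature). First-order propagation is accurate when relative errors are
small, the regime of every fit reported here; the test suite checks it
against Monte-Carlo sampling of the fitted estimates within 5%.

## The synthetic-assay generator

`generate_assay()` emulates the structure of a radioligand competition
assay: for each of `n_curves` independent curves and `n_duplicates`
technical duplicates per concentration, bound label is drawn as a Poisson
count with mean `count_scale * (bg + (1 - bg) * signal)`, then converted
back to the signal scale. Poisson noise is the natural choice because the
measurement is a radioactive count; the defaults — `count_scale = 2000`,
`background_fraction = 0.02`, duplicates, three curves per condition —
correspond to ~1-minute gamma-counter measurements of well-washed pellets
with a small residual nonspecific background, assayed in duplicate with a
few independent curves per condition.

The returned signal is *specific* binding: the expected background
fraction is subtracted before each curve is normalized to its own
zero-competitor mean, mirroring how nonspecific binding measured on
mock-transfected cells is removed in the real protocol. Without this
correction the dataset floor would sit at `background_fraction` while the
fit model (and fraction-of-control plots) assume a zero lower plateau — a
built-in misspecification that would bias every fit. The background still
contributes its counting noise; only its mean is removed.

All randomness flows through one seeded generator (`with_seed()`), which
restores the caller's RNG state afterwards; identical seeds reproduce
identical datasets bit for bit. An optional curve-level multiplicative
variance component (day-to-day variability) was considered and left out:
its magnitude is unknown for these assays, and silently inflating
replicate agreement would make the generator's calibration claims
unfalsifiable. What the generator does *not* emulate, and what passing
tests therefore do not certify about real data: slow equilibration
(incubations that do not reach equilibrium flatten curves), cell-number or
protein-content normalization beyond a scale factor, pipetting drift
across a titration, and day effects. Recovery results on synthetic data
are a check of the estimator's internal calibration, not a validation
against wet-lab variance structure.

`generate_toy_alignment()` plants deletion and insertion columns at exact
reference positions with an exact number of affected rows, so the indel
classifier can be tested against a known design (and recover it
round-trip).

## Indel profiling

`classify_columns()` implements a reference-anchored column
classification: with $x$ the number of rows carrying a residue in a
column of an $n$-row alignment, a full column ($x = n$) carries frequency
0; otherwise the column is a *deletion* column if the reference row has a
residue (frequency $(n - x)/n$) and an *insertion* column if it does not
(frequency $x/n$). Both frequencies are bounded by $(n-1)/n$ — 71/72 =
0.986 for a 72-sequence alignment. Ambiguity characters (X, B, Z) count
as residues: they represent an amino acid of uncertain identity, not the
absence of one. Both `-` and `.` are accepted as gaps; all-gap columns
are rejected rather than silently classified, since they cannot arise in
a sensibly trimmed alignment.

`trim_to_reference()` cuts the alignment to the window from the column of
the reference's first requested residue to that of its last (e.g. the
mature protein), keeping interior insertion columns and discarding
flanking columns where the reference is gapped. Flanking reference-gap
columns outside the window are genuinely outside the reference's span, so
including them would create insertion calls with no anchor coordinate.

`indel_profile()` maps columns to reference coordinates (1-based on the
trimmed reference; an `offset` lets results be reported in precursor
numbering, e.g. mature residue 1 = precursor 23) and extracts maximal
*indel-free stretches*: a reference position is interrupted when its own
column is a deletion column, and a stretch breaks between positions $p$
and $p+1$ when an insertion column lies between them. This is the minimal
reading of "uninterrupted by indels" — a deletion interrupts *at* the
position it removes, an insertion interrupts *between* its flanking
positions and belongs to neither. Region annotations (binding-site loops,
transmembrane segments, the pre-M1 linker) are supplied as a user file of
labeled intervals and overlapped onto stretches at export time; nothing
is hard-coded, because annotation boundaries are themselves
convention-dependent.

The package consumes alignments (FASTA or Clustal via `seqinr`); it does
not run an aligner, and column-level results are only as good as the
alignment they come from. Reproducing any particular published column
count or stretch length additionally depends on the sequence set, sequence
database versions, and aligner build, none of which the package controls.

## Problem sizes and runtime envelope

The test suite builds every fixture in code. The heavier checks use: 100
random parameter draws for the closed-form-vs-enumeration sweep (15,552
microstates each); 100 seeded synthetic datasets (18 concentrations × 2
duplicates × 3 curves) for the ±2 SE coverage check, with coverage
required in ≥ 90 of 100; $10^5$ Monte-Carlo draws for the fold-shift SE
comparison; and 1000 duplicates for the law-of-large-numbers check of the
noise model. These sizes keep the full suite within a few seconds while
leaving each statistical check enough resolution to fail visibly if the
underlying code regresses.

## Known limitations

* Two conformations only; desensitization is not separable from opening
  at equilibrium, and no kinetics (time courses, incubation length,
  pore-block trapping dynamics) are modeled.
* Sites within a class are strictly identical and independent;
  heteromeric receptors with nonequivalent sites are out of scope.
* The Hill equation is used as a descriptive readout, as in the assays
  it mirrors; the mechanistic model is never fitted directly to data.
* First-order error propagation for fold shifts assumes small relative
  errors; for fits with relative SEs above ~20% the Monte-Carlo route
  should be preferred.
* The indel analysis trusts its input alignment; it quantifies indels
  relative to one chosen reference row and has no notion of alignment
  uncertainty.
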