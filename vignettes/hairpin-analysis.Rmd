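---
title: "Models and methods: DNA hairpin force spectroscopy and conformer ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DNA hairpin force spectroscopy and conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpintools)
```

# The scientific problem

Integron *attC* recombination sites function as single-stranded DNA
hairpins. The same strand can fold into more than one conformation: the
canonical *straight* hairpin, in which the paired R boxes (R''/R') and L
boxes (L''/L') stack in register, and a *kinked* hairpin, in which the L
arm pairs out of register into the terminal structure. The two folds are
nearly isoenergetic, so both are populated at equilibrium, and they can
be distinguished mechanically: pulled from its ends, the hairpin unfolds
in two steps, and the contour length released by the final (major) step
reports the size of the apical stem that survived as a mechanically
stable intermediate — about 35 nt for the straight fold and 28 nt for
the kinked one.

`hairpintools` implements the full analysis chain around this idea:

1. worm-like-chain (WLC) elasticity of the tethered construct
   (`wlc_force()`, `construct_extension()` and friends),
2. unfolding-event detection and WLC segment fitting of force-extension
   traces (`detect_events()`, `fit_segments()`, `analyze_major_event()`),
3. Gaussian-mixture analysis of the bimodal contour-length-change
   distribution (`fit_bimodal()`, `assign_conformer()`),
4. a DNA secondary-structure folding engine with suboptimal-window
   enumeration (`fold_mfe()`, `subopt_window()`),
5. conformer classification and Boltzmann occupancies
   (`classify_conformation()`, `boltzmann_occupancy()`),
6. a batch screen over annotated sites (`screen_sites()`), and
7. simulators that generate the synthetic test substrate
   (`simulate_pull()`, `generate_cohort()`, `generate_attc_like_site()`).

The pipeline verbs a command-line tool would expose (simulate,
analyze-traces, populations, fold, classify, screen, demo) map one to
one onto the exported functions above; `run_demo()` chains them end to
end. In an R-native analysis package a shell wrapper would only obscure
the pipe-friendly interface, so the functions *are* the interface.

# Polymer elasticity

Each elastic element is an inextensible Marko-Siggia WLC,

$$F(x) = \frac{k_B T}{p}\left(\frac{1}{4}\left(1 -
\frac{x}{L}\right)^{-2} + \frac{x}{L} - \frac{1}{4}\right),$$

with persistence length $p$ (nm) and contour length $L$ (nm);
$k_B = 0.0138065$ pN nm/K and the default temperature is 298.15 K
everywhere (`hp_constants`). The tether is a serial circuit: dsDNA
handles of fixed 580 nm contour, plus — once the hairpin has (partly)
unfolded — ssDNA with $p_{ss} = 2$ nm and 0.68 nm of contour per
nucleotide. A folded hairpin contributes a fixed 2 nm end-to-end
distance instead. The extensible (stretch-modulus) correction is
deliberately omitted: at the forces of interest (< 10 pN) enthalpic
stretching is negligible and the inextensible form is the model the
analysis is built on.

**Inversion.** `wlc_extension()` does not iterate a bracketed root
search: substituting $u = 1 - x/L$ turns the Marko-Siggia relation into
the cubic $4u^3 + (4f-3)u^2 - 1 = 0$ (with $f = Fp/k_BT$), which has
exactly one root in $(0,1]$. We take that root in closed form and polish
it with two Newton steps, giving machine-precision round trips at vector
speed. `construct_force()` inverts the serial extension with damped
Newton iteration safeguarded by an interval bracket; the returned force
reproduces the requested extension to below $10^{-6}$ nm.

**Handle persistence length.** Fitted handle persistence lengths in
bead-tether assays are commonly far below the dilute-solution ~50 nm;
the package treats $p_{dsDNA}$ as a free per-tether fit parameter
(simulated tethers draw it from 20-27 nm) and takes no position on the
physical origin of the depression.

# Trace analysis

## Event detection

The force channel is smoothed with a Savitzky-Golay filter (polynomial
order 3, default window 51 samples). Rips are found with a
trend-cancelling double difference
$d_i = f_{i+h} + f_{i-h} - 2 f_i$ (with $h$ = half window): a force step
of size $D$ contributes $\mp D$ to $d$ regardless of the smooth loading
slope, which cancels exactly. Candidate runs are merged and each yields
one event at the steepest smoothed slope. Events below the 1 pN
reliable-detection floor are flagged `unassigned`; among the rest the
deepest step is the `major` event. The default threshold of 0.5 pN is
several times the smoothed noise floor at the simulated conditions.

## Segment fitting

Fits minimise force residuals against the force balance
$F = k_{trap}\,(s - \xi_{construct}(F))$ evaluated at the measured trap
separations $s$ — not in the extension coordinate
$s - F/k_{trap}$. The distinction matters: the separation is a commanded,
noise-free quantity, whereas an extension computed from the measured
force carries the force noise onto the abscissa (errors-in-variables),
which biased recovered contour-length changes by about 1 nm at the
simulated noise level. Two further numerical choices keep the estimator
unbiased at that noise level:

* the response is the smoothed force (the filter reproduces the smooth
  loading curve essentially exactly away from rips; squared raw noise
  otherwise biases the nonlinear least squares), and
* segments keep a 40-sample guard band around each rip, wider than the
  filter half-window, so smearing of the step never enters a fit.

The folded (pre-event) segment uses the handles-only model with the
known 2 nm closure offset and a free persistence length. Unfolded
segments share that persistence length and fit one free ssDNA contour
length each; only samples above the 2 pN fit floor (WLC fitting is
unstable below) and more than 0.5 pN below the next rip are used.

The contour-length change of an event is the difference of the ssDNA
contours fitted after and before it. For the first event out of the
fully folded state, the 2 nm closure is subtracted, so complete
unfolding of an $n$-nt hairpin reads $0.68n - 2$ nm (e.g. 41.52 nm for
64 nt) while internal steps read $0.68\,\Delta n$ nm (23.8 nm for the
35-nt apical stem) — the conventions `delta_L_to_nucleotides()` and
`expected_delta_L()` implement.

## The major event of a two-step unfolder

At the study conditions the minor (folded to intermediate) step changes
the force by only ~0.25 pN — the hairpin's first step is a shallow,
hump-like feature that often cannot be called reliably (in the
experiments this work models it was visible in a small minority of
traces). `analyze_major_event()` therefore uses a two-pass scheme: the
major rip is located at a robust threshold, the region before it is
re-scanned at a sensitive threshold, and the *last* candidate before the
rip bounds the pre-rip segment. Whatever that candidate is — the true
minor step or a noise excursion — the segment between it and the major
rip is in the intermediate state, so the major contour-length change is
measured between two well-defined states. Both flanking segments are
fitted jointly (`first_segment = "combined"`): for a trial persistence
length each segment's best ssDNA contour is obtained from a closed-form
extension profile refined by Gauss-Newton on the exact force-balance
residuals, and the persistence length minimising the pooled residual is
kept. A single segment leaves $p$ and $L_{ss}$ nearly degenerate; the
joint profile over segments with different force ranges pins both.

On simulated two-step pulls at experiment-level noise this recovers the
major contour-length change with bias below 0.1 nm and a standard
deviation of about 0.3 nm per pull.

# Conformer populations

`fit_bimodal()` fits a two-component univariate Gaussian mixture by
expectation-maximization: unequal variances (the two populations have
different widths), means initialised at 20.3 and 24.1 nm, at most 500
iterations, tolerance $10^{-8}$ on the log-likelihood, and no random
restarts — the fit is deterministic given data and initialisation, and
the log-likelihood trajectory is stored so its monotonicity is
assertable. Collapsing components are floored at 0.05 nm with a warning.
Population percentages are mixture weights, not histogram counts; the
0.5 nm histogram binning in `autoplot()` is presentation only.
`filter_first_pulls()` restricts an event table to the first unfolding
per tether, the subset that tests whether refolding under residual force
biases the conformer distribution.

# The folding engine

`fold_mfe()` and `subopt_window()` implement a Zuker-style dynamic
program over a nearest-neighbor DNA energy model: unified Watson-Crick
stack enthalpies and entropies plus G·T wobble stacks, a monovalent-salt
entropy correction of $0.368\,\ln[\mathrm{Na^+}]$ cal/(mol K) per stack
(default 0.25 M Na$^+$; Mg$^{2+}$ is accepted but not modelled and is
0 M under the default conditions), hairpin/bulge/internal loop penalties
interpolated from tabulated sizes with Jacobson-Stockmayer extrapolation
beyond 30 nt, a 0.3 kcal/mol·nt internal-loop asymmetry penalty capped
at 3 kcal/mol, an affine multibranch term (3.4 + 0.4 per branch + 0.1
per unpaired nt, kcal/mol) and a terminal penalty for helix-end A·T and
G·T pairs. Loop penalties are treated as purely entropic (scaled by
$T/310.15$). Energies are reported in kJ/mol.

Structural rules: hairpin loops of at least 3 nt, no pseudoknots,
isolated single pairs disallowed (every helix stacks at least twice —
enforced globally through a dedicated helix-start matrix), interior
loops capped at 30 unpaired nt. Suboptimal enumeration is best-first
backtracking over the same canonical recurrences: each partial state
carries the exact energy of its decided loops plus matrix lower bounds
for its open intervals, so structures emerge in non-decreasing energy
without duplicates, banded at
$|\Delta G - \Delta G_{MFE}| \le w\,|\Delta G_{MFE}|$ (default $w$ =
0.05, cap 50 structures, only $\Delta G \le 0$).

For every sequence up to 25 nt in randomized suites the engine's MFE
*and* the complete window contents equal a brute-force enumeration of
all admissible pairings scored by the same decomposition — the
enumeration code lives in the test helpers and shares nothing with the
dynamic program but the scoring function, which itself is validated by
the additivity check `structure_energy()`.

Absolute energies from any nearest-neighbor implementation are
version-dependent; published ensemble energies for a given site will
differ in detail. Nothing downstream depends on the absolute scale:
classification uses pair geometry, occupancies use energy
*differences*, and tool-exact reproduction is supported by importing CT
or dot-bracket files (`read_ct()`, `read_dotbracket()`, the `import`
argument of `screen_sites()`).

# Classification and occupancies

`classify_conformation()` applies a five-group decision table driven by
an `attc_annotation()` (box intervals, UCS positions, extra-helical
bases):

| R box fully paired | L box fully paired | L register offset | class |
|---|---|---|---|
| no | — | — | `other` |
| yes | yes | 0 | `straight_complete` |
| yes | yes | ≠ 0 | `kinked_complete` |
| yes | no | 0 | `straight_incomplete` |
| yes | no | ≠ 0 | `kinked_incomplete` |

"R box fully paired" means every non-EHB position of R'' pairs into R'
and vice versa. The register offset is the modal difference between
canonical and actual partners over paired L''-positions (canonical =
k-th non-EHB position of L'' against k-th-from-last of L'); ties break
toward the smallest absolute offset, and a fully unpaired L'' counts as
canonical (such structures are straight-incomplete). Extra-helical
bases are exempt from every pairing requirement. Straight-incomplete
structures whose L box is opened from within carry a `bubble` flag —
they are structurally close to the straight fold and are counted as
canonical straight by the screen.

`intermediate_size()` returns the nucleotide span of the outermost base
pair apical of the 5'-side UCS internal loop — the stem that persists as
the mechanically stable intermediate; times 0.68 nm/nt
(`expected_intermediate_delta_L()`) this predicts the major
contour-length change (23.8 nm for 35 nt, 19.04 nm for 28 nt).
The UCS location is taken from the annotation, never inferred from the
structure, for determinism.

`boltzmann_occupancy()` converts per-structure free energies to
equilibrium probabilities with $R = 8.314$ J/(mol K) and a max-shift
for numerical stability; class probabilities are sums over members. At
25°C a 0.8 kJ/mol gap between the straight and kinked fold yields a
58/42 split, a 0.6 kJ/mol gap the reverse 44/56 — the package's
headline desk-scale numbers.

`screen_sites()` folds each annotated site on the given (bottom) strand
and its reverse complement (annotation mirrored, inner and outer boxes
swapping roles), classifies both ensembles, and summarises the mean and
SD over sites of the canonical-straight probability per strand. Sites
whose window holds no paired structure are flagged unfoldable and
excluded from the summary.

# What the simulators emulate — and what they do not

`simulate_pull()` generates quasi-static constant-velocity sweeps: 580
nm handles, a 64-nt hairpin with a 35-nt (straight) or 28-nt (kinked)
intermediate, trap stiffness 0.056-0.062 pN/nm, 200 nm/s, 50 kHz
internal sampling, white Gaussian force noise of 0.35 pN, and
block-averaging decimation by 10 on output (noise scales by
$1/\sqrt{10}$, as an instrument's anti-alias filtering would).
Transitions follow Bell kinetics,
$k(F) = k_0 e^{\pm F\Delta x^\ddagger / k_BT}$, integrated exactly along
the sweep via the cumulative hazard. The rate constants are calibration
choices, not measurements: $k_0 = 1.07\times10^{-5}$/s with
$\Delta x^\ddagger = 10$ nm puts the mean major rip at 5.7 pN (Monte
Carlo: 5.73 ± 0.51 pN), and $k_0 = 2.5\times10^{-3}$/s with 12 nm puts
the minor step at 2.8 pN (2.83 ± 0.48). The 12 nm barrier distance for
the minor step keeps that transition reliably above the 2 pN fit floor;
with a broader (smaller-$\Delta x$) distribution a large fraction of
minor steps would fall below 1 pN, which is realistic but removes the
ground truth the recovery tests need. Refolding transitions use
mirrored Bell rates so relaxation sweeps show refolding. Per pull the
conformer is drawn afresh from the mixture weights — each refolding
event is a new choice between the straight and kinked fold, which is
what makes first-pull and cumulative statistics comparable.

Not modelled: bead hydrodynamics and Brownian dynamics, drift,
crosstalk, tether offsets (the simulated separation coordinate is exact,
so fits need no offset parameter — real data would), force-dependent
refolding pathways beyond Bell, and the broad sub-1-pN tail of the
minor transition. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated physics, not robustness
to instrument artifacts.

`generate_attc_like_site()` designs sequences by constraint propagation
(union-find with complement parity) over the intended pair tables: R
helix (10 bp), asymmetric UCS internal loop (4 + 2 nt), L helix (14 bp)
and VTS loop (7 nt), giving the 35-nt apical span of the straight fold;
stems are sampled GC-rich and loops AT-rich to suppress spurious
registers. Options add an extra-helical bulge in R', G·T wobbles in the
R helix (which become A·C mismatches on the reverse complement — the
mechanism by which bottom and top strands of the synthetic cohort fold
differently), or a competing helix shifted by 3 nt into the VTS/UCS for
kinked ensembles. Every design is verified by folding: the default must
give a straight-complete MFE with the designed apical span, the shifted
design at least one kinked-complete structure in the window; failed
draws are resampled. Wobble-biased cohort sites omit the EHB bulge:
under this energy model the bulge penalty plus weakened wobble stacks
tips the canonical register below competing folds, so the two features
are exercised in separate fixtures.

# Problem sizes in the shipped test suite

The suite regenerates all data: a 65-tether × 7-pull cohort (~455
traces) for the mixture-recovery check, a 150-pull Monte Carlo for the
rip-force calibration, 60 single-rip pulls for randomized
contour-change recovery, randomized brute-force folding suites up to 25
nt, and site cohorts of 5-6 sequences for the strand-direction screen.
These sizes are chosen so the whole suite re-derives every claim in
minutes on one core while keeping estimator standard errors several
times smaller than the tested tolerances.

# Known limitations

* The energy model is a single published-parameter family; it supports
  no Mg$^{2+}$ dependence, no coaxial stacking, no sequence-dependent
  hairpin-loop bonuses, and treats loop entropies as temperature-scaled
  constants. Imported structures are first-class citizens for that
  reason.
* Kinked geometries are recognised purely from pairing registers; no
  3D model of the kink is implied.
* The trace pipeline assumes single-tether records with known trap
  stiffness and an offset-free separation coordinate.
* Conformer assignment from a contour-length change is probabilistic;
  near the posterior crossing (~21.5 nm under default fits) single
  events cannot be attributed with confidence.
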