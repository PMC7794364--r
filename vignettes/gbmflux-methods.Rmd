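---
title: "Constraints-based comparison of drug-sensitive and drug-resistant cell-line metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraints-based comparison of drug-sensitive and drug-resistant cell-line metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmflux)
```

## The model and its assumptions

`gbmflux` analyzes metabolism at steady state. A metabolic network with $m$
metabolites and $n$ reactions is summarized by its stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$; a flux vector $v$ (mmol/gDW/h) is feasible
when

$$S v = 0, \qquad v^{\min}_i \le v_i \le v^{\max}_i .$$

Flux balance analysis (FBA) maximizes a linear objective $Z_0 = \max c^T v$
over this polytope — here the biomass reaction of a contextualized model.
Because FBA optima are almost never unique, the package characterizes models
by the *set* of feasible fluxes rather than a single vector:

* **Flux variability analysis (FVA)** computes, per reaction,
  $\min / \max \{ v_i \}$ subject to the constraints above plus
  $c^T v \ge \gamma Z_0$. The control parameter $\gamma \in [0, 1]$ selects
  the optimal face ($\gamma = 1$, the default when an objective is set) or
  progressively sub-optimal network states ($\gamma < 1$); $\gamma = 0$
  drops the objective constraint entirely.
* **Hit-and-run sampling** draws (near-)uniform points from the polytope so
  per-reaction flux *distributions*, not just ranges, can be compared.

Assumptions worth stating explicitly: the cell is at metabolic steady state
over the measurement window; measured exchange rates are representative of
that window; enzyme lesions act through capacity (bound) reductions rather
than kinetic changes; and no thermodynamic (loopless) constraints are
imposed.

## Contextualization of a cell line

`contextualize_cell_line()` applies constraints in a fixed, tested order;
the order is part of the contract because the stages do not commute in
general (the oxygen cap depends on the exchange constraints, the
enzymopathy contraction depends on everything before it):

1. **Biomass.** `build_biomass()` drains one pseudo-metabolite per
   macromolecule class with coefficients equal to the dry-weight fractions.
   Defaults: protein 0.70, lipid 0.20, RNA 0.08, DNA 0.02 g/gDW. The DNA
   fraction scales with the karyotype (`chromosome_count / 46`), and the
   remainder is re-absorbed proportionally by RNA and lipid while protein is
   held fixed — the conversion from chromosome units to a mass fraction is
   this package's documented rule, since only the ploidy itself is an input.
2. **Exchange constraints.** Each measured metabolite exchange is bounded to
   `rate ± (|rate| · tolerance_band + tolerance_abs)`, negative = uptake.
   Exact equality constraints on measured rates routinely make models
   infeasible, so the default band is 5%; the absolute term exists because
   rate estimates near zero have an absolute, not relative, error floor.
3. **Growth.** The biomass flux is fixed to the measured growth rate within
   a 2% band.
4. **ATP maintenance.** A fixed ATP-hydrolysis flux (default 1.07
   mmol/gDW/h) representing non-growth energy demand.
5. **Oxygen-uptake cap.** Mode `fba_max` (default) caps oxygen uptake at the
   FBA-maximal feasible uptake of the model built so far; a `fixed` mode
   accepts a measured value instead. Whether the cap should sit exactly at
   the FBA maximum is genuinely open; it is configurable.
6. **Redox probes.** A pseudo-hypoxia reaction
   (`nad[c] + h2[c] -> nadh[c] + h[c]`) pushes the cytosolic redox state
   toward NADH; an NADH-oxidase probe
   (`nadh[c] + h[c] + ½ o2[c] -> nad[c] + h2o[c]`) measures, via its
   maximal flux, the model's capacity to re-oxidize cytosolic NADH. The
   oxidase stoichiometry is a package choice (a standard oxidase); only the
   pseudo-hypoxia reaction string is fixed by convention.
7. **Enzymopathy constraints.** Mutations with predicted-deleterious
   probability ≥ 0.95 inactivate their genes; a reaction is impaired when
   its gene-protein-reaction rule (``and`` = complex subunits, ``or`` =
   isozymes) evaluates false. Each impaired reaction's bounds become

   $$[\,v_{\min},\; v_{\min} + f \cdot |v_{\min} - v_{\max}|\,], \qquad f = 0.25,$$

   where $(v_{\min}, v_{\max})$ is the reaction's FVA range in the
   *unaltered* model — the model as of stage 6, before any mutation
   constraint. Anchoring at $v_{\min}$ is deliberate and literal; for
   reversible reactions it biases flux toward the reverse direction, and a
   `symmetric` mode that keeps the middle quarter of the range is available.
   Because the new upper bound never drops below $v_{\min}$, this stage can
   never by itself make the model infeasible. Applying it twice without
   recomputing the reference FVA is idempotent; re-supplying a freshly
   computed FVA would contract again.

Every stage re-checks feasibility and an infeasible model is reported with
the name of the stage that introduced it.

## The sampler

`achr_sample()` implements artificial-centering hit-and-run. Warmup points
combine *orthogonal* points — the FVA-extreme solutions from ±unit
objectives, de-duplicated — with *random* points drawn as flat-Dirichlet
convex combinations of those extreme points. Convex combinations rather
than random-objective LP solutions are used because LP solutions land only
on vertices: small polytopes have few of them, and a vertex-only cloud has
no interior spread.

Each chain step picks a random warmup point, takes its difference from the
running center (updated after every step) as the direction, projects the
direction onto an orthonormal basis of $\mathrm{null}(S)$ so the equality
constraints hold by construction, and jumps to a uniformly drawn point on
the feasible chord. Every `thinning`-th point is stored. The default
protocol — 1000 warmup points, 50,000 stored samples, 1000 steps between
stored points — matches the study protocol this package reproduces.

Numerical points that matter (all discovered by the test suite's
feasibility assertions, and all handled in code rather than by loosening
the assertions):

* Coordinates pinned by their bounds (`ub − lb ≤ 1e-9`) are excluded from
  the chord computation: direction components there are rounding noise, and
  a `0/tiny` ratio collapses the chord.
* After the bound clamp, the point is re-projected onto $\mathrm{null}(S)$
  *every step*. A clamp moves the point off the steady-state plane; left
  uncorrected the error feeds back through the running center and grows
  multiplicatively. With per-step projection the residual stays at machine
  precision ($\max |S v| \sim 10^{-13}$ after $2 \times 10^5$ steps).
* Directions with norm below $10^{-8}$ are rejected as noise; a step whose
  chord degenerates is counted in the diagnostics and the chain stays put.

Sampling uses R's RNG, so a seed in `sampler_config()` makes runs
bit-reproducible. Diagnostics report degenerate and clamped steps; no
formal convergence proof is attempted.

## Rates from time courses

`fit_gompertz()` uses the standard three-parameter Gompertz form
$N(t) = K \exp(\ln(N_0 / K) e^{-\mu t})$ (optional lag), fitted by
Levenberg–Marquardt with a deterministic initialization. When all counts
are positive the residuals are taken on the log scale, matching the
multiplicative error of cell counting; with 5% multiplicative noise this
recovers $\mu$ within 10% in 99 of 100 seeded replicates, versus roughly 60
of 100 for natural-scale residuals.

Consumption-and-release (CORE) values are signed endpoint differences
$C_{t_1} - C_{t_0}$ (default 0 and 96 h). The conversion to a
biomass-specific rate is

$$\text{rate} = \frac{\Delta C \cdot V}{\int_{t_0}^{t_1} X(t)\, dt},
\qquad X(t) = N(t) \cdot w_{\text{cell}},$$

with $V$ the culture volume and $w_{\text{cell}}$ the dry weight per cell
(default 400 pg, a typical adherent mammalian cell). The integration scheme
and both constants are package choices, stated rather than hard-coded.

## The differential report

`diff_models()` compares two contextualized models: FVA span widths and
their ratio, range overlap, a direction-flip taxonomy
(`bidirectional->forward`, `bidirectional->reverse`, sign flips), a
distribution-shift statistic per reaction, correlated reaction sets
($|r| \ge 0.99$ over the samples, connected components with signed edges),
and a subsystem rollup. The shift statistic is
$1 - \sum_b \min(p^A_b, p^B_b)$ on bin edges shared by both samples — 0 for
identical distributions, 1 for disjoint supports, symmetric in its
arguments; a Kolmogorov–Smirnov variant is available behind a flag. No
p-values are produced: ranking plus reseeded-null comparison is the
inference surface, since the underlying protocol reports no test.

One identifiability point shapes how recovery is asserted: a capacity
lesion on a linear pathway backbone contracts *every* reaction that mass
balance ties to it by exactly the same factor (on the bundled template, the
oxygen transport and exchange and the water sink move 1:1 with the
respiratory reaction). Span ratios therefore localize lesions to a coupled
pathway, not to a single reaction — the mutation table, through the GPR
rules, supplies the finer localization. The end-to-end tests assert
detection (the planted reaction's span ratio < 0.5 and shift above the
median) and pathway localization (the lesioned subsystem has the smallest
median span ratio).

## What the synthetic data emulate — and what they do not

`make_toy_network()` produces polytopes with closed-form FVA ranges (chain,
branch, cycle, parallel-drain simplex) and seeded flux-consistent random
networks built from a reference flux vector, so feasibility is guaranteed
by construction rather than rejection.

`make_paired_scenario()` emulates a paired sensitive/resistant design on a
curated ~40-reaction core template: glycolysis, lactate fermentation,
pyruvate oxidation, a lumped respiratory chain (complex-I gene in an
``and`` rule, so one deleterious hit impairs it), ATP maintenance,
macromolecule synthesis from glucose and 19 amino acids, and the cofactor
pools the redox probes need. The two cell lines share the template and
differ in growth rate, exchange rates and mutations. Reference fluxes are
solved in closed form from the steady-state balances given a growth rate
and a Warburg split $\phi$ (fraction of glycolytic pyruvate routed to
lactate), so the truth record never passes through the LP machinery it is
used to test.

Default study conditions, chosen once on biological grounds: growth 0.035
vs 0.015 /h (doubling ~20 h for the fast, sensitive-like line A vs ~46 h
for the resistant-like line B); $\phi$ 0.8 vs 0.6 (A secretes more lactate
*and* respires more, which requires a higher total ATP turnover — delivered
by A's higher growth-associated protein synthesis cost, 30 ATP per unit
protein); karyotypes 44 vs 46 chromosomes; ATP maintenance 1.07 mmol/gDW/h
for both; 21 exchange-constrained metabolites (glucose, lactate, 19 amino
acids) with oxygen capped separately. With these conditions line B's
maximal oxygen uptake is below line A's even before the planted complex-I
lesion contracts it further.

`make_timecourses()` generates 5-point (0–96 h, 24-h interval) growth and
concentration series: Gompertz counts (inoculum $10^4$, capacity
$1.2 \times 10^6$ cells), concentrations integrating the planted rates
against the growth curve in a 0.5 mL volume, initial concentrations of
consumed metabolites at 1.3× the 96-h drawdown (media formulated near
demand, keeping the signal above measurement noise), multiplicative noise
with configurable CV. End-to-end tests run at CV 0.02 with exchange bands
sized to roughly 4σ of the rate estimator (15% relative + 0.005 mmol/gDW/h
absolute).

What passing these tests does **not** show about real data: the template is
a stylized core network, not a genome-scale reconstruction; real
exometabolomics has metabolite-specific, often non-multiplicative error and
unmeasured exchanges; real mutation calls carry false positives that the
deleterious-probability threshold only partially absorbs; and intracellular
kinetics, regulation and compartment-specific cofactor pools are entirely
outside the steady-state formalism.

## Numerical choices

* **LP backend.** All flux LPs run through `solve_lp()`, a thin interface
  over the package's dense bounded-variable two-phase simplex (compiled,
  Dantzig pricing with a Bland's-rule fallback). The problems here are
  small (tens to a few hundred reactions) and dense; the backend solves
  them in ~0.1 ms and was fuzz-validated against an independent pure-R
  simplex on 300 random flux polytopes (0 disagreements at $10^{-6}$).
  Infeasibility and unboundedness are reported as statuses, never coerced.
* **Tolerances.** Steady-state and bound tolerance for stored samples
  $10^{-6}$ (configurable); LP pivot tolerance $10^{-9}$; FVA oracle
  agreement asserted at $10^{-6}$.
* **Degenerate inputs.** Flat growth curves return $\mu = 0$ directly (any
  $\mu$ fits a constant); constant-vs-constant flux distributions compare
  to shift 0, never NaN; zero-width spans compare with ratio 1 (both zero)
  or Inf (one zero).
* **Problem sizes.** The test suite runs FVA-oracle checks on ≤ 10-reaction
  networks, uniformity checks at $10^4$ samples on 1–3-dimensional
  polytopes, the full default sampling protocol (1000 / 50,000 / 1000) on a
  5-reaction toy, and 20-seed end-to-end recovery on the ~40-reaction
  paired template — sizes at which every ground truth is analytic or
  independently computable.

## Known limitations

Lower bounds must be finite (free reactions are bounded at ±1000 by
convention). The sampler provides diagnostics, not convergence guarantees;
heavily elongated polytopes may need more thinning than the default.
`span_ratio` is infinite when a reaction is pinned in one model only;
downstream summaries filter non-finite ratios. Transcriptome-based
contextualization (GIMME/iMAT-style), parsimonious FBA, quadratic
objectives and loopless constraints are out of scope.
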