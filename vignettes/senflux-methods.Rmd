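---
title: "senflux methods: expression-constrained flux profiling of senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{senflux methods: expression-constrained flux profiling of senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senflux)
```

# Overview

`senflux` asks a simple question of transcriptomic data: *which metabolic
fluxes change when cells become senescent, and which interventions would push
them back?* It answers it with constraint-based modeling. Expression is
turned into enzyme capacity bounds on a stoichiometric network, per-sample
flux profiles are computed by flux variability analysis (FVA), and standard
differential statistics, meta-analysis, pathway scoring, and in-silico
knockouts run on top of the flux matrices instead of the expression matrix.

This vignette documents the model, the statistical choices, and the rationale
behind the defaults, in the order the pipeline applies them.

# The metabolic model

A `metabolic_model` is a stoichiometric matrix $S$ (metabolites × reactions)
with flux bounds $lb \le v \le ub$, a biomass objective, an ATP demand
reaction, exchange reactions, per-reaction subsystem labels, and
gene-protein-reaction (GPR) rules. Steady state is assumed throughout:
$S v = 0$.

Reversible reactions are split into irreversible forward/backward pairs
(`split_reversible`), so every working model has $v \ge 0$. This makes
expression bounds meaningful in both directions and keeps the linear programs
well-posed; net fluxes are recovered as forward minus backward.

## GPR semantics

GPR rules are parsed into expression trees and evaluated against per-gene
abundances with

* **AND = `min`** — a complex is limited by its scarcest subunit;
* **OR = `sum`** — isozymes contribute additively.

An empty rule means "no enzymatic annotation" and yields `NA`: the reaction
keeps its default bounds rather than being silenced. Genes present in the
rule but absent from the data are treated as zero abundance, with a warning,
so that missing measurements fail conservatively (toward "off") instead of
silently unconstraining reactions.

## From expression to bounds

The capacity bound of a reaction with GPR abundance $E$ is a saturated
Michaelis–Menten ceiling:

$$V_{max} = k_{cat} \cdot E \cdot \sigma$$

`kcat` values come from a kinetics table (`default_kinetics` supplies uniform
placeholders when none are measured) and `sigma` (default 1) is a global
scale absorbing units. The growth medium is a named vector of maximal uptake
rates applied as lower bounds on exchange fluxes (uptake is negative flux
before splitting). Unbounded directions default to `1000`
(`SFX_DEFAULT_BOUND`), the conventional "infinite" bound in constraint-based
models.

## Maintenance constraints

Flux profiles for *comparative* analyses should not be computed at a single
optimum: alternative optima make individual fluxes arbitrary. `senflux`
instead constrains the model lexicographically (`apply_maintenance`):

1. maximize ATP demand, then require it to stay at $\ge 0.9$ of that optimum;
2. maximize biomass under (1), then require $\ge 0.9$ of that optimum.

The 0.9 fraction leaves slack so that FVA intervals are informative rather
than point-valued, while still anchoring the physiological state (cells must
both maintain themselves and grow near-optimally). If a sample's model cannot
satisfy a constraint, it is relaxed — biomass first, ATP second — and the
relaxation is recorded in maintenance flags that propagate into the output
manifest. The per-reaction flux summary is the **FVA interval midpoint**, a
deterministic, solver-order-independent representative of the feasible flux
range; fluxes within `1e-6` (`SFX_FLUX_TOL`) of zero are snapped to zero.

The linear programs are solved by a dense bounded-variable primal simplex
implemented in C++ (two-phase, Bland-safe), chosen so the package has no
external solver dependency. It is validated in the test suite against
`boot::simplex` and an exhaustive vertex-enumeration oracle.

# Differential flux

**Case-control.** Fluxes are compared on the $\log_2(v + \epsilon)$ scale
with limma's moderated t-statistics (`case_control_diff`). The pseudocount
$\epsilon$ is $10^{-6}$ times the mean nonzero flux, small enough not to
compress real signals but large enough to keep exactly-zero fluxes finite.
The reported effect is the $\log_2$ ratio of pseudocounted group means.
Moderation can be disabled (`moderated = FALSE`), in which case ordinary
two-sample t-tests are used; the tests verify both against `t.test` / `lm`.

**Time series.** For passage designs, `timeseries_diff` fits an ordinary
least-squares slope of flux against passage number per reaction; the slope
sign drives downstream direction calls. Biomass decline is summarized by the
Spearman correlation of *passage-level mean* biomass against passage
(`spearman_trajectory`): averaging replicates first removes within-passage
noise that would otherwise dilute a monotone trend.

# Meta-analysis

Per-study effects are combined by a fixed-effects model (`fem_combine`):
inverse-variance weights $w_i = 1/se_i^2$, combined effect
$\hat\theta = \sum w_i d_i / \sum w_i$, and
$Z = \hat\theta / \sqrt{1/\sum w_i}$. Fixed effects are appropriate here
because studies simulated (or processed) through the same pipeline share the
effect-generating mechanism; heterogeneity diagnostics are out of scope.

# Pathway differential abundance

For each subsystem the DA score is

$$DA = \frac{n_{up} - n_{down}}{n_{total}}$$

where up/down are significantly changed reactions (FDR and effect
thresholds from `run_config`). Significance uses a
**bootstrap-without-replacement conditional null**: the identities of the
significant reactions are fixed, and their subsystem labels are re-drawn $B$
times by sampling reactions without replacement from the universe. P-values
are plus-one corrected, $p = (1 + \#\{|DA^*| \ge |DA|\})/(B+1)$, so they are
never zero. Subsystems smaller than `min_subsystem_size` (default 3) get
`NA`: a DA score over one or two reactions is a coin flip. The acceptance
suite verifies the null is calibrated (≈5% of subsystems at $p<0.05$ under
label randomization).

# Knockouts and effective scores

Knockouts are performed on a **study consensus model** built from the
geometric mean expression of the study's samples (geometric, because
expression effects are multiplicative and the planted signal is a log-fold
change). Deleting a gene sets its abundance to zero and re-evaluates every
GPR; reactions whose capacity drops to zero are bound to zero.
Metabolite knockouts zero every reaction touching the metabolite. Effects
are ternary: $\mathrm{sign}(v_{ko} - v_{base})$ with tolerance
`SFX_FLUX_TOL`. Knockouts that make the maintained model infeasible are
flagged lethal and re-solved with relaxed maintenance so their flux effects
are still reported.

The **effective score** of a knockout against a differential signature is

$$s = \sum_{r \in L} e_r \cdot \mathrm{sign}(\mathrm{lfc}_r)$$

with $L$ the significantly changed reactions and $e_r$ the ternary knockout
effect. The sign convention makes *reproducing* the signature score
positively: a knockout that *decreases* flux through a reaction that went
*down* in senescence contributes $+1$ (and symmetrically for up-reactions).
A positive score therefore marks a senescence *agonist* — a perturbation
whose flux consequences recapitulate the senescent state, pointing at the
pathway whose loss drives the phenotype. Significance is a
two-sided normal tail against the empirical score background
(`norm_background_p`), justified because the vast majority of knockouts in a
genome-scale screen are signature-neutral; a robust (median/MAD) variant is
available for heavy-tailed backgrounds. Across studies, `meta_scores`
averages scores and combines p-values by signed Stouffer weighting, so
discordant directions cancel.

# Synthetic data design

`make_toy_network` builds a small network whose default state grows on a
glucose/amino-acid medium: glycolysis-like carbon backbone, ATP generation,
lipid, nucleotide and protein precursor branches feeding biomass, and
transport/exchange reactions. Everything is redundant (isozymes, parallel
routes) **except** a six-gene linear chain modeled on the mevalonate pathway
(`HMGCR`, `MVK`, `PMVK`, `MVD`, `FDPS`, `FDFT1`) feeding the lipid pool.
This is the planted truth: knocking out any chain gene is lethal, and
down-regulating the chain is the senescence signal.

`simulate_expression` draws baseline expression for the planted genes from a
**lower band** ($2^{U(4,5)}$) than other genes ($2^{U(5.6,6.6)}$). This makes
the chain's enzymes rate-limiting, so that a $-1$ log-fold-change on them
measurably reduces the biomass optimum — mimicking how flux control in real
pathways concentrates in low-capacity committed steps. Senescent samples (or
later passages, in time-series mode) multiply planted-gene expression by
$2^{\mathrm{lfc}}$ plus log-normal noise; all other genes get noise only.
The ground truth (`net$truth`) lists planted genes, affected subsystems, and
the metabolites whose knockout is expected to score as senomorphic agonists.

Everything downstream of a seed is deterministic: `with_seed` scopes all RNG
use and restores the caller's state, and `run_study`/`run_meta` derive
sub-seeds from `run_config(seed)` so identical configs give byte-identical
output files.

# Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `maintenance_fraction` | 0.9 | anchors state, keeps FVA informative |
| `sigma` | 1 | unit scale for placeholder kinetics |
| `fdr_thresh` | 0.05 | conventional discovery threshold |
| `p_thresh`, `lfc_thresh` | 0.05, 0.5 | signature membership for scores |
| `bootstrap_B` | 1000 | p-value resolution ~1e-3, seconds of runtime |
| `min_subsystem_size` | 3 | DA undefined on tiny sets |
| `SFX_FLUX_TOL` | 1e-6 | numeric zero for 1e-9-tolerance LPs |

# Limitations

* **Futile loops.** FVA is not loopless; thermodynamically infeasible cycles
  can widen flux intervals. The maintenance constraints curb but do not
  eliminate this.
* **Dense solver.** The simplex implementation stores $S$ densely; it is
  exact and fast for models up to a few thousand reactions but not tuned for
  genome-scale sparse problems.
* **Saturation assumption.** $V_{max} = k_{cat} E \sigma$ ignores substrate
  concentrations and post-transcriptional regulation; expression is a proxy
  for capacity, not rate.
* **Fixed-effects meta-analysis** assumes homogeneous true effects across
  studies; strong between-study heterogeneity would call for a
  random-effects extension.
* **Normal score background** is an approximation; with few knockouts
  (< 10) or zero spread the pipeline reports scores without p-values rather
  than fit a degenerate background.
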