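---
title: "Flux Comparative Analysis of miRNA-extended signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux Comparative Analysis of miRNA-extended signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxnetmir)
```

# The modeling problem

`fluxnetmir` predicts how an individual cell line or patient responds to a
targeted drug by simulating a personalized copy of a molecular signaling
network. The network is a qualitative Petri net: species (genes, mRNAs,
proteins, miRNAs, complexes, compounds, hallmark pseudo-objects, siRNAs)
carry non-negative token concentrations, and typed reactions move tokens
between them. One designated pseudo-object — typically `proliferation` —
accumulates signal from growth-promoting reactions and serves as the
hallmark readout. An individual is represented by initializing the gene
and miRNA-gene species with that individual's expression profile; every
other species starts at zero, so all downstream signal is generated by
the simulation itself.

Drug response is quantified by *Flux Comparative Analysis* (FCA): the
same initialized model is simulated to steady state twice, once untreated
(control) and once with the drug's inhibition spliced into its target
reactions (treatment), and the readout is compared as a fold change

$$P = \frac{\text{readout at treatment steady state}}
           {\text{readout at control steady state}}.$$

$P < 1$ means the drug cut the hallmark flux: a responder.

# The firing rule

Each simulation step processes every reaction once, sequentially in a
pinned lexicographic order of reaction ids (the update is in-place, so
reaction $i$ sees the effects of reaction $i-1$; pinning the order makes
the trajectory reproducible bit for bit). The speed of a reaction is the
mass-action product

$$S = k \cdot \prod_a C_a \cdot \prod_e C_e \cdot
      \prod_I \frac{iKd_I}{[I]} \,\Big/\, eKd,$$

with $C_a$ the reactant concentrations, $C_e$ the enzyme concentrations,
$iKd$/$eKd$ inhibitor and enzymatic dissociation constants (nM), and
$[I]$ the inhibitor concentration. Absent enzymes contribute a factor of
1, an inhibitor at zero concentration contributes a factor of 1, and an
absent $eKd$ behaves as 1 so the formula degenerates to plain mass
action. An inhibitor present at exactly its dissociation constant leaves
the speed unchanged; at twice the constant it exactly halves it.

A reaction fires only when two guards hold, both read from the *limiting*
(minimum-concentration) species, a generalization that reduces to the
single-reactant rule when there is one reactant:

1. the limiting product concentration is below the limiting reactant
   concentration (an empty product set compares as 0, so pure sinks
   always pass; this guard is what lets products equilibrate toward
   their sources instead of growing without bound), and
2. $S$ is below 0.75 times the limiting reactant concentration (the
   firing cap, which also guarantees no concentration is ever driven
   negative: every consumed reactant retains at least a quarter of its
   limiting level).

Firing adds $S$ to every product and subtracts $S$ from every consumed
reactant. Enzymes — including the gene and mRNA *templates* of
transcription and translation, which are modeled as enzyme-like so that
expression levels drive flux continuously without being consumed — are
never touched. For template-only reactions the guards read the templates
in place of the absent reactants.

# Steady state

A state is declared steady at step $t \ge 5$ when every species
satisfies $|C_{j,t} - C_{j,t-5}| \le 0.001$ (window 5 steps, absolute
tolerance 0.001 token units; both configurable via `sim_config()`). The
absolute value is deliberate: a signed test would only catch increases
and could declare an oscillating decline steady. A net in which nothing
can fire is therefore steady at exactly $t = 5$. Simulation stops at
`max_steps` (default 10000) otherwise; non-convergence is flagged on the
result and propagated as a warning by `run_fca()`, never silently
ignored.

Two readout conventions are conceivable — the hallmark's steady token
count, or the summed speed of the reactions feeding it at the final
step. `run_fca()` reports the token-count ratio as `P` (the quantity all
tests and scores are built on) and exposes the speed-based ratio as
`flux_P` for inspection.

# Drugs and dissociation constants

`builtin_drugs()` packages twelve agents with experimentally measured
dissociation constants: ten kinase inhibitors (dasatinib, erlotinib,
everolimus, gefitinib, imatinib, lapatinib, nilotinib, sorafenib,
sunitinib, temsirolimus) plus sirolimus (mTor complex II, 0.65 nM) and
LY294002 (PI3K, 210 nM). Catalogue entries are kept verbatim as
published, including the combined dasatinib target label `EPHA5/8` and
temsirolimus's pharmacologically indirect VEGFR entry; fidelity to the
source constants wins over curation. `apply_treatment()` annotates every
reaction whose enzyme list contains a drug target with an inhibitor
entry; matching normalizes names case-insensitively and strips the
phospho prefix `P-`, since drugs are specified by gene symbols while
model species may carry decorated names. Nothing but inhibitor
annotations changes, so treatments with disjoint targets commute.

The administered concentration `[I]` is a free parameter (`inhibitor_conc`)
because the simulated dose is not part of the published constants; the
inhibition factor is $iKd/[I]$, so meaningful inhibition requires
$[I] > iKd$. The package's own validation uses $[I] = 100 \times iKd$
(e.g. 220 nM everolimus), a strong but not saturating dose; doubling
$[I]$ exactly halves the targeted reaction speeds, which is what the
dose-monotonicity checks exercise.

# The miR-add-on

`extend_model()` splices validated miRNA regulation into an existing
model from two keyed tables: miRNA→target (miRT, keyed by Ensembl gene
ID) and TF→miRNA (TFmiR, keyed by miRNA ID, TransmiR style). A gene
matches when it is a miRT key *and* the model contains its mRNA (located
as the mRNA-kind product of a transcription reaction the gene drives) —
silencing needs a transcript to bind. Per new mature miRNA the extension
adds a miRNA gene (nucleus), a nuclear and a cytoplasmic miRNA species,
a transcription reaction (microprocessing collapsed into it), a
translocation and a decay reaction; per (miRNA, target mRNA) pair it
adds a silenced miRNA:mRNA complex species, a binding reaction consuming
cytoplasmic miRNA plus mRNA (RISC collapsed into a single sequestration
step), and a decay reaction for the complex. Design choices worth
stating explicitly:

* **One shared mature miRNA pool per miRNA ID** rather than one copy per
  target, so targets compete for a common pool — the biologically
  meaningful titration behavior.
* **The silenced complex decays.** A terminal accumulator would either
  never pass the steady-state test (its inflow never stops) or would
  saturate its own firing guard, after which the target mRNA
  re-equilibrates to its unsilenced level and silencing becomes a
  transient. Complex turnover makes repression a persistent sink, and
  steady-state target protein is then genuinely monotone non-increasing
  in miRNA-gene expression. Translation from complexed mRNA is zero
  (sequestration, no partial-repression coefficient).
* **TF regulation reuses the inhibition machinery.** Activating TFs
  join the miRNA transcription as enzymes; repressing TFs become
  reaction inhibitors with a dissociation constant of 1 token unit, the
  same $iKd/[I]$ law as drugs, rather than introducing negative rates.
  TF activity is proxied by the TF gene species, which carries the
  expression level.
* **Kinetics.** Created synthesis and binding reactions default to
  $k = 0.01$ (kinetic constants for such models are calibrated by
  experience rather than measured; 0.01 keeps speeds well under the
  0.75 cap at expression-scale concentrations). Translocation and decay
  default to the faster $k = 0.5$: transport and turnover must outpace
  synthesis, otherwise the nuclear pool, the free cytoplasmic miRNA or
  the silencing complex equilibrate *above* their firing guards and the
  system enters a small-amplitude guard limit cycle that never meets
  the 0.001 steady criterion. With turnover at 0.5, every extension
  species' fixed point sits strictly below its guard for concentrations
  up to several hundred token units. TF-carrying transcription gets
  $eKd = 100$ (the typical expression scale) so template-times-TF
  products stay on the same token scale as first-order rates.
* **Deterministic naming** (`miRgene:<mirna>`, `miR:<mirna>:nuc`,
  `miR:<mirna>:cyt`, `cx:<mirna>:<mRNA-id>`) makes extension output
  reproducible byte for byte and the operation idempotent: re-running
  adds nothing.

# Expression initialization and TMM

`initialize_model()` is a total reset: every concentration is set to
exactly zero, then gene species are matched by Ensembl ID and miRNA-gene
species by miRNA ID (exact string after lowercasing and stripping the
`hsa-` prefix, since identifier styles are mixed in practice).
Expression values are used directly as token concentrations — the model
is qualitative, so any monotone rescaling would cancel out of the
control/treatment ratio anyway. Unmatched features on either side are
counted and reported, never fatal.

Raw count matrices are normalized with the trimmed mean of M-values
(`tmm_normalize()`, delegating to `edgeR::calcNormFactors`): per sample
a precision-weighted mean of gene-wise log2 ratios against a reference
sample, after trimming 30% of the most extreme ratios and 5% of the
most extreme average intensities — the method's published defaults,
which this package does not revisit. Factors are constrained to unit
geometric mean; consequently a change to one library rescales all
factors by a common constant, and the per-library invariances hold *net
of* that constant. The normalized matrix is counts per million of
effective library size, so a sample's normalized values depend on no
other library.

# Sensitivity scores and cohort statistics

The model-based sensitivity score is $\log_{10}(P) + K$ with $K = 5.2$,
placing it on the scale of the experimental GI50 score (the
$-\log_{10}$ molar concentration achieving 50% growth inhibition); base
10 is chosen for exactly that commensurability. Responders are $P < 1$;
the boundary $P = 1$ is pinned to non-responder so the rule is
deterministic and consistent with "score below $K$".

Per-treatment agreement between model and experimental scores uses the
Pearson correlation with its t-based p-value. The cross-treatment
summary (`aggregate_correlation()`) removes the per-treatment means from
both variables, pools the centered pairs and correlates — the
within-subject correlation of Bland and Altman, invariant to any
per-treatment offset. Comparing two such aggregate correlations (e.g.
scores computed with and without miRNA input) has no canonical test, so
`correlation_difference_test()` uses a seeded bootstrap over samples:
resample individuals with replacement, recompute both pooled
correlations, and read a two-sided p-value for a zero difference off the
resampled distribution (continuity-corrected, deterministic given the
seed). Group discrimination is quantified by the ROC AUC in its rank
(Mann–Whitney) formulation with midrank ties, making it invariant under
any strictly monotone transform of the scores.

# The synthetic fixture family

Real inputs for this kind of analysis (cell-line panels, tumor cohorts,
a curated pathway model) are external downloads, so the package carries
a seeded generator whose outputs exercise every pipeline stage. A
`fixture_spec()` describes per-gene cascades
gene → mRNA → protein (→ phospho-protein) feeding one `proliferation`
hallmark. One gene's protein is the drug-target kinase (named `MTOR` so
the built-in mTOR inhibitors resolve); the remaining genes split into a
kinase-*dependent* branch, phosphorylated by the kinase before
activating the hallmark, and a kinase-*independent* branch activating it
directly. How much of an individual's hallmark flux routes through the
druggable branch is what makes them a responder, which is the mechanism
the generator plants: responders get the kinase pathway elevated by
`effect_size` and the miRNAs silencing that pathway lowered by the same
factor; `effect_size = 1` is the null. Expression noise is log-normal
(non-negative, right-skewed, the standard first approximation for
expression data), sd 0.25 on the log scale by default, around baseline
medians of 20 (genes) and 10 (miRNAs).

The kinetic and scale choices are deliberate and load-bearing:
production at $k = 0.01$ against decay at 0.05–0.1 gives stage-to-stage
attenuation of 5–10x; the kinase-catalyzed phosphorylation carries
$eKd = 10$ and the hallmark activation $k = 0.002$ against decay 0.1,
keeping every fixed point strictly inside its firing guards and every
bimolecular speed under the 0.75 cap for the whole plausible expression
range (a baseline of 20 units times an 8-fold planted effect, times
noise). Outside those ranges the engine is still correct, but steady
states become guard-limited and insensitive — which is itself a property
of the modeled rule, not of this package, and is documented rather than
hidden.

What the generator does *not* emulate: real CRC expression
distributions, cohort-level confounders, TCGA/NCI-60 file layouts, or a
biologically curated pathway topology. Passing the end-to-end checks
therefore shows that the machinery — extension, initialization,
simulation, treatment, scoring — recovers structure that is genuinely
present in the inputs; it does not validate the biology of any
particular curated model.

# Validation problem sizes

The package's own test suite checks, among other properties: bit-exact
agreement of the engine with an independently written naive simulator on
100 random nets of up to 5 reactions over 1000 steps; exact inhibition
identities at $[I] = iKd$ and $2\,iKd$; steady detection at $t = 5$ on
frozen nets; closed-form census deltas and idempotence of the
miR-add-on; monotone silencing across 10 miRNA expression levels;
strictly monotone dose response over 5 doubling doses on a fixture whose
hallmark is entirely drug-gated; end-to-end label recovery (AUC 1.0 at
8-fold effect, chance-level AUC under the null, 20+20 individuals, 10
null seeds); TMM agreement with an independent reimplementation of the
published formula to 1e-9; and offset invariance of the pooled
correlation. These sizes keep the full suite under a minute of engine
time while covering the regimes in which the method is meant to operate.

# Known limitations

* The discrete sequential rule is order-dependent by construction;
  results are reproducible because the order is pinned, but they are
  semantics of *this* update scheme, not of an ODE limit.
* Guard-limited regimes (a readout capped by its driver, a bimolecular
  speed capped at 0.75 of the limiting reactant) flatten dose response;
  fixtures and doses should be chosen rate-limited, as the generator's
  defaults are.
* The administered drug concentration is a modeling input, not a
  measured quantity; only relative statements across doses or across
  individuals at a fixed dose are meaningful.
* Expression values feed the model untransformed; cross-platform
  comparisons require prior normalization (TMM for counts).
* Repression strength of TF inhibitors (iKd = 1 token unit) and all
  created kinetic constants are conventions, tunable per call, not
  fitted quantities.
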