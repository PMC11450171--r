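---
title: "Models and methods behind starrpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind starrpairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrpairs)
```

# The experiment this package analyses

Paired-enhancer STARR-seq fuses every ordered combination of two 249-bp
candidate sequences to the 5' and 3' ends of a transcriptionally inert
~300-bp spacer inside an episomal reporter, downstream of a core promoter.
Because the reporter transcribes itself, the ratio of RNA reads to input
(plasmid) reads for a construct measures the transcriptional activity of that
candidate pair. A pool of $n$ candidates — active enhancers spanning a wide
activity range plus inert negative controls — yields $n^2$ ordered fusion
constructs in a single screen (1,000 candidates give one million pairs), and
unique molecular identifiers (UMIs) collapse PCR duplicates so that counts
reflect original molecules.

The scientific question is *how enhancer activities combine*: whether the RNA
output of a pair is the **sum** of the partners' individual outputs
(additive), their **product** in fold-change terms (multiplicative,
i.e. super-additive), or something in between, and how strongly the core
promoter saturates when two strong enhancers are combined.

# Quantification model

## From reads to counts

Reads are assigned to constructs by direct end matching: read 1 must equal
the construct's 5' terminus in forward orientation and read 2 the
reverse-complemented 3' terminus, each within a Hamming budget of 3
substitutions (`max_mismatches = 3`, the screen's mapping stringency for
36-nt reads). Because the constructs are short, known, and determined by the
(5' candidate, 3' candidate) identity of their ends, full read alignment adds
no information here; a read pair compatible with more than one construct is
discarded, mirroring a unique-alignment requirement. UMIs are collapsed by
exact string identity per (pair, replicate, channel) — the conservative,
order-independent choice; UMIs containing `N` are dropped. Only heterotypic
pairs with at least 5 UMI-collapsed counts in **each** input replicate enter
the analysis.

## From counts to activities

With one pseudocount added to every UMI count, per-sample size factors are
computed by the median-of-ratios method (each sample's counts are compared
with the per-pair geometric-mean reference; the median ratio is that sample's
size factor). The pair activity is

$$\mathrm{activity}_p \;=\; \overline{\log_2 \frac{k^{\mathrm{rna}}_{p} + 1}{s^{\mathrm{rna}}}}
 \;-\; \overline{\log_2 \frac{k^{\mathrm{in}}_{p} + 1}{s^{\mathrm{in}}}},$$

averaged over replicates within each channel, followed by subtraction of one
scalar so that the mean activity of control/control pairs is exactly zero.
Activities are therefore log2 fold changes over the basal core promoter.
This explicit size-factor + pseudocount computation stands in for a
generic differential-count fit: it is transparent, exactly reproducible, and
its recovery of simulated ground truth is what the test suite certifies.

## Individual activities and active calls

Control outliers are removed before individual activities are computed: each
control's mean activity across its control x control pairs is standardised
per side (sample SD; if the SD is zero everything is retained), and only
controls with $z \in [-1, 1]$ are kept as *robust*. A candidate's individual
activity on a side is the mean activity of its pairs with robust controls on
the opposite side, and requires at least 10 such partners — otherwise the
candidate is discarded.

To call a candidate *active* we compare, with a one-tailed Fisher exact test,
the pooled RNA vs input UMI counts of its robust-control pairings against
those of the control/control pairs, followed by Benjamini–Hochberg FDR
correction per side; a candidate is active iff its log2 activity exceeds 1
**and** its FDR is below 0.05. The exact 2x2 construction (rows: candidate
pairs vs control/control pairs; columns: summed RNA vs summed input UMIs) is
one reasonable count-based reading of "comparing activities with a one-tailed
Fisher test"; it is isolated in `call_active()` so an alternative can be
swapped in without touching the rest of the pipeline. The one-tailed p-value
is the hypergeometric upper tail, which the tests verify against exhaustive
enumeration.

# Cooperativity models

With $A$ and $B$ the log2 individual activities of the 5' and 3' partners,
the two fixed predictions are

$$P_\mathrm{additive} = \log_2(2^A + 2^B - 1), \qquad
  P_\mathrm{multiplicative} = A + B.$$

The $-1$ removes the doubly counted basal output, so a pair with one basal
partner ($B = 0$) predicts $A$ under both models. The flexible model is an
ordinary least squares fit with interaction term,

$$P_\mathrm{activity} = \beta_0 + \beta_1 A + \beta_2 B + \beta_3 AB + \epsilon,$$

returned as a classed `interaction_fit` with the usual `coef`, `predict`,
`residuals`, `summary` and `plot` methods. Pairs containing a control are
discarded before modelling. Model performance is reported as
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ — this definition (rather than
$SS_\mathrm{reg}/SS_\mathrm{tot}$) is used deliberately because fixed,
non-fitted predictors can do worse than the observed mean, which must show up
as a *negative* $R^2$; for the fitted model the adjusted variant
$1-(1-R^2)(n-1)/(n-p-1)$ with $p = 3$ predictors is reported. In the
best-model fraction, ties between the additive and multiplicative
predictions (exactly equal absolute errors, e.g. basal partners) are counted
as additive — the conservative direction for a super-additivity claim.

Promoter saturation is assessed by anchoring pairs on a *weak* (individual
activity in $[1, 1.5]$) or *strong* (above the maximum individual activity
minus 1) enhancer on either side and regressing the mean pair activity per
partner on the partner's activity: a saturating promoter flattens the
strong-anchor slope while the weak-anchor slope stays near 1 under
multiplicative behaviour.

# Motif analyses

PWM scanning uses log2-odds scores against an i.i.d. background, discretised
on a $10^{-4}$-log2-unit lattice. The null score distribution is computed
*exactly* on that lattice by dynamic programming, and the match threshold is
the smallest score whose null exceedance probability is at most the cutoff
(default `p_cutoff = 5e-4`, the screen's scanning stringency). The
discretised score is the score definition — calibration and scanning use the
same lattice, so the DP tail probability equals brute-force enumeration over
all $4^k$ windows to floating-point precision (verified for $k \le 8$).
Both strands are scanned and overlapping windows count independently.

Motif curation keeps motifs that are over- or under-represented (two-tailed
Fisher, BH-FDR < $10^{-5}$) in any candidate group relative to a control
sequence set and have at least 5 matches in total. Pairwise motif effects
compare pairs whose 5' candidate contains motif $m$ AND whose 3' candidate
contains motif $n$ against pairs lacking both; since activities and
residuals are already log2 quantities, "normalising to the without-group" is
implemented as a difference of group means, keeping activity and residual
effects on a common axis. The LASSO stage follows the screen's protocol:
`glmnet` over the grid $\lambda = 10^{\{2, 1.9, \ldots, -3\}}$ with
standardised features, inner 5-fold cross-validation to choose the best
lambda, and 9-fold outer cross-validation with non-overlapping test sets for
the reported $R^2 \pm$ SD; coefficients come from a full-data refit at the
full-data inner-CV lambda.

# The synthetic-data generator

Downstream stages are validated against simulated screens with known truth
(`simulate_screen()`). The generator emulates:

* a pool of enhancers (log2 activities i.i.d. from a configurable law,
  default Uniform(0, 4), spanning the wide activity range such screens are
  designed around) and controls pinned at exactly 0;
* true pair activities under one of four regimes — `additive`,
  `multiplicative`, `interaction`
  ($\beta_0 + \beta_1 a_5 + \beta_2 a_3 + \beta_3 a_5 a_3$) and `saturating`,
  a smooth harmonic soft-minimum
  $\log_2\!\big(2^{a_5+a_3} \, 2^{c} / (2^{a_5+a_3} + 2^{c})\big)$ with cap
  $c$: monotone, multiplicative far below the cap, and bounded above by it.
  The screen observes saturation but fixes no functional form; the soft
  minimum is this package's choice;
* library representation skew (per-pair log-normal abundance, sdlog 0.5);
* negative-binomial UMI counts, variance $\mu + \mu^2 d$ with dispersion
  $d = 0.2$ by default and two replicates per channel at a mean input depth
  of 50 UMIs per pair (100 in the parameter-recovery setting). The real
  screen's count noise is not quantitatively characterised beyond high
  replicate correlation, so the dispersion is an explicit free parameter of
  the simulator, not an estimated quantity;
* pair-level biological noise, normal in log2 space (default SD 0.1),
  applied before exponentiation — matching the log-scale error term of the
  interaction model;
* optionally, paired FASTQ reads (UMI in the header after the last `:`,
  configurable PCR duplication and substitution-error rates) to exercise the
  quantification stage end to end.

One deliberate convention: under the **interaction** regime the coefficient
law applies to enhancer–enhancer pairs only, while control-containing pairs
take the basal-partner identity (the pair's activity equals the partner's
individual activity, and control/control pairs are 0). The interaction model
is a description of enhancer–enhancer cooperativity — it is fitted after
discarding control-containing pairs — and applying its law to control pairs
would make $\beta_0$ and $\beta_1$ unidentifiable through the pipeline: the
control anchoring absorbs $\beta_0$ and the control-derived individual
activities absorb $\beta_1$. With this convention the full pipeline recovers
all four generating coefficients, which is exactly what the acceptance suite
measures. The other three regimes satisfy the basal-partner identity
automatically (the saturating regime caps single strong enhancers too, which
is the physical expectation for a saturating promoter).

What the generator does **not** emulate: PCR amplification bias chemistry,
fragment-length effects, sequence-composition-dependent mapping artefacts,
batch structure between replicates, or any coupling between a candidate's
motif content and its activity (unless a test plants one). Passing tests
therefore certify the statistical machinery under the stated noise model —
not that real screens meet these assumptions.

# Numerical choices and degenerate inputs

* Additive predictions clamp $2^A + 2^B - 1$ at $2^{-30}$ (with a warning);
  the clamp is reachable only for deeply negative activity pairs outside the
  modelled regime.
* `fit_interaction_model()` rejects rank-deficient designs naming the
  collinear columns, and reports `NA` $R^2$ for zero-variance observations
  (the coefficients remain defined).
* Robust-control z-scores use the sample (n-1) SD; an SD of zero retains all
  controls. BH correction for active calls is per side by default
  (`per_side = FALSE` pools the two sides).
* Motif paste/mutate operations rejection-sample against a forbidden-PWM
  set: replacements are redrawn until no forbidden match overlaps the edited
  intervals (overlapping intervals are merged first, as independent
  replacement of overlapping windows would be order-dependent), and pasted
  placements are redrawn if they create a forbidden match outside the pasted
  copies. A configurable attempt budget turns pathological inputs into
  informative errors. Variant construction is constrained only by these PWM
  checks; no trained activity predictor is involved.
* UMI collisions in the read emitter are resampled so a UMI is unique within
  (pair, replicate, channel) — the zero-error round trip is exact by
  construction.
* Degenerate LASSO targets (zero variance) return an intercept-only fit with
  a cross-validated $R^2$ of 0 by convention, with a warning.

# Problem sizes used by the tests and acceptance script

The suite validates parameter recovery on screens of 300 enhancers + 100
controls (160,000 pairs) at input depth 100 across 20 seeds, regime
discrimination and saturation on 100 + 40 pools across 20 seeds, read round
trips on small pools with full FASTQ emission, and the million-pair
enumeration directly. These sizes give stable statistics for every claim
while keeping a full run in the minutes range on one CPU.

# Known limitations

* The Fisher 2x2 construction for active calls is an interpretation (the
  underlying screen literature states the test but not the table); with
  overdispersed counts the pooled-count test is anti-conservative on its
  own, which is why the activity threshold (log2 > 1) is a mandatory second
  condition.
* Exact-identity UMI collapse does not merge sequencing errors within a UMI;
  a mismatch-tolerant collapse would lower counts slightly at high error
  rates.
* Individual activities estimated from finite control panels carry
  measurement error; as in any errors-in-variables regression this
  attenuates the interaction-fit coefficients slightly (visible as a small
  upward bias of the recovered intercept at screen-scale control numbers).
* The enrichment stage takes the motif collection as input; it does not
  curate redundancy between PWMs or filter by expression data.
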