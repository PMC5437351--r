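---
title: "Methods: quantifying selection and drift in endosymbiont genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selection and drift in endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symdrift)
```

## The scientific question

Maternally transmitted endosymbiotic bacteria of insects pass through a
severe population bottleneck at every host generation. Small effective
population size and the absence of recombination make selection
inefficient, so their genomes accumulate mildly deleterious mutations,
lose genes, and shrink — yet some genes remain under *stronger* purifying
selection than their orthologs in free-living relatives. This package
implements the comparative machinery for detecting both signals: relaxed
constraint genome-wide, and convergent pockets of strong constraint, plus
the mutational-spectrum and genome-flux accounting used to compare
drift-evolved experimental bacterial lines with natural endosymbionts.

## Pairwise dN/dS by counting (NG86)

For a validated pair of aligned coding sequences the package estimates
$\omega = d_N/d_S$ with the Nei–Gojobori (1986) counting method:

* **Sites.** For each codon and each of its three positions, the
  synonymous fraction is (synonymous single-base neighbors)/(non-stop
  single-base neighbors). Stop-codon neighbors are excluded from the
  denominator, a standard convention chosen here because it makes
  $S + N = 3$ *exactly* per codon — a tested invariant. Site counts are
  averaged over the two sequences.
* **Differences.** For a codon pair differing at $k$ positions, all $k!$
  orderings of the single-base steps are enumerated; orderings passing
  through a stop codon are discarded and the synonymous/nonsynonymous
  step counts averaged over the rest. If *every* ordering is blocked the
  codon pair is excluded from both site and difference totals (flagged).
* **Correction.** $p_S$ and $p_N$ are Jukes–Cantor corrected,
  $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, valid for $p < 3/4$.

A maximum-likelihood codon model would weight pathways by their rates;
pure counting weights them equally. One visible consequence, worth
knowing when reading the tests: even when the generating process is
purely synonymous ($\omega = 0$), pathway averaging across multi-hit
codons can traverse nonsynonymous intermediates, so the *estimated* $d_N$
is near zero but not exactly zero. The estimator is accurate without
transition bias; under strong bias ($\kappa \gg 1$) NG86 is known to be
biased, which is why the simulator's default is $\kappa = 1$ and the
recovery tolerance is ±20%.

Parameters:

| parameter | default | meaning |
|---|---|---|
| `saturation_ds` | 2 | genes with $d_S$ above this (or $p_S \ge 3/4$) are flagged `dS_saturated` and excluded downstream |
| `min_codons` | 30 | below this many analyzable codons the estimate is flagged `too_short` (flag only; no silent exclusion) |

$\omega$ is reported as 0 when $d_N = 0, d_S > 0$, and as undefined when
$d_S = 0$ (`dS_zero`) — never as $\infty$.

## Relative constraint R

For each ortholog, $R = \omega_e/\omega_f$ compares the endosymbiont pair
estimate with the free-living pair estimate. $R < 1$ means stronger
constraint in the endosymbiont. Categories: `strong` ($R \le 1$),
`moderate` ($1 < R < 2$), `relaxed` ($R \ge 2$). The $R \le 1$ boundary
follows the tabulated convention; because the strict reading $R < 1$ also
circulates, the count at exactly $R = 1$ is reported separately so either
convention can be reconstructed. Genes with an undefined $\omega$ on
either side, or with $\omega_f = 0$, are `excluded` with a recorded
reason and never enter medians or rank tests — the source analyses are
silent on this point, and exclusion is the conservative, logged choice.
Lineage comparisons use the Mann–Whitney rank-sum test (exact when the
combined sample is ≤ 20 without ties, tie-corrected normal approximation
with continuity correction otherwise).

## The convergence randomization test

Given per-lineage universes of analyzed genes and constrained sublists,
the observed statistic is, for each $k$, the number of genes constrained
in exactly $k$ (and at least $k$) lineages. The null is built by drawing,
per replicate, a pseudo-constrained list *within each lineage's own
universe*, uniformly without replacement, with the observed list size —
universes genuinely differ across lineages, so a shared-universe null
would be wrong. Empirical p-values use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{reps})$, so the
smallest attainable value is $1/(n_{reps}+1)$ and output at that bound
should be read as "$p \le$" that value.

Design choices made here because the source procedure leaves them open:

* Both exactly-$k$ and at-least-$k$ tallies are computed and reported.
* The calibration test uses the at-least-3 statistic: the headline
  convergence claims concern genes shared by 3–5 lineages, and $k \ge 3$
  is the level of that family with the richest null support, which
  minimizes the conservatism that discreteness imposes on empirical
  p-values. That conservatism is real: with counts as test statistics the
  attainable rejection rate at $\alpha = 0.05$ sits slightly *below*
  0.05, so calibration checks should (and do) use a binomial band, not an
  exact match.
* Gene identity across lineages is exact string matching on a shared
  ortholog namespace; no fuzzy mapping is attempted.

## Radical vs conservative substitutions

A replacement is **radical** if it crosses a class boundary of charge,
polarity, or polarity-and-volume; otherwise conservative. The three
tables (the package's single source of truth, also used to build the
simulator's pair pools):

* charge: positive {R, K, H}, negative {D, E}, neutral otherwise;
* polarity: polar {C, D, E, H, K, N, Q, R, S, T, W, Y}, nonpolar
  {A, F, G, I, L, M, P, V};
* polarity & volume: special {C}; neutral-small {A, G, P, S, T};
  polar-small {N, D, Q, E}; polar-large {R, H, K}; nonpolar-small
  {I, L, M, V}; nonpolar-large {F, W, Y}.

Membership, not direction, decides, so radicality is symmetric (tested
exhaustively over all 380 ordered pairs). Nonsense and stop-loss changes
are counted as mutations but never classified — the classes are defined
only for amino acids.

## Genome flux

Indel events carry a position, kind, and length; the coding/intergenic
partition comes from a GFF3 annotation (1-based closed intervals,
converted nowhere else). An event is assigned to the region of its
*start* position; events spanning a boundary are assigned to their start
region with a warning — deterministic and logged, since no convention is
given by the source analyses. The loss rate is
$\text{deleted nt}/(\text{genome size} \times \text{generations})$;
generations are always an explicit input, never inferred, because the
published per-generation rates are internally inconsistent with the
stated generation count (they imply ≈ 5,230 generations against a stated
5,500–5,750) — both values can be supplied and compared. Fold
comparisons against a reference rate report the integer part
(`floor`), matching how such multiples are conventionally quoted, with
the real-valued ratio alongside.

## Exact statistics

* **Binomial**, two-sided by the minimum-likelihood convention
  (delegated to `stats::binom.test`, which implements exactly that).
* **Fisher's exact test** is implemented directly. The p-value sums,
  over the conditional support given the margins, the central
  hypergeometric probabilities of all tables no more probable than the
  observed one (with the customary $1 + 10^{-7}$ relative slack). The
  odds-ratio estimate is the *conditional MLE*: the $\psi$ solving
  $E_\psi[X_{11}] = a$ under the noncentral hypergeometric law, found by
  bracketed root-finding in $\log\psi$ plus Newton polishing until
  $|E - a| < 10^{-8}$. All computation is in log space; the largest table
  handled in practice (total ≈ 38,500, conditional support of 51 states)
  is exact and fast. On extreme tables, general-purpose optimizers with
  loose tolerances can report conditional MLEs that are off by several
  percent while looking plausible; the score-equation residual is the
  invariant this implementation tests.
* **Hypergeometric enrichment** is the upper tail $P(X \ge k)$ with a
  Bonferroni multiplier helper; Bonferroni is the only multiple-testing
  correction provided.

## The synthetic world

The simulators are first-class, tested code; they define the conditions
under which the pipeline is validated.

* `simulate_codon_pair()`: uniform ancestor over the 61 sense codons;
  two copies evolved independently for $t/2$ each under a continuous-time
  process with single-nucleotide changes, transition rate $\kappa$,
  nonsynonymous changes damped by $\omega$, zero rate into stops; rates
  rescaled so $t$ is expected substitutions per codon. Uniform codon
  frequencies and Gillespie-style exact simulation are the simplest
  process under which NG86 recovery is meaningful. It does **not**
  emulate codon-usage bias, among-site rate variation, or indels, so a
  green recovery test establishes correctness of the counting machinery,
  not robustness to those features of real genomes.
* `simulate_constraint_lists()`: shared ortholog namespace; per-lineage
  universes; `n_shared` genes forced into every constrained list
  (`n_shared = 0` gives exact null draws for calibration).
* `simulate_substitutions()`: mixture draws from the radical and
  conservative pair pools derived from the classification tables.
* `simulate_indels()`: uniform positions, Bernoulli deletion bias,
  geometric lengths with mean 3 bp (most observed events affect only a
  few nucleotides), plus an optional injected large deletion emulating
  punctuated losses of whole gene blocks.

All generators are byte-reproducible from their seeds.

## Known limitations

* NG86, not a likelihood codon model: absolute $\omega$ values on real
  genomes will differ from ML estimators (e.g. κ-corrected ones); all
  validation is therefore by simulation recovery and enumeration
  oracles, not by replicating published per-genome medians, which would
  require the original genome alignments.
* The cleaning rules for codon alignments (drop columns with gaps,
  ambiguity, or internal stops) are a stated convention, not a
  reconstruction of any particular published filtering.
* Empirical p-values from the randomization test are conservative by
  construction; with $10^5$ replicates they can only be bounded below by
  $10^{-5}$, and the output says so rather than printing smaller values.
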