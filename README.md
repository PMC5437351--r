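# symdrift

Selection–drift analysis of endosymbiotic bacterial genomes, for
molecular evolutionists comparing host-restricted bacteria (or
experimentally bottlenecked lines) with their free-living relatives.

Maternally transmitted endosymbionts evolve under strong genetic drift:
repeated transmission bottlenecks, tiny effective population sizes, no
recombination. `symdrift` implements the quantitative toolkit for
characterizing what that regime does to a genome:

* **Pairwise dN/dS** (ω = dN/dS) by Nei–Gojobori (1986) counting on
  validated codon alignments — per-codon site fractions with stop-codon
  neighbors excluded (so S + N = 3 exactly), pathway-averaged difference
  counts, Jukes–Cantor correction.
* **Relative constraint** R = ω_e/ω_f per ortholog (endosymbiont pair vs
  free-living pair), with categories strong (R ≤ 1), moderate
  (1 < R < 2), relaxed (R ≥ 2), per-lineage summaries and Mann–Whitney
  lineage comparisons.
* **Convergence randomization test**: are the same orthologs constrained
  in multiple independent lineages more often than random same-size gene
  lists drawn from each lineage's own analyzed universe? Empirical
  add-one p-values per overlap level k (exactly-k and at-least-k).
* **Radical vs conservative substitution spectra** under the
  charge / polarity / polarity-and-volume class schemes, with Fisher
  exact comparisons between experimental lines.
* **Genome-flux accounting**: insertion/deletion ledgers stratified over
  a coding/intergenic GFF3 partition, nucleotide-loss rates per site per
  generation, fold comparisons to reference endosymbiont loss rates, and
  exact tests for deletion bias.
* **Exact statistics**: two-sided binomial, Fisher's exact test with a
  precise conditional-MLE odds ratio (solves E_ψ[X11] = a to 1e-8),
  Mann–Whitney, hypergeometric enrichment with Bonferroni.
* **Simulators** for every input: codon pairs diverged under a known ω,
  constrained-gene lists with a tunable convergence effect, substitution
  catalogs with a known radical fraction, deletion-biased indel streams.

## Worked example

```r
library(symdrift)

# simulate a 10,000-codon ortholog pair diverged under omega = 0.2 and
# recover the parameter with the NG86 estimator
cfg  <- sim_config(n_codons = 10000, omega = 0.2, kappa = 1, t = 0.4, seed = 7)
estimate_omega(simulate_codon_pair(cfg))
#> NG86 estimate for gene 'sim_gene' (10000 codons)
#>   dN = 0.06705  dS = 0.31854  omega = 0.2105

# radical-spectrum contrast: 328/408 radical changes in a strongly
# bottlenecked line vs 1/12 in a large-population control
fisher_exact(328, 80, 1, 11)
#> Fisher's exact test (2x2)
#>   conditional-MLE odds ratio: 44.6067
#>   two-sided p: 2.96e-07

# constraint summary for a lineage with 33 of 487 genes at R <= 1
r <- c(seq(0.05, 1, length.out = 33), seq(1.01, 20, length.out = 454))
summarize_constraint(r, lineage = "example")
#> Relative selective constraints [example]
#>   genes with defined R: 487
#>   R <= 1 (strong):   33 (6.8%)
#>   R > 1  (relaxed):  454 (93.2%)
#>   median R: 9.81
```

The recovered omega (0.2105) is the counting estimate of the generating
value 0.2; the odds ratio 44.61 is the conditional maximum-likelihood
estimate for the 2×2 spectrum table, and 6.8% is the strongly
constrained fraction of genes with a defined R.

## Acceptance script

`scripts/acceptance.R` rebuilds the line-A coding-vs-intergenic
nucleotide-flux table (coding: 38,355 deleted / 62 inserted bp;
intergenic: 15 deleted / 35 inserted bp) from an indel event ledger run
through the package's annotation and tally machinery, applies the Fisher
machinery to it, and writes the resulting conditional-MLE odds ratio as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
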