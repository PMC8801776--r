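# polymads

Gene-family phylogenomics for allopolyploid genomes, modelled on
genome-wide surveys of the MADS-box transcription-factor family in
allohexaploid bread wheat (subgenomes A, B, D).

Given protein and CDS sequences with a gene annotation, the package

* identifies family members by ungapped PSSM scans of the MADS (PF00319)
  and K-box (PF01486) domains, merges domain and keyword candidate lists
  with survey-style bookkeeping, filters to high-confidence non-redundant
  gene models, and computes protein length, molecular weight and
  isoelectric point (EMBOSS pKa set, bisection);
* classifies genes into the M and MIKC superclades and 16 subfamilies by
  best global alignment (BLOSUM62, affine gaps) against labelled
  reference exemplars, builds neighbor-joining trees on Kimura-corrected
  distances (`d = -ln(1 - p - 0.2p²)`) with Felsenstein bootstrap
  supports, and applies the FLC-vs-MIKC\* diagnostic residues at MADS
  positions 30/34/50;
* detects homeologous triads as supported (>90%) single-subfamily clades
  and classifies each subfamily's balance (balanced: a copy on each of
  A, B, D; unbalanced: a copy missing from one or two subgenomes);
* calls duplicated gene pairs at ≥90% CDS identity among non-homeologous
  pairs, types them tandem (same chromosome) or segmental (different
  chromosomes), infers chromosomes for unplaced genes from unanimous
  partners, and places pairs into chromosome-segment categories
  (R1/R2a/C/R2b/R3; distal telomeric / sub-telomeric / proximal);
* estimates Ka and Ks with the Nei–Gojobori (1986) pathway method
  (equal pathway weighting, stop pathways excluded, Jukes–Cantor
  correction `K = -(3/4)ln(1-(4/3)p)`), dates duplications with
  `T = Ks/2r` (default `r = 6.5e-9` substitutions/synonymous site/year)
  and classifies selection by ω = Ka/Ks;
* applies the "log2 TPM < 0 means not expressed" rule and clusters
  expression profiles with seeded Lloyd K-means (defaults K = 10,
  1,000 iterations, best of 5 runs).

A synthetic allohexaploid genome generator plants triads with
configurable subgenome patterns, tandem/segmental duplicates at target
(Ks, ω) and expression clusters with a silent fraction — with complete
ground truth — so the whole pipeline is validated end to end.

## Worked example

```r
library(polymads)

cfg <- pipeline_config(mode = "synthetic", seed = 42)
res <- run_pipeline(cfg)

res$report$superclade_counts
#>    M MIKC
#>   28   44

res$report$duplication$type_counts
#>    tandem segmental  unplaced
#>        10        12         0

head(res$stages$estimates[, c("gene_a", "gene_b", "Ka", "Ks", "omega",
                              "T_mya", "selection")], 3)
#>     gene_a   gene_b         Ka         Ks     omega    T_mya selection
#> 1 SYNG0001 SYNG0053 0.01460492 0.04953657 0.2948312 3.810505 purifying
#> 2 SYNG0002 SYNG0054 0.01462272 0.04933285 0.2964094 3.794834 purifying
#> 3 SYNG0003 SYNG0063 0.01460492 0.06680352 0.2186251 5.138732 purifying

consistency_check(res$report)$pass
#> [1] TRUE
```

The default synthetic genome carries 20 triads (52 homeolog genes) in
eight subfamilies plus 10 tandem and 10 segmental duplicates planted at
Ks = 0.05, ω = 0.3: the report above recovers all 20 planted pairs
(the two extra pairs are duplicate–duplicate pairs inside the same
triads, called correctly by the ≥90%/non-homeologous rule), estimates ω
near the planted 0.3 under purifying selection, and dates the events
near Ks/2r ≈ 3.8 million years. The expressed fraction in
`res$report$expression` is ≈0.57, matching the generator's planted 43%
silent share.

`inst/scripts/polymads.R` is a thin command-line wrapper
(`Rscript inst/scripts/polymads.R run --seed 42 --out out/`) that writes
the stage tables (assignments, homeolog groups, balance table,
duplicate pairs, Ka/Ks estimates) and Newick trees.

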