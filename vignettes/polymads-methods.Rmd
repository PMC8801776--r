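---
title: "Methods: gene-family phylogenomics in an allohexaploid genome"
author: "polymads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family phylogenomics in an allohexaploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymads)
```

# The problem

Bread wheat is an allohexaploid: three closely related diploid subgenomes
(A, B and D) coexist in one nucleus, so most genes occur as *homeologous
triads* — one copy per subgenome. Genome-wide surveys of a
transcription-factor family in such a genome must answer several linked
questions at once: which gene models belong to the family; how the
members partition into superclades (here, M-type versus MIKC-type
MADS-box proteins) and subfamilies; whether each subfamily's triads are
*balanced* (a copy on every subgenome) or *unbalanced* (a copy missing
from one or two subgenomes); which gene pairs arose by recent tandem or
segmental duplication; how fast those duplicates have been evolving
(Ka/Ks, divergence time); and how family members respond transcriptionally
to stress. `polymads` implements that entire workflow as composable,
deterministic functions, together with a synthetic genome generator that
plants known structure at every level so the whole pipeline can be scored
against ground truth.

# Family identification

Membership is decided by domain content. The package scans each protein
with ungapped position-specific scoring matrices (PSSMs) for the MADS
domain (PF00319; the packaged profile spans 60 columns, within the
58–60-residue range characteristic of the domain) and the K-box
(PF01486). PSSM scores are log2-odds against a uniform 1/20 background
with pseudocount 1; the hit threshold is the 99th percentile of maximal
window scores over 1,000 composition-preserving shuffles of the profile
consensus. This is a deliberate, self-contained substitution for
web-based Pfam/CDD searches: it is deterministic, needs no network, and
its false-positive behaviour is controlled by the shuffled null. It is
*not* a profile HMM — it cannot model insertions inside the domain — and
the packaged seed alignments are synthetic exemplars (see the file names
under `extdata/`), so real-data runs should swap in profiles built from a
curated seed alignment via `build_pssm()`.

Candidate bookkeeping mirrors the three-way search protocol used for
wheat: per-domain hit lists plus a literal, case-insensitive keyword
search over annotation descriptions are pooled (`merge_candidates()`
reports the pooled total, with overlaps counted multiply, separately from
the distinct-id union) and then reduced to high-confidence, non-redundant
gene models. Wheat survey protocols typically do not state which redundancy rule
reduces the pooled candidate list to the retained set, so the filter is exposed as an explicit,
configurable step (`filter_nonredundant()`: confidence flag plus id
deduplication) rather than a guessed heuristic.

Protein statistics use average (not monoisotopic) residue masses plus one
water, reported in kDa, matching the conventions behind published kD
ranges; the isoelectric point is the pH at which the Henderson–Hasselbalch
net charge over the termini and ionizable side chains (EMBOSS pKa set)
crosses zero, found by bisection to |charge| < 1e-4.

# Classification

Queries are assigned to one of 16 subfamilies (Mα, Mβ, Mγ; AP1, AP3, PI,
AG/STK, SEP, AGL6, AGL12, AGL17, Bsister, MIKC*, OsMADS32, SOC1, SVP) by
best global-alignment score against a labelled reference exemplar set;
the superclade (M versus MIKC) is implied by the subfamily. Alignments
are exact Needleman–Wunsch with affine gaps (BLOSUM62, gap open 10,
extend 0.5, end gaps penalized) through `Biostrings::pairwiseAlignment()`.
Score ties between subfamily labels are flagged ambiguous with all tied
labels reported. Assignment is invariant to the ordering of the reference
set (references are scored in canonical id order).

Trees are built by distance methods substituting for the maximum
likelihood + ultrafast-bootstrap protocols common in published surveys,
keeping
the same downstream contracts (clades with percent supports): a
center-star progressive multiple alignment (the center maximises total
pairwise score; merges follow once-a-gap-always-a-gap), Kimura-corrected
distances `d = -ln(1 - p - 0.2 p^2)` with pairwise deletion, and
neighbor-joining with a deterministic tie-break (among minimal Q values
the lexicographically smallest taxon pair joins first; permuting the
input order cannot change the result). Edge supports are Felsenstein
bootstrap percentages over alignment-column resamples (default 100
replicates, configurable; replicate distances that saturate are capped at
1.5x the largest finite distance so NJ stays defined). On additive
matrices NJ provably recovers the generating topology and branch
lengths; the test suite checks this against brute-force
minimum-evolution enumeration on up to six taxa.

The FLC diagnostic follows the three-residue signature at MADS-domain
alignment positions 30, 34 and 50: (E, Q, A/G/S) is FLC-like, (K, E, P)
is MIKC*-like, anything else — including a gap — is indeterminate. The
packaged MADS profile defines the coordinate frame for those positions;
if a user-supplied profile has a different column frame the positions
refer to *that* frame, and no silent correction is attempted.

# Homeology

A homeolog group is operationalized as a maximal clade with bootstrap
support strictly above 90% whose leaves all carry one subfamily label and
contain at most one gene per subgenome beyond duplicate candidates.
Homeolog detection runs on **per-subfamily trees** (the family members of
one subfamily plus that subfamily's reference exemplar, rooted on an
outgroup reference from the same superclade). Within a subfamily the
sequences are homologous over their whole length, which keeps the
center-star alignment, the distances and the clade supports clean;
across subfamilies the fast-evolving linker/tail regions are effectively
unalignable and would only add noise. Same-subgenome co-members are
admitted only when linked by a high-identity duplicate-candidate pair —
this is what keeps two distinct triads of one subfamily from merging into
a single supported clade while still letting a tandem duplicate sit
inside its parent triad's group.

Genes in no accepted clade are assessed individually: if the smallest
supported clade above a gene contains no other unresolved gene of its
subfamily, the gene is confidently isolated and forms a singleton group
(a lone A-copy is then classified unbalanced, exactly like a planted
one-member triad); otherwise its status is undetermined — the category surveys use for
genes whose clades fall below the bootstrap cutoff.

Balance follows the published definitions: balanced if the group has at
least one copy on each of A, B and D; unbalanced if a copy is missing
from one or two subgenomes; groups placed only on unassigned (U)
chromosomes are undetermined, since chrU genes count toward no subgenome.
The per-subfamily report flags subfamilies whose duplications coexist
with fully balanced homeologs (the AP3-style exception annotation).

# Duplication and chromosome segments

Pairwise CDS identity is computed from global nucleotide alignments
(match +1, mismatch −1, affine gaps): identity is matches over aligned
columns excluding terminal gap columns, with internal gaps counted as
mismatches; coverage is the aligned overlap as a fraction of the shorter
CDS, and pairs under 50% coverage are uninformative. The coverage floor
replaces the BLAST E-value filter of BLAST/SDT-based protocols, which is
database-size dependent and not reproducible without BLAST; overlap is
the quantity it effectively enforces. The all-against-all matrix applies
a score-based screen first (a batched alignment score bounds the
attainable identity, so pairs far below the calling threshold skip the
exact column-wise computation) — the same role BLAST's heuristic
prefilter plays — and computes exact identities for everything near or
above the threshold.

A pair is called duplicated when identity ≥ 90% (inclusive; pairs within
half a point of the threshold are flagged as boundary cases, since
survey protocols rarely state whether the threshold is inclusive) and the pair is not
homeologous. "Homeologous" is resolved as: both genes in the same
homeolog group *and* on different subgenomes. Same-subgenome pairs inside
a group are therefore callable — that is precisely what a tandem
duplicate inside a triad clade is. Same chromosome means tandem;
different placed chromosomes segmental; pairs with an unplaced member
are unplaced unless every placed partner of the unplaced gene lies on
one chromosome, in which case that chromosome is adopted and flagged
inferred (the chrU-to-3B style inference).

Each placed chromosome is partitioned into the five IWGSC-style segments
R1, R2a, C, R2b, R3 (breakpoints supplied as a TSV in real mode and
generated in synthetic mode; the IWGSC consortium publishes the
real-genome coordinates separately); R1/R3 are distal telomeric, R2a/C/R2b central.
Genes are assigned by midpoint; a pair is distal_telomeric (both
distal), sub_telomeric (one distal, one central) or proximal (both
central).

# Molecular evolution

Ka/Ks follows the Nei–Gojobori (1986) pathway method as popularised by
the SNAP program: per codon, the synonymous site count at each position
is the synonymous fraction of its non-stop single-nucleotide mutants
(stop-codon mutations are excluded from the denominator, so S + N = 3 per
codon always); differences between two codons are averaged with equal
weight over all minimal mutational pathways, excluding pathways through
stop codons (if every pathway is blocked, all pathways are used with
stop-involving steps counted as nonsynonymous — a rare, documented
fallback). Site counts are averaged between the two sequences. The
proportions ps = Sd/S and pn = Nd/N receive the Jukes–Cantor correction
`K = -(3/4) ln(1 - (4/3) p)`; a proportion at or beyond the correctable
range leaves the rate undefined with a saturation flag, and such pairs
are excluded from downstream summaries with their counts reported rather
than silently dropped. No transition/transversion weighting is applied,
matching the equal-weight defaults of the reference implementation.

Codon alignments come from back-translating the protein alignment onto
the two CDS and dropping every codon column containing a gap in either
sequence; a translation mismatch aborts with the offending codon named.
Divergence times use `T = Ks / 2r` with the grass synonymous clock rate
`r = 6.5e-9` substitutions/synonymous site/year by default (configurable).
Selection is positive (ω > 1), purifying (ω < 1), neutral (ω = 1) or
undefined (Ks = 0). Superclade summaries report Ks, ω and T quartiles
plus the percentage of defined-ω pairs under positive selection, the
quantities used to contrast M-type and MIKC-type evolution.

# Expression

A gene is expressed iff any log2-TPM value exceeds 0.0 (strict). The
rule as used on the wheat expression atlas declares genes never rising
above 0.0 not expressed, while observed expressed values start around
0.20 — leaving a dead zone between 0.0 and 0.2 unclassified. The package adopts the
single threshold at 0.0 and reports the observed minimum expressed
value, so real-data runs can be compared against the printed 0.20
without inventing a second cutoff.

Clustering is Lloyd's K-means on the matrix rows as-is (no z-scaling,
matching heatmap-style clustering of log2 TPM; scaling can be applied by
the caller), Euclidean distance, defaults K = 10, 1,000 iterations, 5
restarts with per-run seeds derived from the master seed; the restart
with the lowest within-cluster sum of squares wins. Empty clusters are
re-seeded from the point farthest from its current center. The WCSS
trace is asserted non-increasing on every run — a violated assertion is
a bug, not a warning. This is implemented directly (rather than calling
a library routine) because the contract specifies the restart seeding,
the empty-cluster policy and the exposed WCSS trace; the test suite
cross-checks it against `stats::kmeans` on the same data. K-means runs
on all condition columns by default; a condition-grouping step can be
applied upstream if grouped averages are preferred.

# The synthetic genome generator

`generate_genome()` emulates the *inputs* of the real analysis with
complete ground truth. From each subfamily's reference exemplar it
derives a subfamily ancestor CDS (codon mutation at Ks 0.15, ω 0.5 —
crop-versus-model-plant scale divergence), from that per-triad ancestors
(Ks 0.25, ω 0.5 — clearly separated triads within a subfamily), and from
those the A/B/D copies (Ks 0.015 each, ω 0.3 — tight within-triad
divergence, pairwise about Ks 0.03, mirroring the recent hexaploidization
of wheat). This three-level divergence ladder is what makes triads
well-supported clades while keeping between-triad identity safely below
the 90% duplicate-calling threshold. Planted duplications copy a source
gene and mutate it to a target (Ks, ω); tandem duplicates are placed on
the source chromosome inside the source segment, segmental duplicates on
a different chromosome of the *same* subgenome — a deliberate choice:
within-subgenome segmental duplication is common in wheat, and it keeps
"homeologous" (cross-subgenome co-clade) and "duplicated"
(same-subgenome or cross-triad) cleanly separable in the ground truth.

The codon mutation model (`mutate_cds()`) inverts the Jukes–Cantor
correction to convert target rates into expected change counts, then
draws synonymous and nonsynonymous single-nucleotide changes from
precomputed mutant sets — so the reading frame is preserved, no internal
stop can arise, and realized NG86 estimates concentrate around the
targets (medians within ±25% across the tested grid at ~200 codons).
It applies at most one change per codon per class, which keeps pathway
counting nearly exact; it does not model indels, rate heterogeneity
among sites, codon-usage bias or transition/transversion bias, so
recovery results on synthetic data say nothing about robustness to
those features of real data.

The default specification (`default_genome_spec()`) *is* the validation
condition exercised by the tests: 20 triads across eight subfamilies
with a mixture of balanced and unbalanced patterns (52 homeolog genes),
plus 10 tandem and 10 segmental duplications at Ks 0.05, ω 0.3 — 72
genes total. Expression matrices are generated per cluster (16
conditions mirroring the stress condition groups, Gaussian noise) with a
silent fraction of 0.43 whose rows are clamped strictly negative,
matching the published 43% not-expressed share; the expressed fraction
recovered by the pipeline on the default genome is accordingly ≈57%.
Genes are placed 1-based, inclusive, forward-coordinate style on 21
chromosomes (7 groups × A/B/D, 100 Mbp each) with segment breakpoints at
15/40/60/85% of chromosome length; chromosome names carry the subgenome
letter as a suffix, and the generator does not emit intergenic sequence,
introns or whole-chromosome FASTA.

Everything is deterministic: one master seed, child seeds derived per
stage, and RNG state restored after every seeded operation, so a rerun
with the same spec is byte-identical.

# Numerical choices and problem sizes

* NJ tie-breaks and alignment traceback are deterministic; negative NJ
  branch lengths are clamped to zero.
* Bootstrap replicates default to 100 (configurable); the per-subfamily
  trees used for homeology have 4–14 tips, where 100 replicates resolve
  supports to the percent level.
* The test suite validates NG86 counting against exhaustive single-mutant
  and pathway enumeration over all 61 sense codons and all 3,721
  sense-codon pairs; parameter recovery uses 50 replicates per grid cell
  on a ~195-codon CDS; planted-structure recovery runs the full default
  genome end to end. These sizes were chosen to give stable medians and
  full coverage of the codon table while keeping a complete test run in
  the order of a minute.
* Ties in K-means assignment go to the lowest cluster index; K-means
  initial centers are distinct rows sampled per run seed.

# Known limitations

* The center-star MSA is adequate for family-level and subfamily-level
  alignments of domain-anchored proteins but is not a progressive
  profile aligner; very gappy alignments will degrade distances, which
  is why homeology works subfamily-wise.
* The PSSM scan cannot detect domains interrupted by insertions, and the
  packaged profiles are synthetic stand-ins; real surveys should build
  profiles from curated seed alignments.
* Identity screening assumes the +1/−1 nucleotide scoring; with other
  scoring schemes the screen bound would need re-derivation (the exact
  path is always available via `cds_identity()`).
* NG86 with equal pathway weighting ignores transition/transversion and
  codon-usage effects; ML codon models are out of scope.
* The expression module ingests a provided log2-TPM matrix; no RNA-seq
  quantification or differential-expression testing is included.
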