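---
title: "circheart: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circheart: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`circheart` implements a desk-scale circular RNA (circRNA) discovery and
analysis pipeline for two-group bulk RNA-seq — the setting of a dilated
cardiomyopathy (DCM) versus normal left-ventricle comparison with five
ribo-depleted libraries per group. The stages are: anchor-based back-splice
junction calling from reads that fail contiguous alignment; genomic-origin
annotation; classification of two-gene junctions into read-through
(rt-)circRNAs versus homology artifacts; SRPBM quantification with a
detection tier and a high-confidence tier; negative-binomial exact-test
differential expression; circRNA/host-gene correlation; and miRNA seed-site
sponge screening on the circular sequence. A deterministic synthetic-data
generator with complete truth tables makes every stage testable end to end.

All internal coordinates are 0-based half-open (the BED convention); GTF
I/O converts at the boundary. A junction is keyed by
`(chrom, start, end, strand)`, where `start`/`end` are the genomic left and
right edges of the circularised span and the strand is the transcribed
strand established by the splice signal.

# Junction calling

Reads are first given to a toy contiguous aligner: a read is *mapped* iff
its full length matches a chromosome or an annotated spliced transcript
with at most `mm` mismatches (default 0), in either orientation. This
replaces a production aligner at fixture scale; mapped totals are the SRPBM
denominators. For `mm > 0` the match is seeded by an exact terminal k-mer
at either read end, so at most one read end may carry errors — sufficient
for the substitution-only error model of the generator.

Unmapped reads enter the caller. The terminal `k = 20` nt of the read (the
*anchors*) are looked up in an exact k-mer index over both genome strands;
an anchor is usable only if it has exactly one occurrence genome-wide.
When both anchors fall on one chromosome and strand with the read's leading
anchor *downstream* of its trailing anchor (reversed orientation), the two
anchor alignments are extended toward the read interior. A breakpoint at
read offset `s` is accepted iff the whole read is explained by two genomic
segments and the joint is flanked by the canonical splice signal on the
transcribed strand: `AG` immediately 5' of the acceptor segment and `GT`
immediately 3' of the donor segment (equivalently `CT..AC` on the genomic
plus strand for minus-strand calls). Among signal-consistent breakpoints
the one maximising the acceptor-segment length is reported; this tie-break
is arbitrary but deterministic. Reads with non-unique anchors, forward
orientation, or no signal-consistent breakpoint are dropped and tallied in
a per-sample log.

Candidate calls are grouped by junction key; per-sample support is the
number of *distinct supporting read sequences* (exact duplicates collapse).
"Unique back-spliced reads" is not defined more precisely in the field's
tool descriptions; distinct-sequence collapse is the reproducible reading
we adopt. Junctions are kept iff support reaches 2 in at least one sample
(the detection tier).

# Origin annotation

Precedence: (1) *two-gene* when the acceptor lies in an exon of gene G1 and
the donor in an exon of a different same-strand gene G2, with G1
transcriptionally upstream of G2 and no annotated gene between the pair;
(2) single-gene exonic calls are *CDS*, *UTR* or *UTR-CDS* according to
whether the exonic nucleotides inside the junction span are all, none, or
partly covered by the gene's CDS; (3) *intronic* when both ends are inside
one gene's span but either end is not exonic; (4) *intergenic* otherwise.
Exon indices are 1-based in transcription order; boundary matching demands
exact coordinate equality, since both the generator and real exon-boundary
back-splices produce exact boundaries — no slack window is applied.

A note on orientation: a back-splice joins a transcriptionally downstream
donor (5' splice site) to an upstream acceptor (3' splice site), so for a
read-through circle the *acceptor* exon belongs to the upstream gene and
the *donor* exon to the downstream gene. Two-gene names follow
`<G1>_e<acceptor>:<G2>_e<donor>` — the pattern that renders a circle over
exon 4 of the upstream gene joined to exon 2 of the downstream gene as
`G1_e4:G2_e2`. Single-gene names `circ<GENE>_<n>` rank the gene's junctions
by coordinates; abundance-based numbering would not be reproducible across
runs.

The spliced sequence concatenates annotated exon sequences from the
acceptor exon through the donor exon in transcription order (for two-gene
circles: upstream-gene exons to the gene's end, then downstream-gene exons
from its start). Non-boundary junctions fall back to the genomic span on
the transcribed strand. Record tables report both spliced length and
genomic span, since published size distributions do not always state which
was plotted.

# Read-through versus homology artifact

Adjacent, highly homologous gene pairs (the MYH6/MYH7 situation) produce
apparent two-gene junctions through read misalignment. The classifier takes
the 50-nt flank on each side of the back-splice junction *from the spliced
circular sequence* (genomic flanks would cross introns) and aligns each
flank against the cDNA of both candidate host genes with a Smith–Waterman
local aligner (match +1, mismatch −2, gap of length g costs 5 + 2g, both
query orientations). A flank *hits* a gene when identity ≥ 0.8 over at
least 25 aligned query bases. If either flank hits both genes the junction
is a `homology_artifact`; if each flank hits only its own host it is
`true_rt`. A flank hitting neither gene cannot create a both-gene hit, so
the call falls to `true_rt` with a low-evidence warning. The explicit hit
rule replaces an external aligner's implicit defaults — the only
reproducible reading; both thresholds are exposed. The rule is monotone:
relaxing thresholds can only move calls toward `homology_artifact`.

The Smith–Waterman kernel is compiled (Rcpp); its scores are checked in the
tests against a quadratic-DP oracle in R and against
`Biostrings::pairwiseAlignment` under the same gap convention.

# Quantification, tiers and correlation

SRPBM (spliced reads per billion mapped) is `count * 1e9 / total_mapped`;
gene FPKM is `count * 1e9 / (exon_length * total_fragments)` with
`exon_length` the gene's exon-union length. The high-confidence tier keeps
circRNAs with ≥ 2 unique reads in ≥ 4 samples of at least one group.
CircRNA/host-gene coupling is assessed by Pearson correlation across
samples for each (circRNA, host) pair against randomly drawn (circRNA,
non-host) pairs — draws are seeded and exclude the circle's own host — and
the two r distributions are compared by a two-sided Wilcoxon rank-sum test,
a distribution-free choice for a comparison whose original test is not
named.

# Differential expression

Counts are scaled to the mean library size (the library size of a circRNA
is the sample's total mapped reads, the same depth notion as SRPBM).
A common dispersion is estimated by pooled within-group moments:
`phi_i = max(0, (s2_i − m_i) / m_i^2)` per feature, median over features
with mean ≥ 1, floored at 1e-6. No tagwise shrinkage is applied — the
common-dispersion NB model is the minimal faithful reading of an
"NB exact test", and it is directly testable for calibration. The test
conditions on the total `t` of the equalised counts: group sums are NB with
size `n_g / phi`, and the two-sided p-value sums the probabilities of all
splits no more likely than the observed one; `phi = 0` collapses to a
binomial split. With equal library sizes this reproduces the classic
count-based exact test to machine precision (checked against `edgeR` in the
tests, which serves as cross-check only).

Fold changes use normalised group means with a pseudocount of 0.5 (fold
change only, never the test). Significance mirrors the published
asymmetry: circRNAs use raw `p < 0.05` with `FC > 2`; the linear-gene track
uses BH `FDR < 0.05` with `FC > 2`. The gene track reuses the same NB exact
test; a shrinkage-based GLM framework is out of scope and this substitution
is deliberate.

# Sponge screening

The miRNA seed is nucleotides 2–8 of the mature sequence; with `S` the
reverse complement of the seed on the target, the counted canonical site
types are `8mer` (= `S`+A), `7mer-m8` (= `S`) and `7mer-A1`
(= `S[2..7]`+A); bare `6mer` sites (= `S[2..7]`) are the weakest canonical
class and are counted only on request. Because the molecule is circular,
scanning runs over the sequence plus its first 7 nt, and positions wrap
modulo the spliced length — a site may span the back-splice junction.
Sites may overlap; each start position yields one site of its most specific
type. Note a structural consequence of per-start typing: every 8mer
necessarily contains a 7mer-A1 starting one base later, and such nested
sites are counted. circRNAs with ≥ 5 sites for at least one miRNA are
sponge candidates; ≥ 10 sites marks the top tier. The network export emits
circRNA–miRNA edges weighted by site count and miRNA–mRNA edges annotated
with the target's differential direction; the "release of repression"
pattern (down-regulated circle, down-regulated target) is reported
descriptively, not causally.

# The synthetic fixture

The generator emulates the statistical structure of the study design, not
its sequences: one ~90 kb chromosome carrying 20 single genes (three
dedicated single-circle sponge hosts with long exons, five genes with long
5' UTRs, five with a long intron, two non-coding), five independent
adjacent same-strand pairs (read-through sources) and five pairs whose
downstream gene is a copy of the upstream gene mutated to 95% identity with
splice-site dinucleotides restored (the misalignment trap). All introns
carry GT/AG on the gene strand. Sixty circles are planted: 15 CDS, 10
UTR-CDS, 5 UTR, 5 intronic, 5 intergenic (the last two classes get AG/GT
dinucleotides written at their planted breakpoints), 10 true read-through
and 10 homology-artifact two-gene circles.

With an exact-match toy caller, true read-misalignment cannot arise
spontaneously, so the artifact configurations plant the *outcome* of
misalignment: chimeric junctions across the trap pair whose reads are drawn
from the chimeric circular sequence. Their anchors fall in ~95%-identical
regions, so a fraction are dropped as non-unique — the designed difficulty
— which is why artifact circles get generous support. The homology
*classifier*, not the caller, is what separates them, as in the published
filtering strategy.

Reads are single-end 100-mers with substitution-only errors (default rate
0): error modelling beyond substitutions would not change the logic under
test. Junction-spanning reads keep the breakpoint at least 20 nt (the
anchor length) from both read ends so every planted read is in principle
callable, making planted support exactly equal to callable support on the
error-free fixture. Per-sample support is Poisson around a planted base
(min 3), modulated by a shared per-sample depth factor and the host gene's
per-sample biological factor — the latter is what makes circRNA/host
correlation real while random circRNA/gene pairs share only depth. Planted
fold changes are four-fold, up and down, including both circles of the
first read-through pair (down), mirroring the published rt-circRNA
dysregulation narrative. Five samples per group reflect the target study
design.

miRNA sites are planted by editing genome bases under the chosen circle
positions: accidental occurrences of any counted site type for any panel
miRNA are first scrubbed from every circle by single-base edits, then exact
numbers of sites are injected (with a guard base after each site so the
background cannot upgrade its type), including one junction-spanning site.
Truth counts therefore match an exact scan, including the structurally
nested 7mer-A1 inside each 8mer. 6mer behaviour is validated against a
brute-force oracle on random sequences rather than fixture truth.

What passing on this fixture does *not* show: robustness to indels and
quality-dependent errors, multi-mapping beyond the trap pair, annotation
noise (inexact exon boundaries), overdispersion calibrated to real heart
data, or genome-scale runtimes. The fixture is a correctness instrument,
not a realism claim.

# Numerical choices and problem sizes

* Anchor length 20, exact match; the published two-mismatch anchor
  extension is approximated by a single `mm` knob applied uniformly.
* Exact-test enumeration is over `0..t` splits; `t` is a few hundred at
  fixture scale, so vectorised `dnbinom` suffices.
* Null calibration in the tests uses 10,000 NB features (mean 20, common
  dispersion 0.1, 5 vs 5) — mean 20 matches the "well-quantified circRNA"
  regime the recovery property also uses; effect recovery uses 2,000
  features with 200 planted four-fold changes.
* The alignment oracle compares 200 random pairs up to 60 nt; the
  seed-site oracle 1,000 random 500-nt circles against 10 random miRNAs.
* Degenerate inputs: zero totals are errors for SRPBM/FPKM; a zero count
  total gives p = 1; zero-variance features are excluded (and reported)
  from correlation; empty two-gene sets yield empty classifier tables.

# Reproducibility

Every stochastic step takes an explicit seed; the generator is
byte-identical under a fixed seed, and a pipeline rerun on the same inputs
reproduces every table. `demo_run(seed)` generates the fixture, runs the
full pipeline and prints the property summary (junction recall/precision,
rt accuracy, site agreement, fold-change direction recovery, host
correlation test).

```{r demo}
library(circheart)
d <- demo_run(seed = 1)
d$summary
```

# Known limitations

The toy aligner is exact and transcript-aware but not a read mapper; the
caller does not handle indels, multi-breakpoint reads or A-rich splice
signal variants (GC-AG, AT-AC); isoforms within one junction are not
reconstructed; TMM-style composition normalisation, tagwise dispersion and
covariates are out of scope; sponge scoring counts seed matches only — no
context scoring, conservation or AGO evidence; cross-study comparison
assumes inputs already share one assembly.
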