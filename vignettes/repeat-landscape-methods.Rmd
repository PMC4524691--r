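---
title: "Methods: repeat landscapes, their gene associations, and planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat landscapes, their gene associations, and planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

# Scope and model

`repeatscape` re-implements, as composable R functions, a complete
repeat-landscape analysis of the kind performed on plant genomes such
as potato and tomato: reconciling repeat-family annotations from
several evidence sources, quantifying where repetitive elements sit
relative to genes, screening orthologue pairs for repeat-borne coding
changes (exonization), attributing gains of transcription-factor
binding sites (TFBS) in promoters to repeat-derived sequence, hunting
eroded repeat relics ("footprints") around orthologous pre-miRNAs, and
accounting for repeat-family expression from RNA-seq, microarray and
small-RNA data.

Genome-scale inputs (reference assemblies, read archives, Repbase
libraries) are deliberately out of reach of a test suite, so the
package carries a first-class synthetic-data module that generates
multi-chromosome genomes with planted repeat families, genes,
orthologue pairs, miRNA loci and read sets, together with a truth
manifest.  Every analysis stage is validated by recovering what was
planted.

## Coordinates and containers

All intervals live in `GRanges`/`IRanges` with the Bioconductor
convention: 1-based, closed intervals.  The three input dialects
convert at the I/O boundary — RepeatMasker `.out` and GFF3 are already
1-based inclusive; BED-style input would convert on read.  Keeping a
single arithmetic convention in one place prevents off-by-one drift;
the choice of the host ecosystem's convention (rather than 0-based
half-open) makes every interval op delegate to `IRanges`.

Coverage and overlap are strand-agnostic throughout; strand is carried
only to build upstream windows (`upstream_flank()`) and to orient
footprint motifs.  Coverage is computed on merged (disjoint) intervals
so nested annotations are not double counted; per-element counts
(genic/intergenic, exonic/intronic) use raw elements, because there
the unit of interest is the annotated element, not the base.

# Annotation reconciliation

Each repeat family may carry up to three labels: de novo
(clustering), homology (library search) and protein-domain evidence.
`reconcile_labels()` applies a fixed decision procedure — unanimous
agreement wins outright ("highest" confidence); otherwise domain
evidence dominates; otherwise the de novo/homology agreement (or the
single present label) decides.  One case is genuinely open: de novo
and homology disagreeing with no domain evidence.  We fall back to the
homology label, because homology against a curated library is
externally anchored evidence while de novo labels are self-referential,
and we flag the record for audit rather than deciding silently.

Families left unknown go through a fixed characterization cascade:
non-coding-RNA hits (`ncRNA_derived`), then nucleotide-database hits
(`pseudo_gene`), then diagnostic SINE motifs such as the internal
Pol III A-box/B-box promoters (`SINE_like`).  The cascade order is a
contract: later evidence never overrides an earlier call, and ties
among hits break deterministically (score, then identity, then
subject id).  The shipped motif patterns are configuration, not code
constants — the diagnostic strings differ between element families and
publications, so tests use synthetic patterns and users supply their
own (`motif_pattern()` takes any IUPAC string plus a mismatch budget).
An `N` in the scanned sequence matches nothing.

# Distribution statistics

`chromosome_coverage()` reports merged-coverage percentages per
chromosome plus a genome total computed by summing base counts before
dividing.  Percentages print at two decimals with half-up rounding
(`round_half_up()`), the convention of published coverage tables; raw
values are kept unrounded in the returned data.

A repeat element is *genic* when it overlaps at least one base of a
gene body or its 5 kb upstream window — the "genic region" of this
analysis tradition includes the upstream window because that is where
exapted regulatory elements act.  Exonic/intronic assignment is
exclusive: an element straddling a junction counts in neither bucket.

`pearson_with_t()` computes the Pearson correlation between
per-chromosome repeat coverage and gene coverage, with
`t = |r|·sqrt(n−2)/sqrt(1−r²)` and a two-sided p from Student's t with
n−2 degrees of freedom.  The t-statistic is reported as a magnitude
(negative correlations carry a positive t), matching how such tables
are printed.  At `|r| = 1` the statistic is the degenerate limit and is
returned as `Inf` with `p = 0`.

Two enrichment tests are provided.  `enrichment_binomial()` is the
exact upper-tail binomial probability.  Its null probability for
"does a uniformly placed interval hit a repeat" is not part of the
published procedure, so we define it constructively:
`p0 = (covered_bases + n_blocks·L)/genome_length`, the closed form for
a uniformly placed interval of length `L` overlapping any merged
repeat block.  It tracks exhaustive placement enumeration to within
one start position per block plus edge clipping (asserted in the
tests) and is exposed as an override.  The intergenic-enrichment
t-test is run on length-normalised densities (elements per Mb of
region class) rather than raw counts, since raw counts conflate
region size with preference; this operand choice is recorded in the
output metadata.

# Exonization cascade

Orthologue pairing uses reciprocal best hits over local protein
alignments (BLOSUM62, affine gaps).  Plain "best match" pairing admits
asymmetric many-to-one pairs that would inflate every downstream
denominator; requiring reciprocity prevents that, and non-reciprocal
best hits are still reported, flagged.

Pairwise alignment is delegated to `Biostrings::pairwiseAlignment`,
with presets mirroring the classic EMBOSS tools: global DNA at
+5/−4, gap open 16 / extend 4; global protein at BLOSUM62, 12/2.  The
gap convention is `open + L·ext` for a gap of length `L`.  The test
suite carries an independent Gotoh dynamic-programming oracle and
checks score equality on random sequence pairs, so the engine is
cross-validated rather than trusted.

`extract_diffs()` reduces a global alignment to maximal indel runs and
per-column substitutions with ungapped coordinates in both sequences;
applying the diffs regenerates sequence B exactly (round-trip tested).
Diffs project to the genome through the exon ladder
(`transcript_to_genome()`); a diff spanning an intron projects to
multiple segments and overlap with a repeat on *either* segment sets
the flag.  Whether a repeat-borne diff requires repeat overlap in both
species or either is unstated in the tradition this follows; the
default is *either* (a repeat relic recognisable in even one genome is
evidence of repeat origin), with a *both* mode available.

Codon propagation classifies substitutions as synonymous or not by
codon lookup, length-divisible-by-3 indels as amino-acid indels, and
everything else as frameshifts; pairs whose CDS carries an internal
stop are excluded from downstream counts, mirroring the attrition such
cascades apply.  The structure-prediction stages of the original
analysis chain (secondary/tertiary structure, contact maps) are out of
scope; the cascade ends in a `structure_candidate` count fed by an
external flag column.

# TFBS gain/loss

Binding-site hits are pluggable input (the probabilistic scanners that
produce them are external); the bundled IUPAC scanner generates hits
for synthetic tests.  For each TF and orthologue pair,
`delta = count_A − count_B` over the 2 kb promoter windows.  Which of
the (possibly interleaved) sites constitute the surplus is not
observable from counts, so the `|delta|` lowest-scoring (most-3' on
ties) sites are taken — deterministic and conservative, since
higher-confidence sites are treated as the conserved ones.  A gained
site is repeat-borne when it overlaps a repeat by at least one base;
the per-TF binomial screen uses the repeat-covered fraction of the
promoter windows as its data-driven null, and Benjamini–Hochberg
q-values are reported alongside raw p-values because the published
procedure tests dozens of TF families without correction.

# miRNA footprints

Pre-miRNAs map to the genome by exact/near-exact matching (every
placement with at most one substitution, both strands), giving
multi-locus families one record per placement.  Orthologous pre-miRNA
pairing requires both the same family stem (miRBase naming) and a
reciprocal sequence match at ≥ 0.7 identity — a name alone is not
enough, since family nomenclature can outlive sequence similarity.

The footprint detector repeatedly takes the best local alignment
between the two 2 kb + hairpin + 2 kb flank bundles, records its
ungapped exact-match runs of ≥ 5 bp as motifs, masks the aligned spans
with `N` (scored prohibitively), and iterates until no alignment
reaches `min_score`.  Masking guarantees termination and
non-overlapping motifs.

The scoring needed empirical care.  Classic water-style parameters
(match +5 / mismatch −4, gap open 10, extend 0.5) have a *positive*
expected score on random DNA: unrelated 4 kb flanks chain into
alignments scoring in the thousands, which would make any fixed
threshold meaningless.  We therefore price gaps steeply (open 25,
extend 10) and set `min_score = 100` — the score of a 20-bp exact
match — calibrated against the empirical null: the maximum score over
random 4.2 kb flank pairs is ≈ 86, while a 30-bp relic at 10%
divergence still scores 123.  Both the null and the recovery are
exercised in the tests.

A footprint motif is kept when it overlaps a repeat in at least one
species; the pair is classed `both`/`a_only`/`b_only` by where the
repeat support lies, and graded *strong* when at least two kept motifs
appear in the same relative order and orientation in both species —
"same arrangement" is operationalised as order plus orientation, with
spacing deliberately unconstrained.

# Abundance accounting

`rpkm()` is the standard `10⁹·c/(N·L)`.  The family average divides
the summed member abundances by members × conditions; members
expressed in no condition contribute zeros to the grid, so the
denominator always reflects the family's full size (the alternative —
dividing by expressed members only — would reward families with one
active copy, which is not what "average abundance of a family" should
mean).  Microarray probes assign to a gene when the best placement
covers > 90% of the probe, then to a repeat under the same rule, gene
priority strict.  Small-RNA reads are adapter-clipped (leftmost
adapter-prefix occurrence, ≥ 6 nt exact overlap), length-filtered at
17 nt, purged of exact substrings of ncRNA/transcript sequence
(degradation products), deduplicated, and mapped to repeat sequences
allowing one substitution on either strand.  Multi-mapped reads count
once per matched family by default (matching how per-family
percentages are usually reported, without fractional allocation); a
fractional mode is available.  The ≤ 1-mismatch mapper returns the
exact Hamming-neighbourhood hit set, which the external short-read
aligners it stands in for only approximate.

# The simulator and what it does not emulate

`sim_config()` fixes the study conditions; the seed fully determines
every output (integer RNG streams only, so runs are byte-identical
across platforms).  Defaults: 3 chromosomes × 200 kb; six repeat
families spanning LTR (Gypsy, Copia), LINE, two DNA-transposon
superfamilies and a SINE, ~620 copies total with per-family divergence
between 5% and 18% (a 9:1 substitution:indel event mix, the
conventional decay model); 200 genes with 1–4 exons; exonization rate
`q = 0.2`; 14 footprint-positive miRNA pairs against 6 negatives with
30-bp relics; negative-binomial expression with per-family means
(5–80) and dispersion 2 over 5 conditions; 4000 small-RNA reads with a
24-nt length peak and a real adapter appended.  Background GC is 0.5;
the *Solanum* genomes are AT-rich, but composition does not enter any
statistic tested here.

Planted exonization events are 3-bp in-frame deletions placed so their
genomic projection lies inside a planted "exonized repeat" segment;
clean pairs carry substitutions only.  This makes the recovered rate
an unbiased estimate of `q` and is the acceptance backbone.  What the
simulator does *not* emulate: nested/fragmented insertions with
realistic age structure, splice-site biology of real exonization,
sequencing error, expression covariance between conditions, or
assembly gaps.  Passing tests therefore demonstrate that the
*computations* are correct and recover planted truth — not that the
biological effect sizes of real genomes would be detected at these
desk-scale sizes.

Problem sizes used by the validation suites (100 random ≤ 100 kb
interval fixtures; 30 random alignment pairs; 200 orthologue pairs;
500 enrichment replicates) were chosen as the package's own
desk-scale study conditions and give sub-percent Monte-Carlo noise on
every recovered parameter.

# Numerical and degenerate-input choices

* Exact binomial tails come from `pbinom` (log-space internally), and
  `p0` is capped into `(1e−9, 1−1e−9)` so degenerate landscapes (no
  repeats, all repeats) stay inside the open interval the test
  requires.
* `|r| ≥ 1 − 1e−15` maps to `t = Inf, p = 0` — the perfect-correlation
  limit is flagged rather than returning a floating-point artefact.
* Paired t-tests on zero-variance differences return `t = 0, p = 1`
  (identical vectors) or `p = 0` (constant shift) instead of erroring.
* All tie-breaks (best hits, surplus sites, alignment traceback) are
  deterministic, so identical inputs give identical outputs
  everywhere; the pipeline asserts byte-identical reruns.

# Known limitations

* The reconciliation fallback (homology over de novo) and the binomial
  nulls are reasoned defaults, not published procedure; both are
  surfaced in outputs and overridable.
* The footprint detector's threshold is calibrated for ~4 kb flank
  bundles; much longer flanks raise the null maximum and would need
  recalibration (the null scales roughly with the log of the search
  area).
* `find_orthologs()` is all-vs-all and meant for desk-scale proteomes;
  genome-scale orthology should come from a dedicated tool, with the
  cascade consuming its pairs.
* The microarray path assumes pre-normalised expression values, and
  the RNA-seq path consumes counts; neither implements normalisation
  or spliced alignment.
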