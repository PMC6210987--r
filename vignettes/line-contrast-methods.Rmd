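---
title: "Methods: line-unique fixed SNP discovery from pooled resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-unique fixed SNP discovery from pooled resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linemarker)
```

## The design and its statistical model

`linemarker` implements a contrast between two divergently selected lines,
each sequenced as a *single pooled library* of `pool_size = 10` diploid
individuals. Pooling changes what a "call" means: read counts at a site
estimate the pool allele frequency on the `1/(2 × 10) = 1/20` chromosome
grid, and individual genotypes are unrecoverable. The analysis therefore
works entirely with per-site read-count summaries:

* `SNP%` — the supporting-read fraction, `alt count / depth`, stored as a
  fraction in `[0, 1]`. Under the pool model, at a site fixed in the pool
  (frequency 1) the expected SNP% is `1 − e` for per-base error rate `e`;
  at a site segregating at frequency `f` it concentrates around `f`
  binomially with the depth as sample size.
* *Fixed within a pool* is operationalized as `SNP% ≥ 0.75`. At the
  coverages this design anticipates (~11×), a hard cutoff of 1.0 would be
  destroyed by a single error read; 0.75 keeps fixed sites while excluding
  balanced heterozygous frequencies (0.5) with reasonable margin.
* *Line-unique* removes any site called in the other line's pool. The
  default key is the `(contig, position)` pair — the contrast is about
  *sites* differing between lines; an allele-level key is available for a
  stricter contrast (`key_mode = "allele"`).

The candidate-marker cascade applies, in order: unique-to-line,
`SNP% ≥ snp_pct_min`, region = CDS, amino-acid-changing impact, and
`depth ≥ depth_min`. The stages are pure intersections, so the final set is
order-independent; the per-stage tallies in the `FilterReport` follow this
documented order. There is deliberately no multiple-testing machinery: the
procedure is thresholding, not hypothesis testing.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `snp_pct_min` | 0.75 | fraction | fixation proxy robust to error at ~11× |
| `depth_min` | 10 | reads | one read per pooled individual on average |
| `min_alt_count` | 2 | reads | caller-style floor applied at ingestion |
| `impact_classes` | non-synonymous, frameshift, nonsense, no-start, no-stop | — | amino-acid-changing set |
| `coverage` | 11 (focal), 14 (contrast) | × | the study's sequencing depths |
| `error_rate` | 0.001 | per base | typical short-read substitution error |
| `primer_length` | 20 | nt | standard allele-specific PCR oligo |
| amplicon window | 100–400 | bp | agarose-resolvable product range |
| annealing buckets | 55, 63 | °C | the two thermocycler programmes used |

## Coordinates, strands and annotation

All coordinates are 1-based inclusive throughout (the VCF/GFF3/HGVS
convention); no half-open interval is ever exposed. Alleles in pooled site
records are always on the + (reference) genomic strand; complementation
happens only inside the annotator. For a minus-strand gene, CDS position 1
maps to the *highest* genomic coordinate of its last segment, which is why a
record whose reference base is `T` can carry the coding-level notation
`c.…A>G`.

Effect annotation is codon-local: the spliced, strand-oriented CDS is
extracted, the affected codon substituted, and both codons translated with
the standard genetic code. The package keeps the fine impact taxonomy
(synonymous / non-synonymous / nonsense / no-start / no-stop / frameshift)
internally and offers a display convention that folds every
amino-acid-changing substitution into the single label `N-syn`, matching how
such tables are usually printed. Precedence within the classifier: deletion
→ frameshift; stop gain → nonsense; initiator loss → no-start; stop loss →
no-stop; silent → synonymous; otherwise non-synonymous. Stop gains render
with the legacy trailing dot (`p.Y111.`) by default; `stop_char = "*"`
switches to the modern style.

Three deliberate edge-case choices:

* A gene whose CDS length is not divisible by 3 loads with a warning and is
  flagged; protein-level annotation of its variants returns a
  `partial-CDS` marker rather than guessing a frame.
* One CDS per gene id: alternative transcripts are out of scope, and
  overlapping CDS segments under one gene id are an error.
* Frameshift is reachable only through the single-base deletion channel —
  an SNV cannot shift frame — and insertions are out of scope.

`check_printed_consistency()` validates a printed `c.`/`p.` pair without
knowing the transcript: (a) the c. position must imply the p. residue under
codon arithmetic, and (b) a brute-force search over all codons of the
reference amino acid must find one carrying the c. reference base at the
implied offset whose substitution yields the claimed amino acid. Compound
heterozygous pairs are matched set-wise because published tables do not
always order the two allele annotations consistently. This is intentionally
a *consistency* check, not a coordinate reproduction: which transcript the
original vendor software numbered against is unknowable from the printed
table alone.

## Region classification

Each site gets exactly one label with precedence
`CDS > mRNA-noncoding (UTR) > ncRNA > tRNA > intron > intergenic`.
A position inside an mRNA span but outside the CDS segments is `intron` when
it lies between the gene's CDS segments and `mRNA-noncoding` when outside
them. Sites in none of the annotated spans are `intergenic`.

## Allele-specific primer design

For each SNV the designer emits the F1/F3/common-reverse trio: both forward
primers end exactly on the SNP base (F1 = reference allele, F3 = variant
allele, template-strand oriented) and both carry a deliberate mismatch at
the third position from the 3′ end, replacing the template base with its
transversion partner (A↔C, G↔T; if the primer already carries that base,
the other transversion is used, so the result always mismatches). The
transversion rule itself is a documented package choice — the original
assay protocol does not specify which substitution it used.

The reverse primer is chosen from the downstream amplicon window by Wallace
Tm proximity to the mean of the two forwards (ties go to the shortest
amplicon), and the trio's annealing temperature is the member of
`{55, 63}` °C nearest the trio's *minimum* Tm — the weakest primer limits
the annealing step. Forward primers may be designed on either strand;
`strand = "auto"` prefers the strand whose base adjacent to the SNP
strengthens the 3′ clamp, with the + strand as tie-break.

The Wallace 2–4 rule is crude by design: it is dependency-free, exactly
reproducible, and sufficient for two-bucket assignment; the `tm_fun`
argument accepts any alternative model. Its limits are real: the published
trio set contains pairs with essentially identical Wallace Tm profiles but
different printed annealing temperatures, so no Tm-only rule can reproduce
every published assignment — the acceptance script reports the agreement
count it actually computes, and the empirical temperatures were presumably
optimized on the thermocycler rather than derived from a formula.

## What the synthetic generator does and does not emulate

`simulate_study()` builds a genome (default 2 contigs × 60 kb, 12 genes on
both strands, 1–3 exons each, every CDS a clean ORF), plants every variant
class the cascade must discriminate — line-unique fixed non-synonymous /
synonymous / nonsense / start-loss / stop-loss SNVs, 1-bp CDS deletions,
shared fixed SNVs, low-frequency (5/20) SNVs, intronic and intergenic
SNVs — and draws pooled counts: depth Poisson around the line coverage
(floored at 1), variant reads binomial at the pool frequency adjusted for a
symmetric 0.001/base error, plus error-only records sprinkled at non-variant
positions whenever at least `min_alt_count` error reads accumulate.
Everything is deterministic given the master seed, down to the serialized
FASTA/GFF3/VCF bytes.

The truth manifest flags as `expected_final` exactly the variants a correct
pipeline must recover: frequency 1 in the focal pool, 0 in the contrast
pool, in CDS, amino-acid-changing. At 11× coverage a substantial fraction of
true sites legitimately falls below `depth_min = 10` (Poisson mass below 10
at mean 11 is ≈ 0.34), so recovery is assessed *depth-adjusted*: the tests
require zero false positives and no miss that is not attributable to the
depth stage.

Deliberately not emulated: read-level artifacts (mapping error, base-quality
structure, strand bias, indel realignment), reference bias, copy-number
variation, and linkage between sites. Passing tests therefore demonstrate
the correctness of the *filtering and annotation logic* under the stated
statistical model, not robustness to alignment pathology in real data.

## Problem sizes used by the test suite

The suite exercises: exhaustive genomic↔CDS round-trips on unspliced and
spliced models of both strands; equivalence of the codon-local annotator
with an independent full-CDS-translation oracle on 10,000 random SNVs;
filter monotonicity under random threshold pairs; and end-to-end
planted-truth recovery on five independently seeded synthetic studies.
These sizes keep the full suite in the low minutes on a single CPU while
covering every strand/splice/impact combination.

## Known limitations

* Multi-allelic sites are ingested as one record but annotated per alt
  allele independently; no joint haplotype interpretation.
* The unique-to-line contrast treats absence of a call as absence of the
  variant — at marginal depth this conflates "not present" with "not
  observed"; the depth filter mitigates but does not eliminate this.
* Primer design screens neither hairpins nor primer-dimers; trios should
  still be checked with standard oligo QC before synthesis.
* The compatibility impact label `N-syn` is lossy by construction; use the
  fine taxonomy for any downstream analysis.
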