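---
title: "Methods: isoform and mutation analysis of single-cell long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform and mutation analysis of single-cell long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclriso)
```

`sclriso` analyzes nanopore cDNA reads from droplet-based single-cell
RNA-seq in a hybrid design: cell barcodes and cluster labels come from
matched short-read processing, and the long reads contribute isoform
structure and sequence variants. This vignette documents the models,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the simulation-based tests do and do not
establish.

## Read model and demultiplexing

A 3′-protocol read is `adapter + barcode(16) + UMI + oligo(dT) + antisense
cDNA`, on either strand, with nanopore errors throughout. Demultiplexing
anchors on the adapter with a semi-global alignment (the adapter aligned
end-to-end, free end-gaps on the read) under unit edit costs on both
strands; the better strand wins, ties go to the forward strand. The
default tolerance of 6 edits on the 22 nt adapter (~27%) accepts typical
nanopore error while keeping spurious anchors rare; it is exposed as
`flank_max_ed`.

Barcodes are matched against the short-read whitelist at edit distance
≤ 2 (`barcode_max_ed`). A tie between two whitelist entries at the
minimal distance has no defensible winner and the read is discarded, as
are reads with no adapter or no in-tolerance barcode. The UMI is taken as
a fixed-length slice (`umi_length`, 10 nt for 3′ v2 chemistry) rather than
delimited by the oligo(dT) tract: indels can shorten the observed UMI, and
the downstream edit-distance collapse absorbs 1–2 nt of slippage more
robustly than a delimiter search. The oligo(dT) scan accepts a run of
≥ 4 T with one non-T interruption per run, since isolated substitutions
inside the tail are common. Matched payloads are written sense-oriented
with the `{barcode}_{UMI}#{read}` header that every later stage parses
through one function.

## Isoform discovery

The unit of isoform identity is the **splice chain**: chromosome, strand
and the ordered intron list in 0-based half-open coordinates (GTF/GFF I/O
converts at the boundary). Alignment gaps of at least `min_intron` (30 bp)
count as introns; shorter gaps are indistinguishable from deletions at
nanopore error rates and are absorbed.

Junction grouping is a greedy majority vote per coordinate column: the
most supported coordinate becomes a representative and absorbs sites
strictly within `jct_tol` (5 bp), ties breaking to the lower coordinate,
so the result is independent of read order. Grouped chains are corrected
against reference junctions of overlapping genes (same strict tolerance),
and a corrected chain identical to a reference transcript's chain with
both ends strictly within `end_tol` (100 bp) adopts that transcript's
identity and exact coordinates. Representative transcript ends of a group
are the member medians — a robust choice among reasonable alternatives
(mode, extreme) that the grouping step leaves open.

Gene assignment for the remaining novel chains is the overlapping
annotated gene sharing the most junctions, ties resolved by larger
genomic overlap, with `novelGene_*` identifiers when nothing overlaps.
Whether correction may snap two distinct junctions onto the same
reference junction was left open by the procedure's description; it is
permitted here and the duplicate is dropped, which keeps correction
monotone. Merging with a reference transcript requires *both* ends within
tolerance — the stricter reading — so that a 3′-complete but 5′-truncated
chain is handled by the truncation model rather than silently merged.

Truncation collapse: a chain whose introns form a consecutive sub-chain
of a longer isoform of the same gene, anchored at the protocol-proximal
end (3′ for the three-prime protocol, strand-aware) with proximal ends
within `end_tol`, is collapsed into the parent unless its support exceeds
`f(L)·support(parent)`, with `f(L) = clamp(trunc_slope·L +
trunc_intercept, 0, 0.95)` and `L` the parent's transcript length. The
linear form captures that longer transcripts shed proportionally more
incomplete cDNAs. The default slope of 1e-4 per bp (intercept 0) is
deliberately conservative — a 1 kb transcript tolerates truncated
sub-chains up to 10% of its support — and is exposed in the configuration
as an uncalibrated parameter; datasets with heavy degradation warrant a
larger slope.

## Quantification

A second genome-scale alignment round is replaced by an in-package
projection: a read is compatible with an isoform when the isoform's
introns falling strictly inside the read's span match the read's introns
one-for-one within `jct_tol`, and the aligned-base score and transcript
coverage follow from the projected exonic overlap. This keeps the package
free of external aligner invocations while preserving the assignment
contract; an optional passthrough to a spliced aligner exists for users
who prefer a realignment round against the transcript FASTA.

Assignment picks the best-scoring compatible isoform. Because projection
gives equal aligned-base scores to every compatible isoform, a strict
"score tie means ambiguous" rule would discard every read from a
transcript whose chain is a sub-chain of a longer sibling; score ties are
therefore broken by transcript coverage, and only reads tied on both are
ambiguous. Reads below 60% transcript coverage (`min_assign_cov`) or with
less than half the read aligned are discarded; full-length status
requires coverage strictly above 95% (`fl_cov`). Transcripts with fewer
than 5 full-length reads (`min_fl_support`) are removed and their reads
discarded rather than reassigned — reassignment would need a second pass
whose behavior the original procedure does not define.

UMIs are collapsed per (barcode, gene) — not per (barcode, transcript) —
as connected components at edit distance ≤ 2: alignment noise can spread
one molecule's reads across sibling isoforms, and gene-level grouping
with majority-transcript voting (ties to the better-supported transcript,
then lexicographic) prevents double counting. Connected components match
the flat "within edit distance 2" notion; directional collapse (as in
short-read UMI tools) is deliberately not used.

## Classification and splicing events

Categories follow the SQANTI scheme: FSM (chain equals a reference
chain), ISM (non-empty consecutive sub-chain), NIC (novel combination of
sites known *for that gene* — a donor borrowed from another gene does not
make a junction known), NNC (novel site), with mono-exon chains FSM when
contained in a mono-exon reference transcript and "other" otherwise.
Splicing differences between a gene's two most abundant isoforms are
typed by partitioning the symmetric difference of their chains into exon
skipping, alternative 5′/3′ sites (strand-aware; terminal differences
beyond `end_tol` count as alternative promoter/polyadenylation), and
intron retention; more than one event of any type is "complex" (the
event-count rule, not the event-type-count rule — the alternative is a
one-line change and was judged less faithful to "more than one splicing
event"). Mutually exclusive exon pairs surface as two skipping events and
hence "complex".

## Differential transcript usage

Transcripts sharing an intron chain are summed (usage differences at
identical internal structure are end-choice differences, not splicing),
counts are aggregated to pseudo-bulk per cluster to tame dropout, and a
gene is testable when at least two of its chains each carry strictly more
than 15 UMIs. The tested table is the union over clusters of each
cluster's top-2 transcripts — so more than two rows are possible — and
the statistic is the Pearson chi-square of independence without
continuity correction in every table size, for cross-dimension
consistency (R's `chisq.test` would apply Yates correction to 2×2 tables
by default; `dtu_continuity = TRUE` restores that behavior for
comparison). Genes whose table collapses below 2×2 after removing empty
rows/columns are reported as not testable rather than given p = 1,
distinguishing "no test" from "no evidence". BH adjustment runs across
testable genes only; the significance bar is adjusted p < 0.01.

## Variant analysis

Candidate SNVs are pileup positions outside homopolymer runs longer than
3 nt, with at least 100 reads (`snv_min_cov`; applied to the global
pileup — per-cell informativeness only requires one read) and reference
allele frequency in [10%, 90%]. Pileups use only M/=/X alignment columns,
ignore indels, and drop bases below quality 7.

The clonality filter formalizes "errors are independent of barcode":
under the null each cell's alternative-read count is Binomial(n_cell,
p̂) with p̂ the site's global alternative frequency. Each informative
cell gets an exact two-sided binomial p-value (minimum-likelihood
definition, i.e. `binom.test`; it coincides with the doubled tail at
p̂ = 0.5), and the site-level p-value is the minimum cell p-value
Bonferroni-corrected by the number of informative cells. How per-cell
evidence should be scalarized into one site test was left open by the
procedure's description; min-p-with-Bonferroni was chosen because it is
conservative, exactly testable, and isolated in one function so that
alternatives (Fisher combination, beta-binomial dispersion) can be
swapped. Sites are BH-adjusted and kept at adjusted p < 0.05, then
tested for differential allele frequency across clusters exactly as in
the DTU stage; per-cell alternative and reference count matrices are
exported for external dimensionality reduction.

RNA editing and allele-specific expression can mimic clonal variants; no
pre-masking of edited sites is attempted, and orthogonal validation of
kept sites remains the user's responsibility.

## The simulator, and what the tests show

`sim_design()` fixes every generative knob: gene loci spaced 1 kb on a
random genome; 2–3 isoforms per gene built from a base model by exon
skipping, alternative sites and intron retention (the retained intron is
never the 3′-terminal one, so no isoform is a pure 3′ sub-chain of a
sibling by construction); cluster-specific isoform usage (a fixed
decreasing mix, or an 0.8/0.2 switch for designated DTU genes); unique
UMIs at pairwise distance > 2 within each cell/gene group; 5′ truncation;
i.i.d. substitution/insertion/deletion errors (defaults 5%/1%/1%, the
realistic nanopore regime); and planted subclonal SNVs in carrier cells'
3′-terminal exons. The simulator emits the FASTQ *and* a "perfect"
spliced alignment at the pre-error coordinates (substitutions and
junction jitter applied, indels left to the aligner abstraction), so the
whole pipeline runs without an aligner and every test is hermetic.

Desk-scale problem sizes are used throughout: the round-trip properties
run at 20 genes / ~50 isoforms / 100 cells / 20 000 reads; DTU
calibration at 500 null genes of 200 UMIs per cluster; the variant
operating characteristics at 200 cells × 10 reads per site over 20
simulation replicates. These sizes make the exact-recovery properties
sharp (zero-noise round trips must match truth entry-for-entry) while
keeping the full suite within a few minutes.

What passing does *not* show: the error model is i.i.d. per base, so
homopolymer-biased indels, basecaller-specific signatures and
reference-bias at splice sites are unrepresented; alignments are ideal,
so multi-mapping and supplementary-alignment artifacts never occur; and
barcode collisions are excluded by constructing whitelists at pairwise
distance > 4. Real datasets will show lower barcode yield and some
spurious isoforms that these tests cannot predict.

## Degenerate inputs and tie-breaking

Empty FASTQ, annotation, alignment and count inputs yield empty,
well-formed outputs. All order-dependent steps (junction clustering,
molecule voting, novel-id assignment) break ties deterministically
(support, then coordinate or lexicographic id), so every stage is
invariant to input permutation — a property the test suite asserts
directly.
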