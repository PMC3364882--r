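---
title: "Comparing an assembled strain genome to its reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing an assembled strain genome to its reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`straincomp` analyses the differences between a de novo assembled microbial
genome (the *query*, typically a set of contigs) and an annotated *reference*
genome of a closely related strain. The workflow mirrors what a comparative
resequencing study of two laboratory yeast strains needs end to end:

1. whole-genome alignment of contigs to the reference;
2. SNV and small-indel calling with gene-effect annotation;
3. copy-number analysis from the read-depth ratio of the two strains;
4. classification of assembly gaps and of LTR-retrotransposon loci;
5. gene presence/absence with a high-confidence deletion list;
6. query-unique regions and their conservation in other strains;
7. mosaic genome painting and a coverage-distance UPGMA phylogeny;
8. EASE-score category enrichment of affected gene lists.

Short-read mapping, de novo assembly and gene prediction are out of scope:
contigs, gene models and depth tracks are inputs. A synthetic genome-pair
simulator with a complete truth table stands in for sequencing data, so every
stage is validated against planted ground truth.

# Alignment model

## Seeding, chaining, gap closure

Alignment is anchor-based. Maximal exact matches (MEMs, default minimum
20 bp) are found with a 2-bit packed k-mer index and maximality extension;
`N` never matches any base, including another `N` — the conservative
treatment of ambiguity. Collinear same-strand anchors within
`max_join_gap` (default 10 kb) are chained by dynamic programming that
maximizes anchored length under an affine-style gap penalty; chains are
peeled off in order of decreasing score, so alternative placements of
duplicated sequence survive as secondary blocks. Inter-anchor gaps are
closed *exactly* by unit-cost (Levenshtein) dynamic programming; blocks
whose size product is small enough (default `polish_max = 4e6`) are
re-polished by full DP, so their edit paths are optimal. A gap too large to
close splits the block (the band-overflow rule). Block ends are extended by
greedy gap-free walks with an X-drop of 12.

Two details keep structural events clean. The chain gap cost is subadditive
in its asymmetric part, so two nearby structural events separated by
anchored sequence (say, a deletion and a novel insertion a few hundred
base pairs apart) chain *through* the anchors between them as two clean
gaps rather than being skipped into one smeared gap. And a filled gap
whose two sides turn out to be unrelated — fewer than 0.75 matches per
position of the shorter side, where unrelated DNA aligns at ~0.56 under
unit cost and genuinely homologous sequence at ≥ 0.95 — is rewritten as
one deletion run plus one insertion run, so replacement-like differences
become two structural records instead of a cloud of spurious small indels.

Redundant blocks whose query *and* reference intervals both lie inside a
larger same-strand block are dropped; these arise as self-similar
re-alignments of tandem arrays at a unit shift and carry no information the
containing block does not.

## Edit-path representation and tie-breaks

Edit paths are CIGAR-style strings over `{=, X, I, D}`. The unit-cost DP
records, per cell, the bitmask of cost-optimal moves; the traceback prefers
extending the gap run it is already in, then the diagonal, then `D`, then
`I`. This keeps equal-cost indels contiguous (the behaviour affine-gap
callers achieve with an opening penalty) without rewriting tied mismatch
pairs as spurious gap/match/gap triplets, and it is deterministic. Indels
are left-aligned within their repeat context before reporting, the VCF
normalization convention.

## Identity and structural gaps

Block identity is matching columns divided by aligned columns, **excluding
gap runs longer than the structural threshold** (90 bp, the small-indel
cap). Without this exclusion a single transposon-sized deletion inside an
otherwise near-perfect 25 kb block would drag its identity far below the
97% variant-calling cut and silence every SNV around it; with it, identity
measures alignment noise while structural events are reported separately.
Identity remains exactly recomputable from the edit path.

## Ambiguity

A block is *ambiguous* when more than half of its query interval is also
covered by other blocks of identity at least 0.95. The definition is
query-side: it flags competing placements of the same assembly sequence
(e.g. one query segment matching two reference copies of a duplication).
Variant calling drops ambiguous blocks outright rather than down-weighting
them — reproducing the practice of calling only from non-ambiguous
mappings.

# Variant calling and annotation

Only non-ambiguous blocks with identity ≥ 0.97 contribute. Mismatch columns
become SNVs; gap runs of ≤ 90 bp become indels; longer runs are logged as
structural events. Calls are sorted and deduplicated (duplicate evidence
from overlapping blocks collapses to one record).

Tandem repeats are detected exhaustively as maximal perfect arrays with
unit ≤ 60 bp and span ≥ 2 units; contained reports are dropped and, for
identical spans, the primitive (smallest) unit wins. Calls overlapping an
array are flagged (`TRF` in the VCF).

Gene effects use the standard nuclear code on the coding strand:
synonymous SNVs are labelled `sense`, amino-acid changes `missense`, and
changes that create or destroy start/stop usage `start_stop_altered`
(stop-gain SNVs are folded into this class by codon outcome). In-CDS
indels are `frameshift` iff their length is not a multiple of three;
in-frame indels that touch the first/last codon or introduce a premature
stop are `start_stop_altered`, otherwise `inframe_indel` with
`frame_preserved = TRUE`. Gene models here are intronless single-CDS
records; genes whose CDS length is not a multiple of three are skipped
with a warning.

# Copy-number analysis

Depth tracks are tiled into 414 bp windows (the last window of each
chromosome keeps its true width; window mass is conserved exactly). The
per-window ratio is computed after library-size scaling and normalized to
an average of 1 per chromosome. The default normalization divides by the
per-chromosome **geometric** mean ratio: this makes gain/loss symmetry
exact (swapping the two strains negates every log2 ratio) and is the
multiplicative reading of "average ratio 1". The arithmetic mean and
per-track depth normalizations remain selectable because the verbal
definition admits all three.

Significance per window uses the Geary–Hinkley transformation of a ratio
of Poisson-approximated Gaussians: with counts `x`, `y`, scale
`R = total_test/total_ref` and null ratio `r0 = 1`,
`t = (x − r0·R·y) / sqrt(x + r0²·R²·y)` is approximately standard normal
and `p = 2(1 − Φ(|t|))`. The approximation is a large-count one; at the
per-window read counts of a high-coverage study (hundreds to thousands)
the null p-value distribution is uniform to within Kolmogorov–Smirnov
tolerance, which the test suite checks at 1,725 reads/window. Windows with
zero reference count are tested against a 0.5 pseudo-count and flagged.

Segments are maximal runs of ≥ 3 consecutive windows with |log2| ≥ 0.6 and
consistent sign (the 0.6 cut is the conventional default; the 3-window
rule suppresses single-window Poisson outliers, on which the source
convention is silent). Window p-values combine by Fisher's method. The −4
display cap applies only at serialization; in-memory statistics are never
capped.

# Assembly QC

Contigs are tiled onto the reference by their best block (aligned length ×
identity, ties to the smaller coordinate). Gaps between consecutive
placements are labelled by cause: `missing_sequence` when the query-read
depth track has a zero-coverage stretch in the gap (the data are absent),
`unassembled` when the gap overlaps a reference self-repeat (> 95%
identity elsewhere in the genome — the data are present but unplaceable),
`both`, or `unexplained`. Both flags are recorded independently alongside
the combined label.

Annotated transposon loci are classified into the three observable
situations: `absent_gapped` (GA) — a single spanning block carries an
internal deletion gap within ±20% of the element length; `present_break`
(CB) — distinct contigs terminate within 1 kb of the two flanks;
`present_assembled` (AS) — a spanning block with no gap ≥ 100 bp inside
the locus. Precedence is AS > GA > CB, and loci matching no pattern are
conservatively called `present_break` with a warning. The GA size
tolerance, flank window and minimum gap are configurable; the deletion gap
is measured on the query side (the element absent from the query). Only
non-ambiguous blocks participate, which prevents element-body alignments
from other loci from faking AS calls at excised loci.

Per-family copy numbers are estimated from the library-scaled depth ratio
over each annotated element; the family estimate is the reference copy
count times the **mean** per-element ratio, rounded. The mean (not the
median) is used because each element contributes its own copy ratio to the
family total; with half the elements excised the mean recovers half the
count while a median would collapse to one of the modes.

# Presence/absence and unique regions

A gene is *mapped* when a block covers ≥ 80% of its span with per-gene
identity ≥ 95% (identity is computed over the gene's columns, so a
deletion gap inside a spanning block correctly yields no coverage). The
80% coverage floor is required to make the identity cut meaningful and is
exposed as a parameter. Status combines the assembly and the depth
evidence: `present`, `low_depth` (mapped but depleted), `absent_in_assembly`
(an assembly dropout, *not* a deletion), and
`deleted_high_confidence` — unmapped **and** mean log2 ratio < −0.6. The
intersection is the point: genes lost from the assembly at repeats but
present in the data never reach the high-confidence list. Sequencing
dropouts (regions with no query reads at all) do satisfy both criteria and
are an irreducible blind spot of the intersection rule; the simulator can
plant them precisely to expose this.

Unique regions follow the best-alignment-per-position rule: for every
reference position only the best-identity block covering it is kept; query
positions not covered by any kept alignment above 95% identity, merged
into runs ≥ 500 bp, are unique. The extra copy of a query duplication
therefore surfaces as unique — only one copy can win its reference
positions. The 500 bp floor is a configurable artifact choice.

The conservation screen aligns each unique region against a panel of
strain genomes and keeps hits with query coverage > 60% **and** identity
> 90% (strict inequalities); all passing strains are reported to support
Venn-style occurrence summaries.

# Mosaic painting, coverage distance, UPGMA

Mosaic painting divides the query into non-overlapping 1,000 bp fragments.
Per fragment and strain group, the best identity across the group's
genomes is the fraction of fragment positions aligned as matches, each
position taking its state from the best block covering it. Channels scale
linearly between 0.97 (→ 0) and 1.00 (→ 1). Uncovered fragments get
channel 0. Group identity is a maximum, hence order-free, and painting a
genome against a panel containing itself yields channel 1 for that group.

The coverage distance is `d = 1 − 2C/(|A|+|B|)` with `C` the average, over
the two alignment directions, of the number of positions that are
reciprocally alignable *and identical* (blocks ≥ 90% identity,
best-per-position). It is 0 on self, 1 for unalignable pairs, symmetric,
and grows smoothly with substitution divergence. The function the
formula interprets is cited but not printed in the source literature, so
the implementation is isolated behind one function with its cut-offs
exposed, and alternatives can be swapped in.

UPGMA uses proportional (size-weighted) averaging with merge ties broken
by the lexicographically smallest pair of cluster labels, making the
output deterministic; leaf heights are half the merge distance, so trees
are ultrametric by construction (asserted to 1e−9 in tests, and checked to
be an exact fixed point on ultrametric inputs).

# Enrichment

The EASE score is the one-sided hypergeometric upper tail with the
observed overlap reduced by one: `P(X ≥ k−1)`; it is 1 by construction for
k ≤ 1 and dominates the exact Fisher p, making it conservative under a
uniform-sampling null (verified empirically at 1,000 replicates).
Bonferroni correction multiplies by the number of categories actually
tested (those with k ≥ 1). The background defaults to all genes present in
the annotation map — the convention of the interactive annotation tools
this mirrors — and is configurable. Category maps are plain inputs; no
ontology traversal is performed.

# The simulator: what it emulates, and what it does not

`simulation_plan()` defaults describe the desk-scale study conditions used
throughout the package and its tests:

* two chromosomes of 250 kb (a 500 kb genome) — large enough for
  realistic anchor statistics, small enough that the whole suite runs in
  minutes on one CPU;
* five retrotransposon families with identical ~6 kb copies per family
  flanked by identical 300 bp terminal repeats; excision leaves a solo
  LTR;
* 30 perfect tandem arrays (units 3–60 bp, 5–40 copies);
* 200 intronless ATG…stop gene models placed clear of transposons;
* an SNV rate of 0.2% (the density seen between closely related
  laboratory strains) and 200 indels with geometric mean length 3 bp
  capped at 90 bp, a configurable fraction planted inside tandem arrays as
  whole-unit expansions/contractions (left-aligned, like the calls);
* segmental duplications, subtelomeric multi-gene deletions, novel unique
  insertions generated by rejection sampling against the reference k-mer
  set, and optional sequencing dropouts (regions with no query reads,
  emulating extreme-composition bias);
* contig fragmentation at retained transposon copies ("break-and-drop"
  withholds the repeat interior, creating the unassembled-gap and
  contig-break cases), a low random break rate, random contig orientation;
* Poisson per-window read counts with a deterministic GC bias shared
  between the strains, so the bias cancels from depth ratios; planted
  copy-number events scale the local mean.

Every operation is a pure function of (inputs, seed); each stage draws
from its own sub-stream derived from the plan seed, so stages can be
regenerated independently and reruns are byte-identical.

The simulator does **not** model read-level error, diploidy, inversions or
translocations, GC bias that differs between strains, or sequence that
diverges by anything other than the planted edit classes. Passing tests
therefore demonstrate the correctness of the *procedures* under the
declared generative model, not robustness to every artefact of real
sequencing data; the alignment and classification thresholds are the
levers a user would revisit on real input.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally everywhere; conversion to
  1-based happens only when writing VCF/GFF3. BED stays 0-based.
* Gap closure is exact DP, never banded heuristics; a junction whose gap
  product exceeds `gap_cells_max` splits the block instead of being
  approximated.
* Zero-count windows: log2 of a zero ratio is stored as −Inf in memory and
  capped only at serialization (and when averaging segment means, at ±4).
* All-zero reference chromosomes are skipped with a warning in the ratio
  track; zero-depth elements are skipped in the family copy estimate.
* Empty inputs (no MEMs, no blocks above threshold, categories without
  overlap) return empty, correctly-typed tables rather than errors.

# Problem sizes used by the validation suite

The test suite and the acceptance script regenerate their inputs from
scratch: a 500 kb pair with 1,000 SNVs and 200 indels for variant
recovery; a 750 kb genome with 30 transposon loci (ten excised, ten
contig-broken, ten fully assembled) for locus classification; 12 kb
planted gains/losses at ~207 reads per 414 bp window for copy number;
10,000 null windows for test calibration; 100 random pairs ≤ 300 bp
against brute-force oracles for the aligner; 1,000 resampling replicates
for enrichment calibration. These sizes were chosen once as the package's
validation conditions.

# Known limitations

* Gene models are treated as single-CDS; multi-exon annotation is parsed
  but effect annotation of spliced genes reconstructs the mutant CDS from
  the gene span, which is only correct for intronless genes.
* The mosaic fragment identity is per-position, not a literal local
  re-alignment of each fragment; the two agree except at alignment ties in
  highly mutated fragments.
* The coverage distance is one interpretation of a coverage-based genome
  dissimilarity (see above) and should be treated as such when comparing
  against other tools.
* Contig placements use each contig's single best block; split placements
  of chimeric contigs are visible in the block table but not in the
  placement table.
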