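---
title: "Methods: assembly statistics, annotation transfer and motif screens for a long-read protist genome"
author: "mxpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly statistics, annotation transfer and motif screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

mxpipe is the analysis layer of a long-read genome project on
*Monocercomonoides exilis*, the flagellate argued to lack any mitochondrion.
Four analyses sit on top of shared sequence/annotation I/O:

1. **Assembly structure** — N50, GC, telomeric-end classification of
   contigs, a chromosome-number estimate, coding density in fixed windows,
   and gene/intron/UTR metrics.
2. **Annotation transfer** — deciding, per legacy gene model, whether it
   carried over to a new assembly, with fusion/split detection and the
   locus-tag naming convention for the products.
3. **UTR landscape** — selection of full-length 3'UTRs from oligo-dT read
   boundaries, k-mer enrichment in the terminal 100 bp, positional
   profiles of the polyadenylation signal and of U content, and the Kozak
   position-frequency matrix.
4. **Mitochondrial-hallmark screen** — reciprocal best hits, a dual
   targeting-predictor consensus, a tail-anchor filter, a
   beta-signal/MBOMP scan with secondary-structure filters, and an
   aggregated evidence report.

External aligners, gene predictors and localisation predictors are *not*
run; their outputs enter as standard-format tables (12-column homology
hits, probability TSVs, TMD intervals, H/E/C secondary-structure strings).
The package's contribution is everything downstream of those tables, plus
a seeded generator that fabricates all of them with a ground-truth
manifest, so that every stage is testable end to end without any external
data or binary.

## Models and procedures

### Telomeres and the chromosome estimate

An end is called telomeric when at least `min_units` (default 5) tandem
copies of the repeat unit (default `TTAGGG`) or its reverse complement
occur within the terminal `search_window` (500 bp), tolerating at most 2
mismatches summed over the whole run. No published detection rule exists
for this system, so the rule is explicit and configurable; the mismatch
budget makes the detector robust to isolated sequencing errors without
letting degenerate repeats qualify. Scanning the 3' end is implemented as
the mirror of the 5' scan, which guarantees the invariant that
reverse-complementing a contig swaps the two flags.

With $b$ contigs capped at both ends and $s$ capped at one end, the
chromosome point estimate is $b + s/2$: each one-ended contig contributes
one chromosome end, and two ends make a chromosome. The reported range
rounds the point estimate down/up to the nearest multiple of ten — a
deliberately loose bracket of the kind such estimates are quoted in; the
point estimate is the scientific output, the range is prose. For the
published tallies (10, 65) this gives 42.5 with range 40–50.

### N50 and coding density

N50 uses the cumulative-sum-at-least-half convention (ties included), the
dominant definition; a brute-force oracle in the test suite enforces it on
a thousand random length multisets. GC computations exclude ambiguous
bases from numerator and denominator. Coding density tiles each contig
with 5 kb windows (final partial window kept at true length) and reports
the fraction of window bases under the union of CDS intervals; the test
suite checks the conservation identity that window fractions times window
lengths sum to the per-contig CDS base count.

"Gene length" is the genomic span from first to last exon base, introns
and UTRs included — the only reading consistent with quoting a mean gene
length alongside separate intron and UTR rows. Intergenic length is the
gap between consecutive gene spans on a contig, using gene spans (not CDS
spans); the alternative is not distinguishable from published numbers, so
the choice is documented rather than inferred.

### Annotation transfer

The transfer engine mirrors a staged, semi-automatic procedure: candidate
model sets (one per stage, standing for de-novo prediction, coordinate
lift-over, and two spliced-alignment rounds) are tested in order; a legacy
gene resolved at one stage is never revisited. Stages 1–2 use **exact
clustering**: two CDSs co-cluster iff they have equal length and 100%
identity (the `-s 1 -c 1` regime of greedy clustering tools). Stages 3+
use **near clustering**: equal length and global identity ≥ 0.95, with
identity = matches / alignment length under match +1, mismatch 0, gap
open −2, gap extend −1. The equal-length rule is enforced exactly; the
published heuristic clusterer's identity is approximated by a
deterministic global aligner so that an all-pairs oracle can check it.
Nucleotide sequences are the default comparison currency (the published
procedure extracted both nucleotide and protein sequences without stating
which fed the 95% threshold; the engine supports either).

Unresolved tags then pass through **fusion/split detection** on the
mapper-output coordinates: a new model whose CDS absorbs ≥ 50% of the CDS
of two or more old models (same strand) is a fusion; two or more new
models each drawing ≥ 50% of their own CDS from one old model constitute a
split. The 50% threshold is a package choice — no numeric criterion is
published — and is configurable. Events are disjoint by construction;
conflicts are hard errors. Products are renamed
`PREFIX_a` + `fu` + `b` (numbers ascending) and `PREFIX_n` + `p1..pk`
(parts in plus-strand coordinate order, a single unambiguous rule even for
minus-strand genes). Whatever remains is `failed`. The summary enforces
conservation: every old tag appears exactly once across outcomes.

### UTR landscape

A 3'UTR is **full length** iff at least one read's polyA/oligo-dT boundary
lies within `tolerance` (default 0) of the annotated UTR end and that
read's alignment covers the whole UTR. Zero tolerance — the annotated end
coincides exactly with the oligo-dT boundary — is the strictest reading
and the default; it is a config value because the exact rule used to
build the published full-length subset is unstated.

Motif discovery replaces an external suite with an exhaustive hexamer
census: the observed statistic is the number of terminal-window sequences
containing each k-mer at least once (zero-or-one per sequence, matching a
site-probability reading of positional profiles; a multi-count mode is a
flag away). The null is `n_shuffles` rounds of per-sequence
**dinucleotide-preserving shuffling** (random Eulerian path through the
dinucleotide multigraph — exact counts preserved, first and last base
fixed), and $z = (\mathrm{obs} - \mu_{null})/\sigma_{null}$. Where the
null sd is zero, a binomial fallback
$\sqrt{n p (1-p)}$ with $p = (\mu + 0.5)/(n+1)$ avoids infinite scores.
Ranking is by z, ties by observed count then lexicographic. Under the
null, the maximum z across all 4096 hexamers sits near 4.5–5 (an extreme
over thousands of correlated tests), clearly separated from planted-motif
scores (z > 20 at realistic planting rates); the tests assert both sides
of that separation.

Positional profiles anchor sequences at the cleavage site (last base =
position −1) and count each sequence once at its first motif occurrence;
the reported localisation is the shortest contiguous window holding at
least half of all occurrences. U content is averaged per position over the
sequences long enough to cover it. RNA is displayed as U but stored as T
throughout.

The Kozak matrix summarises 10 bp up- and downstream of the start codon
over genes whose 5'UTR is at least 10 bp (shorter contexts are excluded
and counted). Columns are frequency-normalised; the consensus letter is
the base at frequency ≥ 0.4, else the IUPAC code of bases ≥ 0.25, else
"n". The mean upstream A+T frequency is reported because an AT-rich but
motif-free upstream context is exactly the expected signature here.

### Mitochondrial-hallmark screen

All thresholds follow the stated cutoffs and their boundary semantics are
pinned by dedicated tests:

* **RBH**: best = lowest e-value, ties by higher bitscore then subject id;
  both directions must be best and both e-values ≤ 0.001 (inclusive).
* **Targeting consensus**: both predictor probabilities strictly > 0.5;
  missing scores count 0; the flagged percentage is reported to one
  decimal.
* **Tail anchor**: some TMD ends within 32 aa of the C-terminus,
  inclusive, measured from the TMD's last residue (the most permissive
  natural reading; anchoring on the TMD start is a config option).
* **Beta-signal**: 8-mer `[Po, x, G, Hy, x, Hy, x, Hy]`; the polar and
  hydrophobic alphabets default to {D,E,H,K,N,Q,R,S,T} and
  {A,F,I,L,M,V,W,Y} and are config-exposed, because the source class
  tables are cited rather than reprinted anywhere reachable. The scan is
  restricted to motifs whose last residue lies within 15 aa of the
  C-terminus — "in the C-terminus" made explicit and testable — and the
  rightmost hit is primary.
* **MBOMP filters**: over up to 300 aa preceding the signal, strand
  fraction ≥ 25% and helix fraction ≤ 10%; at most 4 of the 8 signal
  residues helical. All bounds inclusive. For proteins shorter than
  signal position + 300, the context truncates and is flagged
  `short_context` — shortness is reported, not silently filtered, since
  downstream manual evaluation is where length arguments belong.
* A **Kyte–Doolittle hydropathy scan** (19-aa window, mean ≥ 1.6) exists
  as a clearly-labelled fallback so the pipeline runs end to end when no
  external TMD table is supplied; it is not equivalent to a dedicated
  predictor and is never used when a table is present.

The aggregate report unions the channels into one row per protein and
never auto-declares a mitochondrial protein: any flag routes to
`manual_review`, mirroring the survey design in which automated channels
only nominate candidates.

## The synthetic-data generator

The generator fabricates the complete input universe with a ground-truth
manifest: telomere-capped contigs (12 tandem units per capped end),
intron-bearing genes on both strands, planted polyadenylation hexamers at
a uniform offset 20–30 bp upstream of the cleavage site with T-rich
(p = 0.6) 10 bp flanks, an "old" assembly derived by fragmenting contigs
and planting fusion/split/frameshift events, oligo-dT read evidence, and
a proteome with planted positives for every screen channel plus
single-violation decoys.

Defaults follow the study system where it states values: background GC
37.2%, intron GC 27.6% and mean length 119 bp, ~1.95 introns per gene,
mean 3'UTR 312 bp and 5'UTR 62 bp, mean intergenic gap 1855 bp, the
canonical AAUAAA hexamer at 20–30 bp, and a proteome of 4665 proteins
with 24 dual-targeting positives, 7 tail anchors, 2 MBOMPs, 326 database
best-hit pairs and 28 HMM candidates of which 6 carry database homologs.
Where no value is stated the choice is made once and documented: 60% of
genes carry a 3'UTR and 40% a 5'UTR (real annotations are partial), 70%
of UTR-bearing genes have a full-length read, CDS length is
3 × (150 + Geometric(mean 580)) codons truncated at 2000, UTR and
intergenic lengths are shifted geometric (a heavy-tailed, strictly
positive family; the real 3'UTR length distribution is only depicted
graphically and the generator does not claim to match it), and the
telomere unit is `TTAGGG` with the unit recorded in the manifest rather
than asserted as biology.

One integer seed drives everything; sub-generators (genome, old assembly,
reads, proteome) use fixed offsets from it, so identical spec and seed
give byte-identical output and each artifact can be regenerated
independently.

What the generator deliberately does **not** emulate: sequencing error
(apart from the planted frameshifts), repeat families and their collapse,
alternative isoforms, codon-usage bias (coding regions are uniform random
codons, so synthetic assemblies run a few points above the background GC),
UTR introns (UTR intron counts are exercised as exact zeros against the
manifest), and correlated predictor errors in the proteome tables. Tests
passing on this generator therefore demonstrate the correctness of the
decision layer — thresholds, bookkeeping, conservation, recovery — not
the field performance of the upstream predictors it consumes.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed everywhere (GFF3 convention); no
  half-open coordinates cross a module boundary.
* Terminal stop codons are inside CDS intervals but trimmed from protein
  strings; internal stops are flagged, never silently dropped. The
  manifest records proteins after terminal-stop trimming, so either CDS
  length convention can be tested against it.
* Fused legacy models concatenate two stop-terminated CDSs; the resulting
  internal stop is the realistic signature of such fusions and is carried,
  not repaired.
* Frameshift-planted genes change CDS length by one base, so under the
  equal-length rule they can never co-cluster at any stage; they resolve
  as `failed`, which is what their manifest entry expects.
* Empty inputs: an empty FASTA reads as zero records; an empty UTR set
  yields an empty terminal-window table (not an error); an absent motif
  yields an all-zero profile with a warning; an empty transfer-record
  table summarises to zeros.
* A window size of zero, probabilities outside [0, 1], negative counts,
  out-of-bounds intervals, orphan GFF3 parents and duplicated tags are
  hard validation errors.

## Problem sizes used by the tests

The recovery suite runs ten seeds of a 500-gene, 10-contig genome with
its derived old assembly, and a 5000-protein proteome; enrichment tests
use 30 shuffle rounds there and 100 rounds in the smaller worked
examples. These sizes were chosen so the full decision layer (clustering,
event detection, enrichment, all screen channels) is exercised at a scale
where every planted count is still required to be recovered *exactly*,
while a complete test run stays in the minutes range on one CPU. The
coding-density worked example calibrates the generator's intergenic gap
analytically (mean CDS ≈ 2132 bp against ≈ 444 bp of introns+UTRs and an
800 bp gap ⇒ 62.6% coverage) and then checks the measured density against
that target.

## Known limitations

* The near-identity clusterer aligns only equal-length pairs; it
  reproduces the equal-length regime of the published procedure but is
  not a general clusterer.
* Fusion/split detection needs the old models on the new coordinate
  system; mapping quality is assumed, not assessed (the mapper is outside
  the package).
* The hydropathy TMD fallback is a convenience, not a predictor
  replacement; conclusions about tail anchors should rest on external TMD
  tables.
* The chromosome range bracket (multiples of ten) is presentation; use
  the point estimate for any computation.
* Headline numbers of the real assembly (82.3 Mb, 101 contigs,
  N50 1,379,369, 18,152 gene models) require the deposited data and
  external predictors; they are context for the statistics code, not
  desk-reproducible targets, and the package does not pretend otherwise.
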