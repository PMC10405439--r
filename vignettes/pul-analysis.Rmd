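---
title: "Calling and comparing polysaccharide utilization loci with PULscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing polysaccharide utilization loci with PULscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PULscope)
```

## The analysis

*Bacteroidetes* organize polysaccharide catabolism into polysaccharide
utilization loci (PULs): a tandem pair of *susC*-like (TonB-dependent
transporter) and *susD*-like (surface glycan-binding lipoprotein) genes
next to the glycoside hydrolases (GH) and polysaccharide lyases (PL)
that depolymerize one target glycan. PULscope takes per-genome
annotation bundles — gene coordinates (GFF3), contig and protein FASTA,
and a feature table of Pfam domains and dbCAN-style CAZyme families —
and derives from them: PUL calls, substrate assignments, CAZyme
abundance and diversity statistics, and horizontal-acquisition
screens. It deliberately consumes annotation *outputs*; running
Prodigal/Prokka, hmmscan or dbCAN is out of its scope, as is
read-level work (QC, assembly, binning) and phylogenetic inference.

## PUL calling

`classifySusGenes()` labels a gene *susC*-like when its domain set
intersects {PF00593, PF13715, PF07715} and *susD*-like on
{PF07980, PF12741, PF12771, PF14322}. A gene matching both sets is
annotation-ambiguous; we exclude it from pairing rather than guess a
role. `findTandemPairs()` then requires strict adjacency (gene-ordinal
difference 1), a shared strand, and *susC* transcriptionally upstream
of *susD* — the canonical Sus architecture. Because curated PUL
catalogs occasionally accept the inverted order, `relaxOrder = TRUE`
drops the orientation requirement; the default stays strict. Pairing is
greedy left-to-right and a gene joins at most one pair, which keeps
runs of alternating susC/susD genes deterministic.

`callPULs()` slides a `window` of 7 consecutive genes (step 1, over
gene ordinals, not base pairs — a "seven-gene window" is a gene-count
notion) along each contig:

* an **anchor** window fires when it fully contains a tandem pair and
  at least `minDegradative = 2` *genes* carrying a GH or PL family
  (a gene with several GH/PL domains counts once: the criterion is
  "two degradative genes", not "two domains");
* an **extension** window fires on the degradative criterion alone.

Overlapping fired windows merge; merged runs that never contained an
anchor are discarded; each surviving run is trimmed to the minimal
consecutive gene run covering its pairs and GH/PL genes. The two-tier
design is deliberate: if every window had to contain the pair, no call
could ever exceed the window length, yet real PULs routinely string a
dozen catalytic and accessory genes behind one susCD pair. Anchoring
preserves the strict pair-plus-two-enzymes co-occurrence while the
extension windows let the call grow across the full catalytic
complement. Accessory genes (sulfatases, peptidases, transporters)
interior to the trimmed run are retained as members, matching how
curated PULs are drawn. Degenerate contigs with fewer genes than the
window are scanned as one whole-contig window so that fragmented MAGs
remain callable; predicting *incomplete* PULs truncated by contig edges
is intentionally not attempted.

The whole rule is simple enough to enumerate exhaustively, and the test
suite holds `callPULs()` equal to an independently written brute-force
enumeration over randomized genomes of up to 200 genes — the rule *is*
the specification, so the oracle check is the strongest statement we
can make about it.

## Substrate assignment

`classifyPUL()` scores a PUL's (gene, GH/PL family) records against an
editable rule table (`substrateRules()`): every record votes for each
substrate whose diagnostic set contains its family, the winner needs
`min_hits` votes, ties between distinct winners return `"mixed"`, and
no qualifying votes returns `"unclassified"`. Families in no rule
contribute nothing: conservative by construction. dbCAN subfamily
labels (GH43_4) are kept verbatim but matched at family level unless a
rule names the subfamily, since substrate reasoning in the field is
family-level while annotators emit subfamilies.

The built-in table covers 14 substrate types. Most entries follow the
standard one-family diagnostics (GH13 for α-1,4-glucan, GH16 for
β-1,3-glucan/laminarin, GH92 α-mannan, GH29 fucose-containing glycans,
GH33 sialic acid oligosaccharides, GH144 β-1,2-glucan, GH10/GH115
xylan, GH43/GH51/GH127 arabinan, PL6/PL7/PL17 alginate). GH2 and GH5
are functionally broad families, so β-galactan and
β-1,4-glucan/cellulose carry `min_hits = 2` to avoid calls on a single
ambiguous gene. For three types no single convention dominates, and the
defaults are our choices, deliberately config-overridable: xyloglucan
{GH74, GH31}, β-mannan {GH26, GH130}, pectic main chain
{GH28, PL1, PL11}. Expert curation against experimentally validated
PUL databases can and should override the table via the JSON schema
`{"substrate": {"families": [...], "min_hits": n}}`.

## Abundance, diversity, statistics

`calcCPM()` uses each sample's *total mapped reads* as denominator —
not the in-table column sum, which undercounts whenever the gene
catalog misses reads — and `calcRPKM()` additionally divides by gene
length in kb. `shannonIndex()` (natural log, zeros omitted) and
`brayCurtis()` delegate to vegan behind input checks. Ordination (NMDS)
of the Bray–Curtis matrix is left to vegan directly:
`brayCurtisMatrix()` hands over exactly the `dist` it needs.

`rankSumTest()` is a two-sided Mann–Whitney/Wilcoxon rank-sum
comparison with mid-ranks for ties. For pooled sizes up to 12 it
enumerates all group splits exactly; beyond that it uses a seeded
permutation null with add-one smoothing, `p = (1 + k)/(1 + n)`. The
p-value is the proportion of splits whose statistic falls at least as
far from its null mean as observed; on tie-free data this reproduces
`wilcox.test(exact = TRUE)` (verified in the tests), and under ties it
remains exact where R's implementation falls back to a normal
approximation — which is why the test is implemented in-package. The
comparison is unpaired; per-family multiple-testing correction is
deliberately not applied, leaving that judgement to the analyst.

## Horizontal-acquisition screens

`gcProfile()` computes GC over non-overlapping windows (default
2000 bp; trailing partial window dropped; ambiguous bases excluded from
numerator *and* denominator, with per-window informative-base counts
kept so the base-weighted window mean reconstructs the prefix GC
exactly). `regionGCDelta()` contrasts an exact span against the
genome-wide GC in percentage points.

`alignIdentity()` is a global (Needleman–Wunsch) alignment — BLOSUM62,
gap open 10 / extend 0.5 for protein; +2/−2 with the same gap costs for
nucleotide — with percent identity counted over aligned columns after
excluding terminal gap overhangs. Database searches report *local*
identities; for positionally matched full-length orthologs, global
identity is a stable, oracle-checkable proxy, and overhang exclusion
keeps a clean extension from diluting identity.

`pulVsBackgroundIdentity()` contrasts the mean identity of positionally
matched PUL gene pairs against the mean over reciprocal-best-hit (RBH)
pairs among all genes outside both PULs. "All other gene pairs" is
ambiguous as a population; RBH is the standard orthology proxy and is
the default, with `background = "best"` switching to best
unidirectional hits for sensitivity analysis.

`detectPULDeletion()` asks whether a related genome descends from a
PUL-bearing ancestor: it anchors the `flankGenes = 3` genes on each
side of the reference PUL to their best protein matches in the query
(candidates prefiltered to within 30% of the reference protein length,
anchors accepted at ≥ 50% identity), requires the two anchored blocks
to sit on one query contig in consistent orientation, computes each
flank's *nucleotide* identity by globally aligning the corresponding
spans, and reports a deletion event only when both flanks reach
`minFlankIdentity = 97` while the intervening query span lacks at
least 80% of the PUL's interior genes (a gene counts as present at
≥ 40% protein identity). Anchoring via proteins rather than aligning
each flank block against whole contigs keeps the search near-linear in
genome size without changing what is reported: the flank identities are
still nucleotide-alignment identities of the located blocks. Unalignable
flanks yield an empty result, not an error — absence of evidence.
`integraseNearby()` separately reports integrase/recombinase genes
within 40 gene ordinals of a call, as an informational annotation only:
phage integrases recur near laterally acquired PULs but are not by
themselves evidence.

## The synthetic-data generator

`makeGenome()` emulates the *annotation structure* the pipeline
consumes: one contig of spaced gene models (mean length 900 bp,
sd 20%, 150 bp intergenic), planted PULs (adjacent
susC(PF00593)+susD(PF07980) followed by 2+ diagnostic genes of a named
substrate, optionally with an interior accessory gene), background
annotation noise (5% of background genes get a random *non-degradative*
GT/CE/CBM/AA family), and a truth table. Planted loci are separated by
at least 10 background genes from each other and 5 from contig ends.
All randomness derives from the seed; the same seed reproduces the
bundle byte for byte, and the caller's RNG state is restored.
`makeRandomGenome()` is the adversarial sibling: it sprinkles sus
domains and GH/PL families independently at given rates to produce the
tangled window configurations the brute-force oracle test needs.

`makeHGTPair()` plants the contrast typical of a recent horizontal
acquisition, with defaults set to the study conditions the package is
exercised under: shared-PUL protein identity 79%, ortholog background
61.8%, and a +3.1-point GC anomaly on a 31.2%-GC recipient
(donor at 36.2%). Three numerical choices make those signals exactly
recoverable rather than merely approximately planted. First, random
DNA is composition-exact (exactly `round(n * gc)` G/C bases, randomly
arranged), so planted GC contrasts carry no binomial sampling noise.
Second, because the planted span also contributes to the genome-wide
mean it is compared against, its GC is inflated by `1/(1 − f)`
(`f` = span fraction of the genome) so the *measured* region-vs-genome
delta equals the requested shift regardless of genome size. Third,
mutation models substitute an exact count `round(L × rate)` of
positions (each to a uniformly different residue/base), stratified in
500-bp chunks for nucleotide mutation in `makeDeletionPartner()`, so
realized local identities sit at the target instead of a binomial
draw around it. `makeDeletionPartner()` excises the PUL interior
between its first and last genes, shifts coordinates, and mutates the
remaining sequence to the requested flank identity;
`excise = FALSE` yields the matched negative control with the locus
intact. `makeCountTable()` draws negative-binomial counts
(dispersion 0.2, a typical metagenome overdispersion) around
family-specific means scaled by per-group multipliers.

Two deliberate unrealisms matter for interpreting test results. The
nucleotide and protein tracks are statistically independent — proteins
are not translations of their CDS spans — because no operation in the
pipeline ties them and independence lets protein identity and GC be
planted separately. And divergence is substitution-only: no indels, no
rearrangements, no phylogenetic rate structure. Passing tests therefore
demonstrate that the *rules and estimators* are implemented exactly as
specified and recover planted signals under clean conditions; they do
not demonstrate robustness to fragmented assemblies, indel-rich
divergence, or annotation error, which real MAG data will contain.

## Problem sizes and reproducibility

The shipped checks run on: 50 genomes with 5–10 planted PULs each for
precision/recall; 100 randomized genomes of 20–200 genes for the
window-rule oracle; one donor/recipient pair at the default study
conditions for identity and GC recovery; and 100 deletion pairs plus
100 intact controls (24-gene genomes) for the deletion screen.
`scripts/acceptance.R` re-derives the same quantities from any seed at
slightly reduced counts and writes them as JSON; all thresholds,
window sizes and generator parameters used there are the package
defaults described above.

## Known limitations

* PUL confidence is single-valued (`"complete"`): fragmented or
  edge-truncated loci are not modelled.
* Substrate voting is a reproducible proxy for expert curation, not a
  replacement; `"mixed"` and `"unclassified"` calls need human eyes.
* The RBH background requires enough shared orthologs; between very
  distant genomes the background mean is an average over few pairs.
* Deletion detection assumes the flanks stayed colinear; flank
  rearrangement defeats the consistent-orientation requirement and the
  event is (conservatively) not reported.
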