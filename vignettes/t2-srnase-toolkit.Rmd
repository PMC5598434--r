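---
title: "Characterizing plant T2/S-RNases and scanning for S-loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing plant T2/S-RNases and scanning for S-loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaseScout)
```

## The problem

The T2/S-RNase family of endoribonucleases is ubiquitous in plants and
poorly characterized functionally. Within the core eudicots, one clade —
class III — houses the S-RNases, the pistil-side recognition determinants
of RNase-based gametophytic self-incompatibility (GSI). The S-locus couples
one S-RNase with multiple tightly linked F-box genes (SLF/SFB) in a region
of suppressed recombination; when self-incompatibility is lost, the locus
decays slowly, leaving recognizable relicts (pseudogenized F-boxes, intact
class III RNases) in the genomes of self-compatible species.

Three structural correlates separate the classes and flag S-RNase
candidates without any tree inference:

* **Intron architecture.** Eleven positionally homologous intron sites are
  observed across land-plant members of the family. Class I genes carry
  subsets of positions \{2, 5, 9\}; class II genes invariantly carry eight
  introns (\{3,4,5,6,7,8,10,11\}); class III genes carry position 5
  (S-RNases), 5+1 (Prunus), 5+9, or 9 alone. Intron phase is constant
  within a homologous position.
* **Isoelectric point.** Class I and II proteins are typically acidic
  (medians near 5.0 and 5.9); class III proteins are basic, and functional
  S-RNases rarely show pI < 8.0.
* **Conserved regions.** Five conserved sequence regions, two of which
  (CAS I and CAS II) carry catalytic histidines; the CAS II histidine is
  essential for ribonuclease activity, so its absence marks a protein as
  catalytically dead.

`rnaseScout` implements these measurements, an explicit classification
rule built on them, and a genome scanner that reports putative (possibly
relict) S-loci: class III RNase loci with several intact or stop-disrupted
F-box ORFs within a 2 Mb flank.

## Isoelectric points

`isoelectricPoint()` implements the Bjellqvist method: the
Henderson–Hasselbalch net charge

$$Q(\mathrm{pH}) = \sum_{i \in \mathrm{pos}} \frac{m_i}{1 + 10^{\mathrm{pH} - pK_i}}
 - \sum_{j \in \mathrm{neg}} \frac{m_j}{1 + 10^{pK_j - \mathrm{pH}}}$$

with positive groups the N-terminus, H, K, R and negative groups the
C-terminus, D, E, C, Y. $Q$ is strictly decreasing in pH, so the root is
unique; it is bracketed on [0, 14] by bisection to a default tolerance of
0.01 pH and reported to two decimals, the precision customary for protein
pI. The default pK table is the Bjellqvist set popularized by the ExPASy
lineage of tools, including residue-specific overrides for the terminal
groups; other pK dialects exist, so the table is data
(`defaultPkTable()`, overridable from a two-column TSV via
`readPkTable()`). `X` residues carry no charge. Signal peptides are
excluded when a boundary is supplied (`ProteinRecord`,
`matureSequence()`); the package does not predict boundaries, and
dataset-level pI summaries depend on that upstream choice.

```{r pi}
isoelectricPoint("GG")        # analytic root 5.525
rec <- makeProtein("III", 9.0, seed = 1)
isoelectricPoint(rec@seq)
```

## Conserved regions and catalytic histidines

The five conserved regions are represented as a panel of equal-width
exemplar windows (`defaultMotifPanel()`); each candidate window in a query
is scored by a BLOSUM62 sum normalized by the exemplar self-score, and the
reported hits are the best *collinear* subset (the regions are
positionally ordered in all described family members; collinearity is
selected dynamically, maximizing region count then total score). The
bundled panel is a synthetic construction anchored on the canonical RNase
T2 active-site architecture (an `HGLWP`-like CAS I core, a second
catalytic histidine in CAS II); the family's true motif composition is not
printed in the literature in a directly reusable form, so the panel is
deliberately data, not code, and can be swapped via `readMotifPanel()`.
The per-region threshold of 0.45 was chosen together with the 12-residue
window width so that random sequences essentially never reach it (about
1% of random 100-mers produce any hit) while exemplar-derived sequences
score 1.0.

Two filters from the family's curation practice are exposed directly:
`passesInclusionFilter()` keeps sequences with coding length > 350 bp and
at least 3 of 5 regions hit, and `catalyticHistidines()` returns tristate
evidence (present / absent / undetermined) for the CAS I and CAS II
histidines, inferring non-functionality only when the CAS II region was
found without its histidine.

## Intron architecture

Intron insertion points are represented as counts of coding nucleotides 5′
of the intron, which is strand- and coordinate-free; phase is the offset
modulo 3 (phase 0 before a codon, phase 1/2 inside it). Mapped onto a
codon-aware alignment (`intronSites()` + `columnMap()`), introns are
clustered into homologous positions by single linkage under a
seven-nucleotide window (`clusterIntronPositions()`): two sites link when
their anchor columns fit inside a 7-column window, i.e. |Δcolumn| ≤ 6.
The alternative reading (|Δ| ≤ 7) is available via the `window` argument.
Window distance counts all alignment columns, including gap columns. The
intron's anchor is the column of the first coding nucleotide 3′ of it;
ties at cluster boundaries resolve by ascending column then gene id.
Phase disagreement inside a cluster is recorded as a conflict, never
silently merged.

Clusters are labeled against a bundled reference frame of the 11 canonical
positions (`canonicalIntronTable()`); novel clusters get labels above 11.
The published record fixes the phases of positions 5, 8 and 10 (phase 0)
and implies phase 2 near position 3; the remaining phases in the reference
table are package-chosen constants of the synthetic frame — nothing
downstream depends on their particular values, only on within-position
constancy. `presenceMatrix()` emits the presence (1) / absence (0) /
undetermined (U) matrix — `U` marks positions whose column range the
sequence does not span (cDNA records, truncations) — and
`assignPattern()` names presence sets against the canonical catalog
(`patternCatalog()`): I-A \{2\}, I-B \{5\}, I-C \{2,5\}, I-D \{2,5,9\},
II \{3,4,5,6,7,8,10,11\}, III-A \{5,9\}, III-B\* \{9\}, III-C \{5\},
III-D \{1,5\}. III-B\* is retained but flagged provisional (predicted from
genomic sequence only, without transcript support). \{5\} deliberately
returns both I-B and III-C: that pattern is uninformative without class
context.

```{r introns}
assignPattern(c(2, 5, 9))
assignPattern(5)
```

## Classification

`classifySequence()` makes the class call by an explicit ladder:

1. an intron pattern matching catalog entries of exactly one class fixes
   the class (`pattern-exact`);
2. otherwise the lines of evidence vote — the pattern's compatible
   classes, the pI side (acidic < 7.0 supports classes I and II; basic
   supports III), and the class of the nearest labeled exemplar
   (`nearestReference()`: alignment distance
   $d(a,b) = 1 - S(a,b)/\min(S(a,a), S(b,b))$, majority of k = 3
   neighbours, ties by mean distance). Two or more agreeing lines give
   `multi-line` confidence, one `single-line`; unresolved ties fall back
   to the nearest-reference class alone or to `unclassified`.

The S-RNase candidate flag demands class III, pI ≥ 8.0, an intron pattern
in \{III-C, III-D, undetermined\}, CAS II histidine not absent, and at
least 3 regions hit. III-A (\{5,9\}) is excluded because known S-RNases
lack position 9; undetermined patterns (protein or cDNA input) remain
eligible, with the weaker evidence reflected in the confidence field. Both
pI thresholds are arguments. The published service places queries on a
reference phylogeny by likelihood; its class-assignment rule after
placement is not specified, and tree placement is out of scope here by
design, so the nearest-exemplar distance rule is this package's documented
stand-in. Class III calls are not restricted by taxonomy.

## S-locus scanning

`findOrfs()` scans both strands in all three frames for `ATG..stop` ORFs
(stop included in the length; bounds 900–1800 nt inclusive, the canonical
S-locus F-box gene size window). One ORF is reported per (strand, frame,
stop), anchored at the 5′-most ATG after the previous in-frame stop —
i.e. the longest ORF per stop; reporting every internal ATG would drown a
planted gene in its own nested sub-ORFs. Codons containing `N` translate
to `X` and never count as stops; runs of ≥ 10 `N` are treated as assembly
gaps that break ORFs, and the ambiguous fraction of each flank is reported
because poorly resolved assemblies can hide F-box loci. ORF proteins are
called F-boxes when `scoreFbox()` — the maximum reference-normalized
global alignment score against an exemplar panel — reaches τ = 0.25. The
original keyword-matching step against database descriptions is replaced
by this implemented score; the bundled exemplars are synthetic stand-ins
(`fbox_refs_synthetic.fasta`) and curated SLF/SFB panels should be
substituted for real scans.

Relict loci are found by `findDisruptedFbox()`, which translates all six
frames straight through stop codons and locates exemplar-like regions by
exact amino-acid 6-mer seeding: chained seeds define a candidate span,
which is reported as a disrupted F-box when it scores ≥ τ by the same
normalized alignment and contains a stop *strictly inside* the
seed-covered span. The strict-interior rule is what keeps an intact gene's
own terminal stop from being mistaken for a disruption. Seed-and-extend
was chosen over a dense sliding window because it evaluates the same
decision on the same regions at a small fraction of the alignment work;
random 2-Mb contigs produce a handful of isolated seed hits and no
reportable spans.

`scanHaplotype()` assembles the report: every F-box locus (intact or
disrupted) within 2 Mb of each supplied RNase locus, distances in kb, and
the candidacy verdict — at least one *class III* RNase locus with at least
`minFbox = 4` F-box loci in its flank ("more than a few", made concrete;
the parameter is exposed and recorded in the report). Class I/II RNases
with many flanking F-boxes are reported with a note but never promote
candidacy, mirroring the fact that F-box clusters also surround non-S
RNase loci.

```{r scan, eval = FALSE}
hap <- makeHaplotype(seed = 7, contigLength = 2e6, rnaseClasses = "III",
                     nFboxIntact = 6, nFboxDisrupted = 2)
rn <- subset(hap$truth, type == "rnase")
scanHaplotype(hap$contig, data.frame(start = rn$start, end = rn$end,
                                     classLabel = rn$classLabel))
```

## The synthetic-fixture generator

Every test input is generated, none downloaded. `makeProtein()` builds a
220-residue backbone — one exemplar window per conserved region joined by
random linkers — and greedily swaps K/R ↔ D/E at linker positions until
the pI is within 0.3 of its target. Because charge is tuned in whole
residue steps, pI values in the sparsely ionizable band around neutrality
(roughly 6.8–8.1) are not finely reachable; the class-panel generator
(`makeClassPanel()`) therefore draws class I/II targets from truncated
normals capped at 6.1 (means 5.0 and 5.9, the published class medians) and
class III targets from a truncated normal on [8.4, 9.9] (mean 8.8),
preserving the acidic/acidic/basic class structure. Class membership is
given sequence reality by per-class backbones: all members of a class are
mutated copies (15% of linker positions) of one shared backbone, emulating
within-clade similarity against between-clade divergence — the property
that makes nearest-exemplar classification informative. The bundled class
reference panel was drawn from the same backbones.

`makeGene()` back-translates a protein with a fixed one-codon-per-residue
table (determinism), appends a stop, and inserts `GT..AG` introns at the
canonical coding offsets of the requested pattern, so phases are correct
by construction and all generated CDSs align gaplessly in the reference
frame. `makeHaplotype()` plants RNase genes, intact F-box ORFs (lengths
uniform over 900–1800 nt), stop-disrupted F-box copies (one internal codon
→ `TGA`, placed centrally so neither half reaches the 900 nt ORF floor),
and optional out-of-bounds decoys on an i.i.d. uniform background; each
feature is wrapped in a 12-nt all-frame stop pad so planted coordinates
are exactly what an ORF scan must recover. F-box reference proteins avoid
methionine so back-translated copies contain no internal in-frame ATG,
keeping planted truth unambiguous.

What the generator does *not* emulate: codon usage, substitution processes
along a tree, indels, alignment uncertainty, UTRs and non-canonical splice
sites, and real S-locus repeat structure. Green tests therefore establish
the correctness of the package's algorithms against planted truth and
independent oracles, not the field performance of the panels on natural
sequences — for real scans the motif, class and F-box panels should be
rebuilt from curated data.

## Numerical and design choices

* Internal coordinates are 0-based half-open; all GFF3 I/O is 1-based
  inclusive. Intron placement uses coding-nucleotide counts, never contig
  positions.
* Proteins admit the 20 canonical residues plus `X`; other ambiguity
  letters are rejected at ingest (sequences with ambiguous residues were
  excluded from the family curation this mirrors).
* Bisection bounds [0, 14], tolerance 0.01, two-decimal reporting.
* ORF length bounds are inclusive and include the stop codon; ORFs must
  start with ATG. Both conventions are explicit in the function contracts.
* Alignment scoring uses BLOSUM62 with affine gaps (open 10, extend 0.5)
  throughout classification and F-box scoring; a gap of length L costs
  open + L·extend.
* Validation problem sizes: 100 proteins against a 10⁻⁴ grid-scan pI
  oracle, 200 random pairs against exhaustive alignment enumeration,
  30 genes for exact pattern recovery, 20 planted haplotypes (2–5 Mb) for
  scanner precision/recall and candidacy, 50 random 10-kb contigs against
  the ATG-walk ORF oracle, and a 300-sequence panel for classifier
  accuracy.

## Known limitations

* The motif panel, class exemplars and F-box exemplars are synthetic; all
  classification quality statements are with respect to the generator's
  statistical structure.
* Nearest-reference classification is a deterministic stand-in for
  phylogenetic placement and will misbehave for queries outside the
  reference panel's diversity.
* The pI engine assumes independent ionizable groups (no electrostatic
  coupling), as does every Bjellqvist-style calculator.
* `findDisruptedFbox()` requires exact 6-mer seed matches; pseudogenes
  diverged far beyond ~20% amino-acid identity to every exemplar will be
  missed.
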