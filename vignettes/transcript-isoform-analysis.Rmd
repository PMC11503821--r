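---
title: "Methods: transcript-isoform reconstruction and variant analysis for multi-exon casein genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-isoform reconstruction and variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseinsplice)
```

## The problem

Donkey milk carries two paralogous alpha-s2-casein genes, *CSN1S2* I
(19 exons, a 221-aa mature protein) and *CSN1S2* II (16 exons, 142 aa).
Both loci are spliced promiscuously: Sanger sequencing of cloned RT-PCR
products reveals, besides the correctly assembled mRNA, transcript classes
lacking whole exons, lacking the 5' or 3' end of an exon (cryptic splice
sites), or carrying normally intronic segments recognized as exons
("exonification" of exons 12' and 7'). A G>A substitution at the intron
acceptor immediately upstream of *CSN1S2* I exon 17 switches splicing
allele-specifically onto an in-frame cryptic acceptor 15 nt into the exon,
and, because the substitution destroys an XbaI site (T^CTAGA), it can be
genotyped by PCR-RFLP.

caseinsplice implements that entire desk workflow as reusable, tested
components: exon-level gene models, a declarative splice-event engine, a
frame-aware conceptual translator, a dynamic-programming isoform caller for
clone libraries, SNV aggregation and annotation, splice-site variant
interpretation, in-silico restriction digestion and assay design, and
Hardy-Weinberg statistics. A synthetic-data module generates gene models,
clone libraries and genotype panels with the structural and statistical
properties the analysis assumes, so every stage is testable offline.

## Gene models and coordinates

A gene model (`gene_model()`) is one plus-strand contig plus an ordered exon
table. Coordinates are 0-based half-open internally; every human-facing
report is 1-based. Reverse-strand genes must be reverse-complemented
upstream — the analysis lives entirely in mRNA orientation. Exon labels are
plain strings ordered by genomic start, so primed labels ("12'", "7'") need
no numeric parsing. Cryptic sites are *annotations* on exons
(`acceptor_offsets`, `donor_trims`): discovery is supported
(`find_cryptic_acceptors()`), but the caller only branches on annotated
sites, mirroring how the real events were established by inspection of clone
sequences. N bases are tolerated in the contig but not inside coding exons
of the reference isoform, so translation is always well defined.

The optionally included exons 12' (CSN1S2 I) and 7' (CSN1S2 II) are marked
`extra` and excluded from the reference isoform. Exon 15 of CSN1S2 II, by
contrast, is modeled as a *regular* non-coding exon of the 16-exon reference
that splice events may remove: the reference cDNA contains it, and the
catalogued classes treat its absence as a skip, not its presence as an
insertion.

## Splice events and pattern keys

Four event kinds cover the observed vocabulary: `skip_exon`,
`skip_5prime_partial` (cryptic acceptor), `skip_3prime_partial` (cryptic
donor), `include_extra_exon`. An isoform is an event set with at most one
event per exon; `apply_events()` materializes its mRNA. Pattern keys
serialize the canonically ordered event set (genomic start order) into
strings like `skip:4,skip:5,skip:6,skip5:17:15`, with `FL` for the
reference; the key is injective over event sets and doubles as the parse
format (`parse_events()`).

`find_cryptic_acceptors()` is deliberately minimal: AG-dinucleotide
positions, optionally restricted to frame-preserving offsets (multiples of 3
for exons opening on a codon boundary, as both printed cases do). No
splice-strength scoring is attempted, and the function returns *all*
candidates: the printed 33-nt exon-13 segment contains an earlier in-frame
AG at offset 18 that is not the observed site, so choosing "first match"
would be wrong. Selection among candidates is evidence-driven (clone data or
annotation).

## Conceptual translation

`translate_isoform()` translates from the model's annotated initiator ATG to
the first in-frame stop and cleaves the annotated signal peptide (15
residues at both loci; cleavage is annotation, not prediction). Diagnostics:

* **frameshifted** — some event changed the coding sequence by a
  non-multiple of 3 (removals are intersected with the reference CDS span,
  so trimming UTR never counts).
* **ptc** — the stop codon lies genomically upstream of the reference stop.
  A stop *relocated downstream* by a frameshift (the 35-nt exon-17 trim
  moves the TAA 14 nt deeper into exon 18) is not premature.
* **nmd_candidate** — the classic 50-nt rule (`flag_nmd()`): a stop more
  than 50 nt upstream of the last exon-exon junction, strict inequality at
  the boundary. Candidacy additionally requires `ptc`: the normal
  termination codon is not a decay substrate even when non-terminal exons
  follow it, which matters here because the non-coding exon 15 of CSN1S2 II
  places the last junction ~140 nt downstream of the normal stop.
* **novel_cterm** — residues downstream of the last codon whose genomic
  triplet belongs to the reference codon stream. In-frame deletions and
  insertions have reference-identical C-termini (empty); frameshifts and
  extra-exon read-through (EGIEIIIFM before the exon-12' TAA) report their
  novel tails.
* Transcripts with no in-frame stop are reported as `status = "run_off"`
  with an empty mature chain rather than raised as errors, so a library scan
  never aborts midway.

Theoretical masses (`average_mass()`) use average (isotope-weighted) residue
masses, unmodified side chains, reduced cysteines, one water per chain —
the standard convention of casein "theoretical Mw" tables, which never state
it explicitly. Equality with printed masses is therefore only asserted to
±0.5 Da where it is asserted at all; the implementation is cross-checked in
the tests against an independent oracle (`seqinr::pmw`).

## Isoform calling

`call_clone()` is an exact dynamic program over (exon index, clone
position). At each exon it branches on full match, annotated 5'/3'
truncation, whole-exon skip, or inclusion of a following extra exon, scoring
base mismatches per exon (default cap 2 per exon, matching the observed SNV
density). Indels are never scored inside exons: length differences are
explained exclusively by splice events, which is the right bias for
Sanger-sequenced clones at desk scale. The objective minimizes `(n_events,
n_mismatches, lexicographic pattern key)` — parsimonious splice explanations
beat mismatch-heavy ones, and output is deterministic. Clones tying on two
distinct optimal patterns are reported `ambiguous` (the lexicographically
smallest pattern is shown) and excluded from library pattern counts;
partial amplicons are `unalignable` by design rather than partially matched.
The tests hold the DP to brute-force enumeration over all event subsets on
small models.

`summarize_library()` tabulates distinct patterns with counts and
frequencies over cleanly called clones. Per-pattern clone counts of the real
libraries were never published, so frequencies are validated only by
simulator round trips.

## Variants

`aggregate_snvs()` pools per-clone mismatch lists: substitutions at one site
supported by at least `min_clone_support` clones (default 2) become SNVs;
singletons are retained as putative artifacts, acknowledging the elevated
false-positive rate of RT-PCR-clone sequencing. No frequency estimation is
done from clone counts — clones from one animal are pseudoreplicates.

`annotate_snv()` reports cDNA positions counted from the initiator ATG and
protein changes in `p.<ref><pos>><alt>` style. Residue numbering defaults to
the mature-protein convention (position 1 follows signal cleavage), which is
how this literature numbers its peptides; `numbering = "precursor"` is
available because published variant labels for these loci are not uniformly
on one convention, and the two conventions differ by exactly the 15-residue
signal peptide.

`classify_splice_variant()` formalizes the acceptor-variant analysis: a
variant destroying the canonical AG predicts, for each in-frame cryptic
acceptor in the downstream exon, a partial 5' skip (the model-annotated site
is marked); with no candidate AG it predicts whole-exon skipping. The
variant is located structurally (acceptor offset −1 of the intron preceding
exon 17) rather than by absolute cDNA coordinate, which the available
information does not fix unambiguously.

## PCR-RFLP

`digest()` scans one strand for IUPAC matches of the site as written plus
its reverse complement (palindromes match once per locus) and cuts after
`cut_offset` bases; all overlapping occurrences are cut. `design_assay()`
returns every enzyme whose fragment pattern separates two allelic amplicons,
with heterozygote band sets as the union of the homozygote patterns, and
excludes degenerate sites that cut both alleles. `genotype_from_fragments()`
calls genotypes with a per-band tolerance (default 5 bp — 3% agarose
resolution). The packaged enzyme table is a small curated subset of common
commercial enzymes; a full REBASE-derived table can be supplied as TSV.

The genotyping amplicon around the exon-17 acceptor is an explicit input
(`acceptor_amplicon()`, default 191 bp upstream of the exon start, 558 bp
total): the primer coordinates that defined the real amplicon are not
public, and the published genomic region is slightly shorter than the
amplicon, so bounds cannot be derived. The defaults are chosen so that the
engineered acceptor context TCTAG|A yields the documented 187 + 371 bp
G-allele split.

## Population genetics

`allele_frequencies()` is simple allele counting; `hwe_test()` is the plain
Pearson chi-square on the three genotype classes against `n(p², 2pq, q²)`
with 1 df — the conventional HWE test, with Yates' correction behind a flag
(off by default; no correction was specified for the original analysis) and
no exact test (the original used chi-square). Monomorphic panels are flagged
invalid rather than tested. Strata (breeds) are reported separately and
pooled. The published panel's genotype count table is unavailable, so the
statistic is validated by oracle equivalence on hand-computed counts, by
type-I-error calibration (~5% at alpha = 0.05 over 1000 simulated
119-animal panels), and by 3-standard-error frequency recovery at
n = 10,000.

## The synthetic-data module

`donkey_csn1s2_model()` builds the two pseudo-gene models from the published
structural facts — exon counts and the printed exon sizes (24-bp exons 4/8/15
and 7/9/11; 129-bp exons 12 and 17; >100-bp exon 19; >200-bp exon 16; 105-nt
exons 12' and 15; 45-nt exon 7'), signal peptides, printed exon peptides
(EIKHVSSSE, KTSKKTVDM, EIELSDEEKNYLKQL, KIELTKEEKLYLKQL, EGIEIIIFM), the
printed cryptic-acceptor openings of exons 17 and 13, stop-codon positions,
and the exon-8/10 and exon-12/17-opening duplications. Every whole exon
subject to catalogued skipping is placed codon-aligned with a length
divisible by 3, since each printed whole-exon skip removes an integral
peptide; only the annotated 35-nt exon-17 trim breaks frame. The exon-18
filler is engineered so the shifted frame reads exactly 8 codons before a
TAA at nt 24-26 — the only reading of the relocated-stop description
consistent with the 214-aa isoform — while the residue identities of that
novel tail are free (they are a property of the real sequence, not of the
printed constraints, so the synthetic model does not force them). Filler
elsewhere is random but fully seed-determined, drawn from sense codons
inside the CDS; models are re-drawn (deterministically) until all invariants
hold and, for CSN1S2 I, the XbaI site is unique on the contig.

`simulate_clone_library()` draws clones from isoform classes (uniform
weights by default — real class weights were never published), plants SNVs
in a carrier fraction of clones, and applies i.i.d. substitution errors.
Errors are substitutions only, matching the caller's contract; RT-PCR
chimeras, template switching, cloning bias and base-quality information are
not simulated. Consequently, passing tests demonstrate correctness of the
reconstruction logic under the stated error model, not robustness to every
artifact of real clone libraries. `simulate_genotype_panel()` draws
genotypes multinomially from Hardy-Weinberg proportions (or a supplied
distribution). All generators take explicit integer seeds and restore the
session RNG state.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_mismatch_per_exon` | 2 | substitutions/exon | observed SNV density (≤2 per exon) |
| `min_clone_support` | 2 | clones | singleton mismatches are likely RT/PCR artifacts |
| `nmd_threshold` | 50 | nt | classic junction rule; strict inequality |
| `signal_peptide_len` | 15 | residues | annotated for both loci |
| `tolerance_bp` | 5 | bp | 3% agarose band resolution |
| `error_rate` | 0 | subs/base | simulation default: clean Sanger consensus |
| `n_clones` | 80 | clones | scale of one clone-screening campaign |

## Problem sizes used in the test suite

Tests run the generators at the study's own scale: 80-clone (CSN1S2 I) and
60-clone (CSN1S2 II) zero-error libraries for catalogue recovery, 119-animal
panels for the HWE calibration (1000 replicates), and n = 10,000 panels for
frequency recovery; brute-force caller comparisons use 4-exon toy models
where exhaustive enumeration is cheap.

## Known limitations

* Cryptic-site discovery is dinucleotide + frame only; no MaxEnt/PWM
  scoring.
* The caller does not discover unannotated intronic exons de novo; extra
  exons are model annotations, found in reality by inspection.
* Clones shorter than the transcript are not partially matched.
* No diploid phasing or haplotype reconstruction from clone data.
* Printed reference masses tied to deposited accessions are not asserted
  against the real records (the package computes them from any supplied
  cDNA FASTA via `reference_protein_report()`); the synthetic models carry
  random filler, so their absolute masses differ from the real proteins
  while every length, frame and flag behavior is exact.
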