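---
title: "Quantifying CRISPR/Cas9 editing outcomes from pooled short-read sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR/Cas9 editing outcomes from pooled short-read sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editAftermath)
```

## The problem

CRISPR/Cas9 followed by non-homologous end joining (NHEJ) is the standard
route to gene knockouts in yeasts with poor homologous recombination, such
as *Komagataella phaffii*. The repair outcome at the cut site is not always
the intended small frameshift: large deletions, chromosomal rearrangements
between simultaneously targeted loci, and even telomere-capped chromosome
truncations occur at substantial rates, while true off-target mutations are
rare. Characterising this spectrum requires whole-genome sequencing of many
transformant colonies, usually pooled to keep costs reasonable.

`editAftermath` implements the full desk-side analysis for such experiments:

* **guide design**: enumerate protospacers with an NGG PAM inside a coding
  sequence, keep guides that cut in the 5' portion of the CDS (where a
  frameshift is most disruptive) and that have no second verbatim match in
  the genome; independently, find all maximal regions larger than a cutoff
  that contain no essential gene (candidate regions for large deletions);
* **off-target scanning**: enumerate every genomic site matching a guide
  with up to a configurable number of protospacer mismatches next to an
  intact NGG or NAG PAM, annotate mismatches in the 5-base seed region, and
  intersect sites with observed variants;
* **variant triage**: reduce raw variant calls to candidate *de novo*
  mutations (DNMs) by subtracting base-strain variants, masking blacklist
  regions, removing variants that recur across experiments with unrelated
  guides, annotating coding effects and splitting on- from off-target;
* **on-target quantification**: rebuild the local mutant sequence for every
  variant at a target, assign each read to its best-matching genotype,
  and report relative read support per genotype and per class, plus
  targeting efficiency;
* **junction analysis**: imperfect microhomology at rearrangement
  breakpoints (the MMEJ signature) and telomeric tandem repeats at
  one-sided junctions (chromosome truncation);
* **simulation**: a generative model of the whole experiment — annotated
  genome, per-colony repair outcomes, edited genomes, pooled paired-end
  reads with a truth manifest — used to validate every analysis step by
  plant-and-recover.

## Outcome classes and classification rule

Genotypes are classified from the signed net length change *n* of the
variant:

| condition                         | class          |
|-----------------------------------|----------------|
| no change                         | WT             |
| single-nucleotide substitution    | substitution   |
| 1 ≤ \|n\| ≤ 49, n ≡ 0 (mod 3)     | in-frame       |
| 1 ≤ \|n\| ≤ 49, n ≢ 0 (mod 3)     | frameshift     |
| \|n\| ≥ 50, or any breakend/inversion/duplication/translocation | SV |

SVs additionally carry a frame-preserving flag (`n mod 3 == 0`): a 57 bp
deletion is an SV that conserves the reading frame. On-target substitutions
get their own class rather than being folded into in-frame, because the
four-way scheme above never produces them and silently merging them would
distort targeting efficiency. Targeting efficiency is the summed relative
read support of all non-wildtype genotypes, i.e. 1 − WT fraction.

## Read-support quantification

For each target the reference window (default flank: 1000 bp each side of
the cut, comfortably beyond the reach of a 550 bp fragment) is the wildtype
model; every distinct variant produces one mutant model by splicing the
variant into the window (deletions remove the span, breakends concatenate
the two partner flanks in junction orientation, truncations append the
telomeric cap, inversions append the reverse-complemented far flank). A
reciprocal rearrangement creates two junctions anchored at the same cut
site, one per derivative chromosome; only the retained-left junction is
modelled so that each repair event yields exactly one genotype sequence per
target and read support is not double-counted.

Reads are assigned by a purpose-built best-match classifier, not a general
aligner: each mate is anchored into the models by exact k-mer lookup
(k = 25, three anchor positions; every anchor's proposed offset is verified
by Hamming distance and the best-verifying one kept, which makes anchoring
robust inside periodic sequence such as a telomere tract), scored on both
strands, and assigned to the unique model with the strictly lowest mismatch
count within a per-read budget (default 8). Ties across models are
discarded as ambiguous — the analogue of removing multimapped reads — and
an assignment only counts if the alignment covers the model's variant
position with at least 5 bases on each side, an explicit anchor rule for
"read support counted at the exact position of the variant". Relative
support is computed over retained reads only; genotypes with fewer than 5
reads are flagged as minor genotypes (colonies that had not yet lost the
CRISPR plasmid present as such mixtures) but never dropped.

## Triage model

A call is a candidate DNM if it survives, in order: blacklist masking
(reference-error regions supplied as BED), base-strain subtraction (exact
match on chromosome/position/REF/ALT for small variants; breakend-locus
matching with a 10 bp per-breakend tolerance for SVs, reflecting caller
jitter), and recurrence filtering (a variant seen in two or more
experiments whose guide sets are disjoint is a base-strain artefact, not a
CRISPR effect). DNMs are then annotated for coding effect (reference span
intersecting any CDS; frameshift iff the net length change is not a
multiple of 3) and classified on- vs off-target (within 100 bp of any
experiment cut locus, or a breakend partnered to such a locus — the radius
is a design choice that must contain NHEJ indel scatter while excluding
unlinked variants). Every input call receives exactly one fate
(`blacklisted`, `pre-existing`, `low-support`, `recurrent`, `on-target-DNM`,
`off-target-DNM`), logged per call, so the count ledger is auditable:
totals equal DNMs plus removed calls, and on-target plus off-target equals
DNMs, per sample and variant type (SNV / InDel / SV, where explicit-allele
indels of at least 50 bp count as SVs).

For pooled samples the variant caller is expected to run at ploidy equal to
the pool size (five in the emulated design); triage optionally gates calls
on a minimum supporting-read fraction of local depth (default 1/10, half a
colony's expected share) when depth information is available.

## The simulator and what it does (not) model

The generator emulates the study design end to end: a multi-chromosome
genome of uniform random sequence with non-overlapping single-exon genes
(CDS length a multiple of 3) and Bernoulli essentiality flags; single- or
double-target experiments with one repair outcome per target locus per
colony (a joint rearrangement or inversion replaces both); pools of up to 5
colonies; 150 bp paired reads from ~550 bp fragments (Gaussian, SD 60 bp)
at 100- or 300-fold coverage with uniform substitution errors and constant
base qualities. Fragment counts across pool members are proportional to
genome size — the fragment pool obtained by mixing equal cell quantities —
so per-locus depth is equal across colonies even when an edit changes a
genome's size. Fragments overlapping a chromosome terminus are clipped at
it, as mechanical shearing of a linear molecule dictates; fragment ends
therefore pile up at chromosome ends and junctions close to a new terminus
(a telomere-capped truncation) retain full mate coverage. Truth is emitted as a TSV manifest and VCF 4.2 (indels
left-anchored; rearrangements as two MATEID-linked BND pairs; inversions as
`<INV>`; truncations as single breakends whose ALT carries the appended
telomere sequence). All serialized coordinates are 1-based inclusive.

Free parameters the source experiments do not pin down were fixed once:

* **indel size models**: small indels uniform on 1–10 bp, large indels
  uniform on 50–1200 bp. The upper bound keeps any deletion inside the
  default ±1000 bp genotype window (both are configurable together); the
  observed spectrum in gene targets spanned tens of bp to a few kb.
  Deletions outnumber insertions (0.6 small, 0.8 large), reflecting the
  deletion bias of end joining.
* **telomere cap**: the repeat motif is not printed in the source and is a
  configuration value shared by simulator and detector (default
  `TGGTGTGG`, an 8-mer; yeast telomeric repeats are short and G/T-rich).
  The default tract is 25 tandem copies (200 bp), comparable to yeast
  telomere tracts and longer than one read, so junction-spanning reads
  always contain enough cap sequence to call the tandem repeat.
* **class probabilities** (pipeline default 0.2 WT / 0.4 small indel /
  0.15 large indel / 0.15 rearrangement / 0.1 truncation) produce the
  qualitative mix reported for double-target experiments: mostly indels,
  a substantial SV fraction, occasional truncations.

The simulator deliberately omits: empirical error profiles (no indel
sequencing errors, no quality decay), GC or coverage bias, mitochondrial
and plasmid sequence, and any attempt to replicate the real CBS7435
assembly. Consequently, passing plant-and-recover tests demonstrates that
the analysis logic is correct under the stated read model — not that it is
robust to real-instrument artefacts, mappability structure or repeat
content of a real genome; on real data the variant calls come from
dedicated callers upstream and this package consumes their VCFs.

## Numerical and convention choices

* Coordinates are 1-based inclusive in every serialized record; BED output
  follows its own 0-based half-open standard.
* The cut locus is the protospacer base 3 nt from the PAM (the canonical
  blunt cut position); the field definition is an anchor for windows, not a
  mechanistic claim.
* Off-target scanning is fixed-length Hamming comparison (no DNA/RNA
  bulges). Mismatches are counted over the protospacer only; any deviation
  of the 3-mer PAM from the allowed motifs (NGG, NAG by default) excludes
  the site. `N` in a genome never matches a guide base. Overlapping sites
  on opposite strands are both reported. The scan is exactly equivalent to
  a naive per-position comparison, and is tested for set equality against
  an independent brute-force implementation and against
  `Biostrings::matchPattern`.
* A variant's range is its reference-allele span (insertions occupy the
  single anchor base), following VCF semantics. "Within *w* bases" of a
  site means the spans are separated by at most *w − 1* gap bases, i.e.
  the variant's *w*-base flanking windows touch the site span.
* Microhomology at a junction compares the *L* bases ending the retained
  flank of breakend A with the *L* bases on the lost side of breakend B and
  reports the longest *L* (up to 25) with at most the allowed mismatches
  (default 2); with a 2-mismatch budget, unrelated flanks typically score
  2–4 by chance, which is why the planted-signature tests force
  disagreement just beyond the planted window.
* Truncation calls require at least 3 complete tandem motif copies at the
  start of the appended sequence (a trailing partial copy is tolerated but
  does not count towards the threshold).
* Determinism: every stochastic operation takes an explicit seed; the
  pipeline derives per-stage seeds from one master seed, and two runs with
  identical configuration produce byte-identical outputs (FASTQ is written
  uncompressed by default because gzip headers are not byte-stable).

## Validation strategy and problem sizes

The test suite validates each operation against an independent oracle:
brute-force per-position scans for binding sites and essential-free
regions, exhaustive window search for microhomology, an independently
restated rule table for classification, and binomial sampling theory for
all stochastic recoveries. The end-to-end check runs the full synthetic
study — a 4-chromosome ~2 Mb genome with 400 genes, two guides on
different chromosomes, 10 colonies in 2 pools with every outcome class
represented, 300× pooled coverage, 0.1% base errors — and requires every
planted DNM to be recovered, no base-strain variant to survive triage,
class-support fractions to land within 3 binomial SD of the planted colony
mixtures, the truncation breakpoint within ±5 bp, and the planted
5 bp / 2-mismatch junction microhomology to be recovered exactly. The same
study, driven by `run_recovery_study()`, is what `scripts/acceptance.R`
re-executes. A ~2 Mb genome keeps a full run at a few minutes on one core
while leaving every length scale (gene, fragment, flank, chromosome) well
separated; the recovered quantities are read fractions whose precision is
set by coverage, not genome size.

## Known limitations

* The read assigner is a window classifier, not an aligner: it does not
  model indel sequencing errors within a read, soft-clipping or split
  reads, and it presumes the genotype window contains the whole variant.
* Colony attribution inside a pool is not attempted; support fractions are
  pool-level quantities.
* Essentiality is an annotation input; the NE-region finder makes no
  viability predictions of its own, and curated exclusions (e.g. genes
  essential only on some carbon sources) must be supplied by the user.
* The recurrence filter needs experiment metadata (guide sets per
  experiment); within a single experiment it never removes anything when
  distinct guides are required.
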