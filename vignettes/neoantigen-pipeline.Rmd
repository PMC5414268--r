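---
title: "Calling tumour-specific neoantigens with neoscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tumour-specific neoantigens with neoscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscan)
```

## The model

A tumour-specific neoantigen is a peptide produced only by tumour cells,
either presented to T cells by class I MHC molecules or, for membrane
proteins, exposed extracellularly to antibodies. `neoscan` models the path
from paired tumour–normal somatic calls to both candidate classes as a
chain of small, individually testable stages. The underlying assumptions
are:

* somatic status is decided purely from read support in the two samples of
  one donor (no panel-of-normals, no population frequencies);
* one variant is applied to one transcript at a time — co-occurring
  variants on a haplotype are not phased;
* MHC presentation is summarised entirely by a predicted IC50 in nM per
  (peptide, allele); no cleavage, transport or expression modelling;
* a mutant peptide is interesting when it binds and the matched wild-type
  peptide does not — the wild type then cannot occupy the same HLA in
  normal tissue, so recognition should be tumour-specific.

## Stage by stage

### Somatic filter

A record passes iff **all** of: tumour depth > 10 reads, normal depth > 6,
tumour alt reads > 5, tumour VAF > 0.05, and normal VAF = 0. All
comparisons are strict, matching the "greater than" form in which such
cut-offs are conventionally stated, and the normal-VAF rule is an exact
zero (a single supporting read in the normal rejects the record): the
filter's job is to exclude germline variants and artefacts, and a
tolerance here would readmit low-level germline contamination. "Depth" is
total site depth (reference plus alternate reads) per sample — the only
reading consistent with a separate alt-read criterion. VAF is recomputed
from the `AD` field as alt/(ref+alt) whenever depths are available, so the
verdict does not depend on caller-specific `AF` conventions; an explicit
`AF` is used only when `AD` is absent. Multiallelic rows are decomposed
per ALT allele before filtering, with per-allele alt counts. Failures are
audited with the first failing criterion in a fixed order (tumour depth,
normal depth, tumour alt, tumour VAF, normal VAF). INDELs are subjected to
the identical thresholds — there is no read-level reason to treat them
differently.

### Coding consequences

Transcripts are a deliberately minimal flat model — id, gene, strand,
ordered CDS segments, spliced sense-strand CDS, downstream UTR sequence —
rather than a full GTF/GFF import: the pipeline needs exactly the
information to re-translate a mutated CDS, fixtures stay self-contained,
and users with richer annotation can project it down. The CDS must start
`ATG`, end in a stop, and tile the declared segments.

SNVs substitute one codon (reverse-complemented onto the sense strand for
`-`-strand transcripts); frameshift indels re-translate the shifted frame
from the first affected codon, continuing past the original stop into the
downstream UTR sequence until a stop is found (flagged `no_stop_found` and
truncated if none exists); in-frame indels are handled analogously with a
common-prefix/suffix novel span. Start-loss, stop-loss, splice-region and
complex substitutions are declared unsupported and classified
`non_coding` with a warning rather than guessed at, since nothing
downstream could use them (stop-gain similarly yields no novel residues
and hence no candidate peptides). When a variant hits several isoforms,
all are reported; selection is left to aggregation, which counts donors,
not transcripts.

### Peptide windows

The context is 21 residues — 10 each side of the mutation — because class
I ligands are 8–11-mers: 10 flanking residues are exactly enough for every
8–11-mer containing the mutated residue to lie inside the window. At
protein termini the context is clipped, never padded: peptides containing
padding characters would be chemically meaningless. Candidates are all
substrings of length 8–11 whose span covers a mutated residue, emitted in
(length, offset) order; an interior missense site yields 8+9+10+11 = 38.
For frameshifts every residue from the first novel one to the mutant
C-terminus is mutated, there is no matched wild-type peptide, and all its
binders are therefore mutant-specific by construction. Duplicate peptide
strings at different offsets are kept at this stage and deduplicated at
prediction time, so provenance is preserved but backends are called once
per unique (peptide, allele).

### Binding classification and comparison

IC50 thresholds: strong < 150 nM, weak 150–500 nM inclusive, non-binding
> 500 nM. The weak interval is closed on both ends so the three classes
tile the positive axis with no gaps — the stated "less than 150" and "more
than 500" force both endpoints into the middle class. Mutant-specificity
is the conjunction *mutant binds* AND *wild type absent or non-binding*.
All mutant binders are retained in output with the specificity flag, so
both the specific-only and the all-binders counting are available
downstream.

Backends are pluggable behind the contract `(peptide, allele) -> IC50 nM`.
The built-in toy backend is a pure integer hash (base-31 string hash
modulo 1000003, documented in the source) mapped into [1, 50000] nM, with
a pinned anchor table that fixes a dozen literature peptide–allele pairs
(the TP53 R248W pair among them) to their published affinities; it exists
so that the full pipeline, including binding-class logic, runs
deterministically offline on any platform. It is not a predictor of real
affinities. NetMHCpan v2.8 tabular output is parsed into the same record
shape, so swapping backends changes values, never structure.

### Membrane topology

TMHMM v2.0 long-format segments are parsed with the tiling invariant
enforced (segments must cover 1..length contiguously), making region
lookup a total function. Only `outside` segments count as extracellular;
signal peptides are not modelled. Membrane-protein membership is a plain
id list supplied by the user. Only missense mutations are mapped — an
antibody epitope requires a folded, membrane-anchored protein, which a
frameshift rarely preserves. Polarity change (four classes: nonpolar,
polar-uncharged, acidic, basic; any class change counts) is an
*annotation*, never a filter: it marks substitutions more likely to alter
antibody binding, but non-changing substitutions remain in the output.

### Aggregation

Recurrence counts **distinct donors** per mutation key, so a donor
reporting a mutation on two isoforms counts once, and renders "k out of N"
against the user-supplied cohort size. Sorting is count-descending with
lexicographic (gene, protein change) tie-breaks, so tables are
deterministic. Per-allele load divides binder records by donors *carrying
the allele* (per the manifest); per-type load summarises per-donor
mutant-specific binder counts with mean, median and quartiles using the
lower-interpolation convention (`stats::quantile`, type 1), chosen so
integer fixtures have exact expected summaries. Donors with zero
neoantigens are included as zeros. Because the unit behind a "neoantigen
count" is ambiguous (records vs unique peptides), both countings are
exposed via the `unit` argument.

## The fixture generator

`generate_fixture_cohort()` emulates, at toy scale, the input universe of
a tumour–normal cohort study: per-donor paired VCFs with `AD` fields,
transcript models, TMHMM topologies, a membrane list, and a manifest with
per-donor six-allele class I typings (two per locus, mirroring diploid
HLA) drawn from the built-in 16-allele panel. Defaults — 5 donors, 8
transcripts of 45–75 codons, per donor 4 missense + 1 synonymous + 1
frameshift passing variants, half the proteins membrane — were chosen once
as the smallest cohort that exercises every code path: one shared missense
in an extracellular segment (recurrence across all donors), missense at
near-N-terminal, C-terminal, extracellular and transmembrane positions,
and five records for the first donor each violating exactly one filter
criterion at its boundary. The generator writes an expected-count ledger
computed from the planted construction (closed-form window arithmetic per
site), which a pipeline run then re-counts independently.

What the fixtures do **not** emulate: real read-depth noise and strand
bias, splice structure (single-segment CDS only, though the projection
code handles multi-segment transcripts and is tested on them), sequence
context effects on binding (the toy backend is a hash), isoform
multiplicity, and cohort-scale heterogeneity. Passing tests therefore
demonstrate the correctness of the record-level logic and bookkeeping,
not predictive performance on real tumours.

## Numerical and degenerate-input choices

* All thresholds live in constructor objects (`filter_thresholds()`,
  `binding_thresholds()`, `window_params()`) and are overridable;
  defaults are the values above.
* Exact-zero normal VAF: no epsilon.
* Context shorter than the minimum peptide length yields an empty
  candidate set with a warning (a 7-residue protein has no 8-mers).
* A frameshift that exhausts CDS+UTR without a stop is truncated and
  flagged rather than dropped.
* An indel that leaves the protein unchanged is reclassified synonymous.
* TSV outputs carry a fixed column order with a `#` header line and are
  written atomically (temp file + rename); identical inputs reproduce
  byte-identical tables under the toy backend.
* The run log's config hash uses the same documented string hash as the
  toy backend; it is a provenance aid, not cryptography.

## Problem sizes used in the test suite

Property checks run on generated cases under fixed seeds: 1000 random
contexts against a brute-force window enumerator, 1000 random CDSs against
an independent codon-table translation, 500 random transcripts for
strand-symmetry and reciprocal-variant checks, grids of a few hundred
points for the filter and classifier boundaries, and the seed-42
five-donor cohort end to end (twice, for byte-identity). These sizes make
the suite exhaustive over the combinatorial edge cases while completing in
about a minute.

## Known limitations

* No phasing: two somatic variants in one codon are applied separately,
  each against the reference transcript.
* Splice-site, start-loss and stop-loss variants are reported unsupported
  rather than modelled.
* IC50 is the sole binding score; percentile-rank thresholds of newer
  predictors are out of scope.
* The somatic filter is read-count based only; it will not remove
  artefacts that look clean in both samples.
* Extracellular accessibility is equated with TMHMM `outside` topology;
  no structure-based epitope accessibility.
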