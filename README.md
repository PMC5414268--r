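# neoscan

Prediction of candidate tumour-specific neoantigens from paired
tumour–normal somatic variant calls.

## The problem

Somatic mutations in protein-coding regions can produce proteins that exist
only in tumour cells. Two kinds of mutant protein are of immediate
therapeutic interest: peptides presented on the cell surface by class I MHC
(HLA-A/B/C) molecules, where a mutant peptide that binds a patient's HLA
while its wild-type counterpart does not is a candidate T-cell target; and
missense mutations falling in the extracellular regions of membrane
proteins, which are accessible to antibodies. `neoscan` implements the
analysis chain from somatic calls to both kinds of candidate, for
bioinformaticians analysing tumour–normal sequencing cohorts.

## What it computes

1. **Somatic filter.** A variant record with per-sample depths passes iff
   tumour depth > 10, normal depth > 6, tumour alt reads > 5, tumour
   VAF > 0.05 and normal VAF = 0 (all strict; the normal-VAF rule is an
   exact zero). VCF 4.x with per-sample `AD` fields is read via `vcfR`;
   multiallelic rows are decomposed per ALT.
2. **Coding consequence.** Each passing variant is applied to overlapping
   transcript models: SNVs substitute a codon (synonymous / missense /
   stop-gain); indels in anchor-base VCF convention yield frameshifts whose
   mutant protein is re-translated through the downstream UTR to the first
   stop, or in-frame indels. The full mutant protein is always produced.
3. **Candidate peptides.** Around each protein-altering site a 21-residue
   context (10 residues each side, clipped at termini) is extracted on both
   mutant and wild-type proteins, and every 8–11-mer containing a mutated
   residue is enumerated — 8+9+10+11 = 38 candidates for an interior
   missense site — each paired with the same-offset wild-type peptide
   (frameshift peptides have none).
4. **HLA binding.** Each unique (peptide, allele) is scored as an IC50 in
   nM by a pluggable backend and classified: strong < 150 nM,
   weak 150–500 nM, non-binding > 500 nM. A mutant peptide is
   *mutant-specific* when it binds and its wild-type counterpart does not
   (or does not exist). Backends: a deterministic offline toy scorer with
   pinned literature anchors, and a parser for NetMHCpan v2.8 tabular
   output. A default panel of the 16 class I alleles with >5% population
   frequency is built in.
5. **Extracellular mapping.** Missense mutations on listed membrane
   proteins are mapped through TMHMM v2.0 long-format topologies; those in
   `outside` segments are reported, annotated (never filtered) with whether
   the substitution changes amino-acid polarity class.
6. **Cohort aggregation.** Mutation recurrence ("k out of N donors",
   counting distinct donors), neoantigen load per HLA allele and per tumour
   type (mean, lower-interpolation median and quartiles of per-donor
   counts).

A synthetic fixture generator (`generate_fixture_cohort()`) emits a
complete toy cohort — transcripts, per-donor VCFs, topologies, manifest —
with known planted ground truth and an expected-count ledger, so the whole
pipeline runs and is tested fully offline.

## Worked example

The TP53 R248W site: mutant 11-mer `GMNWRPILTII`, wild type `GMNRRPILTII`,
on HLA-A\*02:01 (toy backend, which pins this pair to its published
affinities):

```r
library(neoscan)
pairs <- data.frame(mt_peptide = "GMNWRPILTII", wt_peptide = "GMNRRPILTII")
preds <- predict_affinities(pairs, "HLA-A*02:01")
preds
#>       peptide      allele ic50_nm binding_class backend_id
#> 1 GMNWRPILTII HLA-A*02:01     350          weak        toy
#> 2 GMNRRPILTII HLA-A*02:01    8000   non_binding        toy
compare_bindings(pairs, preds, "HLA-A*02:01")$mutant_specific
#> [1] TRUE
```

The mutant binds weakly (350 nM, between the 150 and 500 nM cut-offs), the
wild type does not (8000 nM > 500 nM), so the pair is called
mutant-specific: a candidate neoantigen.

End to end on a generated five-donor cohort:

```r
fx  <- generate_fixture_cohort(fixture_spec(seed = 42, n_donors = 5), "fixtures")
cfg <- pipeline_config(vcf_dir = "fixtures/vcf",
                       transcripts_tsv = "fixtures/transcripts.tsv",
                       cds_fasta = "fixtures/cds.fasta",
                       tmhmm = "fixtures/topology.tmhmm",
                       membrane_list = "fixtures/membrane_ids.txt",
                       manifest = "fixtures/manifest.tsv",
                       out_dir = "out")
res <- run_pipeline(cfg)
res$counts
#>       records   pass_filter        coding      peptides      bindings extracellular
#>            35            30            25           940          5640            10
head(res$frequency[, c("gene_symbol", "protein_change", "frequency")], 1)
#>   gene_symbol protein_change  frequency
#> 1      GENE01           K15N 5 out of 5
```

35 variant records enter; 30 pass the somatic filter (the generator plants
one violation of each of the five criteria); 25 are protein-altering
(missense/frameshift — the per-donor synonymous variants drop out); they
fan out to 940 candidate peptides and 5640 peptide×allele binding records;
10 missense sites fall in extracellular membrane-protein segments. The
recurrence table shows the planted shared mutation present in all 5 donors.
These counts equal the generator's expected-count ledger, which the test
suite asserts.

## Scope

`neoscan` consumes somatic calls; it does not do read alignment or variant
calling, does not reimplement the TMHMM hidden Markov model or the
NetMHCpan neural networks (it parses/adapts their outputs), and does not
model proteasomal cleavage, TAP transport or class II presentation. See the
methods vignette (`vignettes/neoantigen-pipeline.Rmd`) for the model,
parameter choices and limitations.
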