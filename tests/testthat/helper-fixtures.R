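# Builders shared across test files. All randomness is seeded by callers.

# Random transcript on its own chromosome; single CDS segment at 1001.
random_transcript <- function(n_codons = 40L, strand = "+", id = "TX01",
                              utr = "TTAATTAATTAA") {
  code <- genetic_code()
  non_stop <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  cds <- paste0("ATG", paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                             collapse = ""), sample(stops, 1L))
  transcript_model(id, paste0("G", id), "chr1", strand,
                   matrix(c(1001L, 1000L + nchar(cds)), ncol = 2), cds, utr)
}

# The '-' strand mirror of a '+' strand transcript: same sense CDS, segment
# re-anchored so that sense coordinates map through the reverse projection.
mirror_transcript <- function(tx) {
  stopifnot(tx$strand == "+")
  transcript_model(tx$transcript_id, tx$gene_symbol, tx$chrom, "-",
                   tx$cds_segments, tx$cds_sequence,
                   tx$downstream_utr_sequence)
}

# Genomic coordinates/alleles of the variant at sense CDS position cpos.
genomic_snv <- function(tx, cpos, sense_alt) {
  seg <- tx$cds_segments[1L, ]
  sense_ref <- substr(tx$cds_sequence, cpos, cpos)
  if (tx$strand == "+") {
    list(pos = unname(seg["start"]) + cpos - 1L, ref = sense_ref,
         alt = sense_alt)
  } else {
    rc <- function(b) chartr("ACGT", "TGCA", b)
    list(pos = unname(seg["end"]) - cpos + 1L, ref = rc(sense_ref),
         alt = rc(sense_alt))
  }
}

# Independent brute-force candidate enumerator: generate every substring of
# every admissible length, then keep those whose index range covers the
# mutated span. Used as the oracle for enumerate_candidates().
brute_force_candidates <- function(sequence, span, kmin = 8L, kmax = 11L) {
  if (length(span) == 1L) span <- c(span, span)
  L <- nchar(sequence)
  grid <- expand.grid(offset = seq_len(L), length = kmin:kmax,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$offset + grid$length - 1L <= L, , drop = FALSE]
  covered <- vapply(seq_len(nrow(grid)), function(i) {
    idx <- grid$offset[i]:(grid$offset[i] + grid$length[i] - 1L)
    any(idx >= span[1L] & idx <= span[2L])
  }, logical(1))
  grid <- grid[covered, , drop = FALSE]
  grid <- grid[order(grid$length, grid$offset), , drop = FALSE]
  if (!nrow(grid)) {
    return(data.frame(sequence = character(), length = integer(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  data.frame(sequence = substring(sequence, grid$offset,
                                  grid$offset + grid$length - 1L),
             length = grid$length, offset = grid$offset,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Minimal raw two-sample VCF text for reader tests.
write_test_vcf <- function(path, rows,
                           samples = c("TUM", "NORM")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

fixture_dir_for <- function(seed = 42L, n_donors = 5L) {
  dir <- file.path(tempdir(),
                   sprintf("neoscan_fx_s%d_d%d", seed, n_donors))
  if (!dir.exists(dir)) {
    generate_fixture_cohort(fixture_spec(seed = seed, n_donors = n_donors),
                            dir)
  }
  dir
}
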