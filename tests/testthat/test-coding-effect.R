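toy_tx <- function(strand = "+") {
  # CDS "ATG GGT AAG TGA" -> protein MGK
  transcript_model("TX", "GENE", "chr1", strand,
                   matrix(c(101L, 112L), ncol = 2),
                   "ATGGGTAAGTGA", "ATAA")
}

test_that("translation halts at the first stop and validates its alphabet", {
  expect_equal(as.character(translate_cds("ATGAAATAG")), "MK")
  expect_equal(as.character(translate_cds("ATGTAA")), "M")
  expect_error(translate_cds("ATGAAXTAG"), "outside")
  expect_warning(tr <- translate_cds("ATGAAATAGC"), "partial")
  expect_equal(as.character(tr), "MK")
  no_stop <- translate_cds("ATGAAAAAA")
  expect_true(attr(no_stop, "no_stop_found"))
})

test_that("translation agrees with Biostrings over random CDSs", {
  set.seed(21)
  code <- genetic_code()
  for (i in 1:1000) {
    n <- sample(2:30, 1) * 3
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    mine <- as.character(translate_cds(seq))
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                              no.init.codon = TRUE))
    ref <- sub("\\*.*$", "", ref)          # independent stop-trim
    expect_identical(mine, ref)
  }
})

test_that("genomic-to-CDS projection handles both strands and outside sites", {
  plus <- transcript_model("T1", "G", "chr1", "+",
                           matrix(c(101L, 109L), ncol = 2),
                           "ATGAAATAG", "")
  expect_equal(project_genomic_to_cds(plus, 105L), 5L)
  expect_true(is.na(project_genomic_to_cds(plus, 100L)))
  minus <- transcript_model("T2", "G", "chr1", "-",
                            matrix(c(101L, 109L), ncol = 2),
                            "ATGAAATAG", "")
  expect_equal(project_genomic_to_cds(minus, 109L), 1L)
  expect_equal(project_genomic_to_cds(minus, 101L), 9L)
})

test_that("projection walks multi-segment (spliced) transcripts", {
  # two CDS exons with an intron between
  tx <- transcript_model("T3", "G", "chr1", "+",
                         matrix(c(101L, 106L, 201L, 206L), ncol = 2,
                                byrow = TRUE),
                         "ATGAAACCCTGA", "")
  expect_equal(project_genomic_to_cds(tx, 106L), 6L)
  expect_equal(project_genomic_to_cds(tx, 201L), 7L)
  expect_true(is.na(project_genomic_to_cds(tx, 150L)))   # intron
})

test_that("SNVs are classified missense / synonymous / stop-gain", {
  tx <- toy_tx()
  # CDS pos 5 G>T: codon GGT -> GTT, Gly -> Val
  mis <- apply_variant(tx, 105L, "G", "T")
  expect_equal(mis$kind, "missense")
  expect_equal(mis$wt_residue, "G"); expect_equal(mis$mt_residue, "V")
  expect_equal(mis$protein_pos, 2L)
  expect_equal(mis$protein_change, "G2V")
  expect_equal(mis$wt_protein, "MGK"); expect_equal(mis$mt_protein, "MVK")

  syn <- apply_variant(tx, 106L, "T", "C")   # GGT -> GGC, both Gly
  expect_equal(syn$kind, "synonymous")
  expect_equal(syn$mt_protein, syn$wt_protein)

  sg <- apply_variant(tx, 107L, "A", "T")    # AAG -> TAG stop
  expect_equal(sg$kind, "stop_gain")
  expect_equal(sg$mt_protein, "MG")

  expect_equal(apply_variant(tx, 100L, "A", "T")$kind, "non_coding")
})

test_that("a 1-bp deletion frameshifts and re-translates into the UTR", {
  tx <- toy_tx()
  # delete CDS pos 5: ATG GTA AGT GAA TAA -> MVSE
  fs <- apply_variant(tx, 104L, "GG", "G")
  expect_equal(fs$kind, "frameshift")
  expect_equal(substr(fs$mt_protein, 1, 1), "M")    # shared prefix with MGK
  expect_equal(fs$mt_protein, "MVSE")
  expect_equal(fs$novel_span, c(2L, 4L))
  expect_false(fs$no_stop_found)
})

test_that("mirror-strand variants give identical consequences", {
  tx <- toy_tx("+")
  mtx <- mirror_transcript(tx)
  # '+' CDS pos 5 G>T is genomic 105 G>T; on '-', genomic 108 C>A
  plus <- apply_variant(tx, 105L, "G", "T")
  minus <- apply_variant(mtx, 108L, "C", "A")
  for (f in c("kind", "wt_residue", "mt_residue", "protein_pos",
              "wt_protein", "mt_protein", "protein_change")) {
    expect_identical(plus[[f]], minus[[f]], info = f)
  }
})

test_that("strand symmetry and reciprocal application hold on random transcripts", {
  set.seed(22)
  for (i in 1:60) {
    tx <- random_transcript(sample(20:50, 1))
    mtx <- mirror_transcript(tx)
    cpos <- sample(4:(nchar(tx$cds_sequence) - 3L), 1)
    sense_ref <- substr(tx$cds_sequence, cpos, cpos)
    sense_alt <- sample(setdiff(c("A", "C", "G", "T"), sense_ref), 1)
    vp <- genomic_snv(tx, cpos, sense_alt)
    vm <- genomic_snv(mtx, cpos, sense_alt)
    a <- suppressWarnings(apply_variant(tx, vp$pos, vp$ref, vp$alt))
    b <- suppressWarnings(apply_variant(mtx, vm$pos, vm$ref, vm$alt))
    expect_identical(a[c("kind", "protein_pos", "wt_protein", "mt_protein")],
                     b[c("kind", "protein_pos", "wt_protein", "mt_protein")])
    if (a$kind == "missense") {
      # hamming distance exactly 1 at protein_pos
      wt <- strsplit(a$wt_protein, "")[[1]]; mt <- strsplit(a$mt_protein, "")[[1]]
      expect_equal(which(wt != mt), a$protein_pos)
      # reciprocal variant on the mutant transcript restores the wild type
      mut_cds <- tx$cds_sequence
      substr(mut_cds, cpos, cpos) <- sense_alt
      tx2 <- transcript_model("R", "G", tx$chrom, "+", tx$cds_segments,
                              mut_cds, tx$downstream_utr_sequence)
      back <- apply_variant(tx2, vp$pos, vp$alt, vp$ref)
      expect_identical(back$mt_protein, a$wt_protein)
    } else if (a$kind == "synonymous") {
      expect_identical(a$wt_protein, a$mt_protein)
    }
  }
})

test_that("unsupported variant shapes degrade to non_coding with a warning", {
  tx <- toy_tx()
  expect_warning(sl <- apply_variant(tx, 110L, "T", "C"), "stop-loss")
  expect_equal(sl$kind, "non_coding")
  expect_warning(st <- apply_variant(tx, 102L, "T", "C"), "start-loss")
  expect_equal(st$kind, "non_coding")
  expect_warning(cx <- apply_variant(tx, 104L, "GG", "TT"), "complex")
  expect_equal(cx$kind, "non_coding")
})

test_that("reference mismatches are reported, not silently accepted", {
  tx <- toy_tx()
  expect_error(apply_variant(tx, 105L, "A", "T"), "mismatch")
})

test_that("annotation reports all overlapping transcripts per record", {
  tx1 <- toy_tx()
  tx2 <- transcript_model("TXB", "GENEB", "chr1", "+",
                          matrix(c(101L, 112L), ncol = 2),
                          "ATGGGTAAGTGA", "")
  recs <- somatic_variants("chr1", c(105L, 500L), "G", "T", 100, 50, 20, 0)
  ann <- annotate_records(recs, list(tx1, tx2))
  expect_equal(sum(ann$record_index == 1L), 2L)   # both isoforms
  expect_equal(ann$kind[ann$record_index == 2L], "non_coding")
})
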