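test_that("filter applies the five criteria with strict boundaries", {
  base <- somatic_variants("1", 100, "A", "T",
                           tumour_depth = 100, normal_depth = 50,
                           tumour_alt_reads = 20, normal_alt_reads = 0)
  expect_true(passes_somatic_filter(base)$pass)

  cases <- list(
    list(mod = list(tumour_depth = 10, tumour_alt_reads = 6),
         criterion = "tumour_depth"),                 # 10 is not > 10
    list(mod = list(normal_depth = 6), criterion = "normal_depth"),
    list(mod = list(tumour_alt_reads = 5, tumour_depth = 50),
         criterion = "tumour_alt"),                   # VAF 0.1 still passes
    list(mod = list(tumour_depth = 200, tumour_alt_reads = 10),
         criterion = "tumour_vaf"),                   # VAF exactly 0.05
    list(mod = list(normal_alt_reads = 1), criterion = "normal_vaf")
  )
  for (cs in cases) {
    r <- base
    for (f in names(cs$mod)) r[[f]] <- cs$mod[[f]]
    r$tumour_vaf <- r$tumour_alt_reads / r$tumour_depth
    r$normal_vaf <- r$normal_alt_reads / r$normal_depth
    v <- passes_somatic_filter(r)
    expect_false(v$pass)
    expect_identical(v$criterion, cs$criterion)
  }
})

test_that("verdict equals the brute-force conjunction on random records", {
  set.seed(11)
  n <- 400
  td <- sample(0:60, n, TRUE); ta <- pmin(td, sample(0:30, n, TRUE))
  nd <- sample(0:20, n, TRUE); na <- pmin(nd, sample(0:3, n, TRUE))
  recs <- somatic_variants("1", seq_len(n), "A", "T", td, nd, ta, na)
  v <- passes_somatic_filter(recs)
  manual <- td > 10 & nd > 6 & ta > 5 &
    ifelse(td > 0, ta / td, 0) > 0.05 & ifelse(nd > 0, na / nd, 0) == 0
  expect_identical(v$pass, manual)
})

test_that("improving a record never flips pass to fail (monotonicity)", {
  set.seed(12)
  mk <- function(td, nd, ta, tv) {
    somatic_variants("1", 1, "A", "T", td, nd, ta, 0,
                     tumour_vaf = tv, normal_vaf = 0)
  }
  for (i in 1:100) {
    td <- sample(11:200, 1); ta <- sample(6:td, 1)
    nd <- sample(7:80, 1); tv <- runif(1, 0.06, 1)
    r <- mk(td, nd, ta, tv)
    if (!passes_somatic_filter(r)$pass) next
    # raise one criterion field at a time, others held
    expect_true(passes_somatic_filter(mk(td + sample(1:50, 1), nd, ta, tv))$pass)
    expect_true(passes_somatic_filter(mk(td, nd + sample(1:50, 1), ta, tv))$pass)
    expect_true(passes_somatic_filter(mk(td + 50, nd, ta + sample(1:20, 1), tv))$pass)
    expect_true(passes_somatic_filter(mk(td, nd, ta, min(1, tv + runif(1))))$pass)
  }
  # any normal alt read above zero always fails
  r <- somatic_variants("1", 1, "A", "T", 1000, 1000, 500, 1)
  expect_false(passes_somatic_filter(r)$pass)
})

test_that("paired VCF reading decomposes per ALT and computes VAF from AD", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT:AD\t0/1:80,20\t0/0:50,0",
    "chr1\t200\t.\tA\tC,T\t.\t.\t.\tGT:AD\t0/1:60,30,10\t0/0:40,0,0"
  ))
  recs <- read_paired_vcf(path, "TUM", "NORM")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$tumour_depth[1], 100)
  expect_equal(recs$tumour_alt_reads[1], 20)
  expect_equal(recs$tumour_vaf[1], 0.2)
  # multiallelic row: two records sharing pos, per-allele alt counts
  expect_equal(recs$pos[2:3], c(200L, 200L))
  expect_equal(recs$alt[2:3], c("C", "T"))
  expect_equal(recs$tumour_alt_reads[2:3], c(30, 10))
  expect_equal(recs$tumour_depth[2:3], c(100, 100))
})

test_that("reader errors name missing samples and missing AD fields", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "chr1\t100\t.\tA\tT\t.\t.\t.\tGT:AD\t0/1:80,20\t0/0:50,0")
  expect_error(read_paired_vcf(path, "TUM", "ABSENT"), "ABSENT")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path2, "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1\t0/0")
  expect_error(read_paired_vcf(path2, "TUM", "NORM"), "AD|allelic")
})

test_that("records survive a write/re-read round trip", {
  set.seed(13)
  n <- 20
  td <- sample(20:200, n); ta <- round(td * runif(n, 0.1, 0.5))
  recs <- somatic_variants(paste0("chr", sample(1:3, n, TRUE)),
                           sample(1000:2000, n),
                           sample(c("A", "C", "G", "T"), n, TRUE),
                           "N", td, sample(20:60, n), ta, 0)
  recs$alt <- ifelse(recs$ref == "A", "G", "A")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_paired_vcf(recs, path, "TUM", "NORM")
  back <- read_paired_vcf(path, "TUM", "NORM", donor_id = "donor")
  ord <- order(back$chrom, back$pos)
  for (col in c("chrom", "pos", "ref", "alt", "tumour_depth", "normal_depth",
                "tumour_alt_reads", "normal_alt_reads", "tumour_vaf",
                "normal_vaf")) {
    expect_equal(back[[col]][ord],
                 recs[[col]][order(recs$chrom, recs$pos)],
                 info = col)
  }
})

test_that("coding restriction keeps passing protein-altering records only", {
  recs <- somatic_variants("1", 1:4, "A", "T",
                           tumour_depth = c(100, 10, 100, 100),
                           normal_depth = 50, tumour_alt_reads = c(20, 6, 20, 20),
                           normal_alt_reads = 0)
  kinds <- c("missense", "missense", "non_coding", "synonymous")
  kept <- filter_to_coding(recs, kinds)
  expect_equal(kept$pos, 1L)           # passing missense only
  expect_equal(nrow(filter_to_coding(recs[0, ], character())), 0L)
  expect_error(filter_to_coding(recs, c("missense", NA, "missense", "missense")),
               "missing")
})

test_that("filter_vcf_file writes the retained rows and a rejection audit", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT:AD\t0/1:80,20\t0/0:50,0",
    "chr1\t200\t.\tG\tC\t.\t.\t.\tGT:AD\t0/1:8,2\t0/0:50,0"
  ))
  out <- withr::local_tempfile(fileext = ".vcf")
  audit <- withr::local_tempfile(fileext = ".tsv")
  recs <- filter_vcf_file(path, "TUM", "NORM", out, audit)
  expect_equal(sum(recs$pass), 1L)
  kept <- readLines(out)
  expect_true(any(grepl("neoscan", kept)))
  expect_equal(sum(!startsWith(kept, "#")), 1L)
  rej <- read_neoscan_tsv(audit)
  expect_equal(rej$pos, 200L)
  expect_equal(rej$criterion, "tumour_depth")
})
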