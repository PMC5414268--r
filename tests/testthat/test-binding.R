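test_that("IC50 classification respects the printed boundaries", {
  expect_equal(classify_affinity(350), "weak")
  expect_equal(classify_affinity(149.9), "strong")
  expect_equal(classify_affinity(150), "weak")
  expect_equal(classify_affinity(500), "weak")
  expect_equal(classify_affinity(500.1), "non_binding")
  expect_error(classify_affinity(0), "positive")
  expect_error(classify_affinity(-5), "positive")
})

test_that("the three classes tile the positive axis monotonically", {
  set.seed(41)
  x <- sort(c(10^runif(500, -2, 5), 149:151, 499:501))
  cls <- classify_affinity(x)
  expect_true(all(cls %in% c("strong", "weak", "non_binding")))
  # class index never decreases as IC50 grows
  idx <- match(cls, c("strong", "weak", "non_binding"))
  expect_true(all(diff(idx) >= 0))
})

test_that("the default allele panel is the fixed 16-allele class I set", {
  panel <- default_allele_panel()
  expect_length(panel, 16L)
  expect_equal(sum(startsWith(panel, "HLA-A")), 5L)
  expect_equal(sum(startsWith(panel, "HLA-B")), 4L)
  expect_equal(sum(startsWith(panel, "HLA-C")), 7L)
  expect_silent(check_hla_alleles(panel))
  expect_error(check_hla_alleles("HLA-D*01:01"), "malformed")
  # lossless dialect round trip
  expect_equal(hla_dialect(hla_dialect(panel, "netmhcpan"), "standard"),
               panel)
})

test_that("the toy backend is pure, bounded and honours its anchors", {
  expect_equal(toy_backend("GMNWRPILTII", "HLA-A*02:01"), 350)
  expect_gt(toy_backend("GMNRRPILTII", "HLA-A*02:01"), 500)
  expect_equal(toy_backend("TEYKLVVVGAV", "HLA-B*40:01"), 90)
  set.seed(42)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    p <- paste(sample(aas, sample(8:11, 1), TRUE), collapse = "")
    a <- sample(default_allele_panel(), 1)
    v1 <- toy_backend(p, a); v2 <- toy_backend(p, a)
    expect_identical(v1, v2)
    expect_gte(v1, 1); expect_lte(v1, 50000)
  }
})

test_that("prediction deduplicates (peptide, allele) backend calls", {
  pairs <- data.frame(
    mt_peptide = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC"),
    wt_peptide = c("AAAAAAAC", "AAAAAAAC", NA),
    stringsAsFactors = FALSE)
  calls <- new.env(); calls$n <- 0L
  counting <- function(p, a) { calls$n <- calls$n + 1L; toy_backend(p, a) }
  preds <- predict_affinities(pairs, "HLA-A*02:01", backend = counting)
  expect_equal(calls$n, 3L)             # 2 unique mt + 1 wt
  expect_equal(nrow(preds), 3L)
  expect_equal(anyDuplicated(preds[c("peptide", "allele")]), 0L)
})

test_that("unsupported peptide lengths are skipped with a warning", {
  pairs <- data.frame(mt_peptide = c("AAAAAAAA", "AAAAAAAAAAAA"),
                      wt_peptide = NA_character_, stringsAsFactors = FALSE)
  expect_warning(preds <- predict_affinities(pairs, "HLA-A*02:01"),
                 "unsupported length")
  expect_equal(preds$peptide, "AAAAAAAA")
})

test_that("mutant specificity requires a mutant binder and a silent wild type", {
  mk <- function(p, a, ic) list(peptide = p, allele = a, ic50_nm = ic,
                                binding_class = classify_affinity(ic))
  # published pattern: WT non-binder + MT weak binder => specific
  cmp <- compare_wt_mt(mk("GMNWRPILTII", "HLA-A*02:01", 350),
                       mk("GMNRRPILTII", "HLA-A*02:01", 8000))
  expect_true(cmp$mutant_specific)
  expect_false(compare_wt_mt(mk("A", "HLA-A*02:01", 100),
                             mk("C", "HLA-A*02:01", 100))$mutant_specific)
  expect_false(compare_wt_mt(mk("A", "HLA-A*02:01", 600), NULL)$mutant_specific)
  expect_true(compare_wt_mt(mk("A", "HLA-A*02:01", 100), NULL)$mutant_specific)
  expect_error(compare_wt_mt(mk("AA", "HLA-A*02:01", 100),
                             mk("CC", "HLA-B*07:02", 100)), "alleles")
})

test_that("NetMHCpan v2.8 tabular output parses to predictions", {
  txt <- c(
    "# NetMHCpan version 2.8",
    "# Input is in PEPTIDE format",
    "HLA-A02:01 : Distance to traning data  0.000",
    "-----------------------------------------------",
    "  pos          HLA         peptide       Identity  1-log50k(aff)     Affinity(nM)    %Rank",
    "-----------------------------------------------",
    "    0  HLA-A02:01      GMNWRPILTII   PEPLIST        0.458          350.0     1.50",
    "    0  HLA-A02:01      GMNRRPILTII   PEPLIST        0.158         8000.0    12.00",
    "    0  HLA-B40:01      TEYKLVVVGAV   PEPLIST        0.561           90.0     0.50",
    "-----------------------------------------------")
  preds <- parse_netmhcpan_output(txt)
  expect_equal(nrow(preds), 3L)
  expect_equal(preds$allele[1], "HLA-A*02:01")
  expect_equal(preds$ic50_nm, c(350, 8000, 90))
  expect_equal(preds$binding_class, c("weak", "non_binding", "strong"))
  expect_equal(nrow(parse_netmhcpan_output(txt[1:6])), 0L)
  bad <- sub("350.0", "NOTANUMBER", txt)
  expect_error(parse_netmhcpan_output(bad), "line 7")
})

test_that("swapping backends changes values, never the record schema", {
  pairs <- data.frame(mt_peptide = "GMNWRPILTII", wt_peptide = "GMNRRPILTII",
                      stringsAsFactors = FALSE)
  a <- predict_affinities(pairs, "HLA-A*02:01", backend = toy_backend,
                          backend_id = "toy")
  b <- predict_affinities(pairs, "HLA-A*02:01",
                          backend = function(p, al) 42, backend_id = "other")
  expect_identical(names(a), names(b))
  expect_identical(vapply(a, class, ""), vapply(b, class, ""))
})

test_that("binding comparison joins predictions onto all pairs and alleles", {
  pairs <- data.frame(mt_peptide = c("GMNWRPILTII", "KLVVVGAV"),
                      wt_peptide = c("GMNRRPILTII", NA),
                      donor_id = "D1", stringsAsFactors = FALSE)
  alleles <- c("HLA-A*02:01", "HLA-B*07:02")
  preds <- predict_affinities(pairs, alleles)
  cmp <- compare_bindings(pairs, preds, alleles)
  expect_equal(nrow(cmp), 4L)
  r <- cmp[cmp$allele == "HLA-A*02:01" & cmp$mt_peptide == "GMNWRPILTII", ]
  expect_equal(r$mt_ic50, 350)
  expect_equal(r$wt_class, "non_binding")
  expect_true(r$mutant_specific)
  # flag always implies a mutant binder with silent/absent wild type
  sp <- cmp[cmp$mutant_specific, ]
  expect_true(all(sp$mt_class != "non_binding"))
  expect_true(all(is.na(sp$wt_class) | sp$wt_class == "non_binding"))
})
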