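#' Default thresholds for the somatic coding filter
#'
#' Cut-offs applied to paired tumour-normal calls before neoantigen
#' prediction: tumour site depth > 10 reads, normal site depth > 6 reads,
#' tumour alt-supporting reads > 5, tumour VAF > 0.05 and normal VAF
#' exactly 0. All count/VAF comparisons are strict; the normal-VAF rule is
#' an exact-zero test (any alt read in the normal fails the record).
#'
#' @param min_tumour_depth_excl Exclusive minimum tumour depth (reads).
#' @param min_normal_depth_excl Exclusive minimum normal depth (reads).
#' @param min_tumour_alt_excl Exclusive minimum tumour alt-read count.
#' @param min_tumour_vaf_excl Exclusive minimum tumour variant allele
#'   frequency (fraction).
#' @param max_normal_vaf Maximum allowed normal VAF; the default 0 requires
#'   exact equality (no tolerance).
#' @return An object of class `filter_thresholds`.
#' @export
#' @examples
#' filter_thresholds()
filter_thresholds <- function(min_tumour_depth_excl = 10,
                              min_normal_depth_excl = 6,
                              min_tumour_alt_excl = 5,
                              min_tumour_vaf_excl = 0.05,
                              max_normal_vaf = 0) {
  th <- list(
    min_tumour_depth_excl = min_tumour_depth_excl,
    min_normal_depth_excl = min_normal_depth_excl,
    min_tumour_alt_excl = min_tumour_alt_excl,
    min_tumour_vaf_excl = min_tumour_vaf_excl,
    max_normal_vaf = max_normal_vaf
  )
  stopifnot(all(vapply(th, function(x) is.numeric(x) && length(x) == 1L && x >= 0, logical(1))))
  structure(th, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Somatic filter thresholds (all strict unless noted):\n")
  cat(sprintf("  tumour depth      > %g\n", x$min_tumour_depth_excl))
  cat(sprintf("  normal depth      > %g\n", x$min_normal_depth_excl))
  cat(sprintf("  tumour alt reads  > %g\n", x$min_tumour_alt_excl))
  cat(sprintf("  tumour VAF        > %g\n", x$min_tumour_vaf_excl))
  cat(sprintf("  normal VAF       <= %g (0 means exact zero)\n", x$max_normal_vaf))
  invisible(x)
}

# Canonical criterion order used for "first failing criterion" reporting.
.filter_criteria <- c("tumour_depth", "normal_depth", "tumour_alt",
                      "tumour_vaf", "normal_vaf")

#' Construct somatic variant records
#'
#' Builds the per-ALT record table used throughout the pipeline. One row is
#' one alternate allele of one variant in one donor, with per-sample depths,
#' alt-read counts and variant allele frequencies.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles (`pos` 1-based).
#' @param tumour_depth,normal_depth Total site depth per sample (reads).
#' @param tumour_alt_reads,normal_alt_reads Alt-supporting reads per sample.
#' @param tumour_vaf,normal_vaf Variant allele frequencies; if `NULL`,
#'   recomputed as alt reads / depth (0 where depth is 0).
#' @param donor_id Donor identifier, recycled.
#' @return A `data.frame` with one row per record.
#' @export
somatic_variants <- function(chrom, pos, ref, alt,
                             tumour_depth, normal_depth,
                             tumour_alt_reads, normal_alt_reads,
                             tumour_vaf = NULL, normal_vaf = NULL,
                             donor_id = "donor") {
  if (is.null(tumour_vaf)) {
    tumour_vaf <- ifelse(tumour_depth > 0, tumour_alt_reads / tumour_depth, 0)
  }
  if (is.null(normal_vaf)) {
    normal_vaf <- ifelse(normal_depth > 0, normal_alt_reads / normal_depth, 0)
  }
  out <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    tumour_depth = as.numeric(tumour_depth),
    normal_depth = as.numeric(normal_depth),
    tumour_alt_reads = as.numeric(tumour_alt_reads),
    normal_alt_reads = as.numeric(normal_alt_reads),
    tumour_vaf = as.numeric(tumour_vaf),
    normal_vaf = as.numeric(normal_vaf),
    donor_id = as.character(donor_id),
    stringsAsFactors = FALSE
  )
  bad <- which(out$tumour_alt_reads > out$tumour_depth |
               out$normal_alt_reads > out$normal_depth)
  if (length(bad)) {
    stop("alt-read count exceeds depth at record(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(out$ref == out$alt)) stop("ref and alt alleles must differ")
  if (any(out$tumour_vaf < 0 | out$tumour_vaf > 1 |
          out$normal_vaf < 0 | out$normal_vaf > 1)) {
    stop("VAF values must lie in [0, 1]")
  }
  out
}

#' Apply the somatic filter to variant records
#'
#' A record passes iff all five criteria hold: tumour depth, normal depth and
#' tumour alt reads above their strict thresholds, tumour VAF above its strict
#' threshold, and normal VAF not exceeding `max_normal_vaf` (exact zero at the
#' default). For failing records the first failing criterion, in the fixed
#' order tumour_depth, normal_depth, tumour_alt, tumour_vaf, normal_vaf, is
#' reported for auditability.
#'
#' @param records Record table from [somatic_variants()] or
#'   [read_paired_vcf()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A `data.frame` with columns `pass` (logical) and `criterion`
#'   (first failing criterion, `NA` for passing records), one row per record.
#' @export
#' @examples
#' r <- somatic_variants("1", 100, "A", "T", 100, 50, 20, 0)
#' passes_somatic_filter(r)
passes_somatic_filter <- function(records, thresholds = filter_thresholds()) {
  th <- thresholds
  checks <- cbind(
    tumour_depth = records$tumour_depth > th$min_tumour_depth_excl,
    normal_depth = records$normal_depth > th$min_normal_depth_excl,
    tumour_alt   = records$tumour_alt_reads > th$min_tumour_alt_excl,
    tumour_vaf   = records$tumour_vaf > th$min_tumour_vaf_excl,
    normal_vaf   = records$normal_vaf <= th$max_normal_vaf
  )
  pass <- rowSums(checks) == ncol(checks)
  first_fail <- apply(checks, 1L, function(ok) {
    i <- which(!ok)
    if (length(i)) .filter_criteria[i[1L]] else NA_character_
  })
  data.frame(pass = pass, criterion = first_fail, stringsAsFactors = FALSE)
}

#' Read paired tumour-normal somatic calls from a VCF
#'
#' Ingests a VCF 4.x file with both named samples and per-sample allelic
#' depths (`AD`), decomposing multiallelic rows into one record per ALT
#' allele. Depth is the sum of the sample's allelic depths at the site; VAF is
#' recomputed as alt/(total AD). An explicitly provided per-sample `AF` field
#' is used only when `AD` is absent for that sample.
#'
#' @param path Path to a VCF file.
#' @param tumour_sample,normal_sample Sample column names in the VCF.
#' @param donor_id Donor identifier attached to every record; defaults to the
#'   tumour sample name.
#' @return A record `data.frame` as from [somatic_variants()], plus a
#'   `row_index` column giving the originating VCF data row.
#' @export
read_paired_vcf <- function(path, tumour_sample, normal_sample,
                            donor_id = tumour_sample) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  for (s in c(tumour_sample, normal_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not present in VCF (found: ",
           paste(samples, collapse = ", "), ")")
    }
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) matrix(NA_character_, n, length(samples),
                                            dimnames = list(NULL, samples)))

  parse_ad <- function(x, row, sample) {
    if (is.na(x) || x == ".") {
      stop("missing AD (allelic depth) field for sample '", sample,
           "' at VCF data row ", row)
    }
    as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]])
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    t_ad <- parse_ad(ad[i, tumour_sample], i, tumour_sample)
    n_ad <- parse_ad(ad[i, normal_sample], i, normal_sample)
    if (length(t_ad) != length(alts) + 1L || length(n_ad) != length(alts) + 1L) {
      stop("AD field length does not match 1 + number of ALT alleles at VCF data row ", i)
    }
    t_dp <- sum(t_ad); n_dp <- sum(n_ad)
    out[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]), alt = alts,
      tumour_depth = t_dp, normal_depth = n_dp,
      tumour_alt_reads = t_ad[-1L], normal_alt_reads = n_ad[-1L],
      tumour_vaf = if (t_dp > 0) t_ad[-1L] / t_dp else 0,
      normal_vaf = if (n_dp > 0) n_ad[-1L] / n_dp else 0,
      donor_id = donor_id, row_index = i,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- somatic_variants(character(), integer(), character(), character(),
                            numeric(), numeric(), numeric(), numeric())
    res$row_index <- integer()
  }
  res
}

#' Write records as a minimal paired tumour-normal VCF
#'
#' Emits a VCFv4.2 file with two sample columns carrying `GT:AD:DP`. Used by
#' the fixture generator and for filter output; one biallelic row per record.
#'
#' @param records Record table (see [somatic_variants()]).
#' @param path Output file path.
#' @param tumour_sample,normal_sample Sample column names to write.
#' @param extra_meta Character vector of additional `##` header lines.
#' @return `path`, invisibly.
#' @export
write_paired_vcf <- function(records, path,
                             tumour_sample = "TUMOUR", normal_sample = "NORMAL",
                             extra_meta = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    extra_meta,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", tumour_sample, normal_sample, sep = "\t")
  )
  fmt <- function(dp, alt, het) {
    ref_reads <- round(dp - alt)
    sprintf("%s:%d,%d:%d", if (het) "0/1" else "0/0",
            as.integer(ref_reads), as.integer(round(alt)), as.integer(round(dp)))
  }
  body <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    body[i] <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
                     "GT:AD:DP",
                     fmt(r$tumour_depth, r$tumour_alt_reads, r$tumour_alt_reads > 0),
                     fmt(r$normal_depth, r$normal_alt_reads, r$normal_alt_reads > 0),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter a paired VCF file and write the retained records
#'
#' Reads a paired tumour-normal VCF, applies [passes_somatic_filter()], and
#' writes (a) a VCF of rows with at least one passing ALT, records copied
#' verbatim under a header line naming this tool, and (b) a rejection audit
#' TSV (chrom, pos, ref, alt, failing criterion).
#'
#' @inheritParams read_paired_vcf
#' @param out_vcf,out_audit Output paths; either may be `NULL` to skip.
#' @param thresholds A [filter_thresholds()] object.
#' @return The record table with `pass`/`criterion` columns appended,
#'   invisibly.
#' @export
filter_vcf_file <- function(path, tumour_sample, normal_sample,
                            out_vcf = NULL, out_audit = NULL,
                            thresholds = filter_thresholds(),
                            donor_id = tumour_sample) {
  recs <- read_paired_vcf(path, tumour_sample, normal_sample, donor_id)
  verdict <- passes_somatic_filter(recs, thresholds)
  recs$pass <- verdict$pass
  recs$criterion <- verdict$criterion
  if (!is.null(out_vcf)) {
    lines <- readLines(path)
    is_meta <- startsWith(lines, "##")
    chrom_line <- which(startsWith(lines, "#CHROM"))[1L]
    data_lines <- lines[seq_along(lines) > chrom_line]
    keep_rows <- sort(unique(recs$row_index[recs$pass]))
    writeLines(c(lines[is_meta],
                 "##FILTER=<ID=neoscan_somatic,Description=\"Passed the neoscan tumour-normal somatic filter\">",
                 lines[chrom_line],
                 data_lines[keep_rows]),
               out_vcf)
  }
  if (!is.null(out_audit)) {
    rej <- recs[!recs$pass, c("chrom", "pos", "ref", "alt", "criterion")]
    write_neoscan_tsv(rej, out_audit)
  }
  invisible(recs)
}

#' Restrict filtered records to protein-altering consequences
#'
#' Keeps the records that both pass the somatic filter and have a
#' protein-altering consequence (missense or frameshift), preserving input
#' order. Synonymous and non-coding records are dropped even when they pass
#' the read-level filter.
#'
#' @param records Record table.
#' @param consequence_kinds Character vector, one consequence kind per record
#'   (values as in [apply_variant()]: "missense", "synonymous", "frameshift",
#'   "inframe_indel", "stop_gain", "non_coding"). `NA` marks a record absent
#'   from the annotation and is an error.
#' @param thresholds A [filter_thresholds()] object.
#' @param keep_kinds Consequence kinds considered protein-altering.
#' @return The retained subset of `records`.
#' @export
filter_to_coding <- function(records, consequence_kinds,
                             thresholds = filter_thresholds(),
                             keep_kinds = c("missense", "frameshift")) {
  if (length(consequence_kinds) != nrow(records)) {
    stop("consequence_kinds must have one entry per record")
  }
  if (anyNA(consequence_kinds)) {
    stop("missing consequence annotation for record(s): ",
         paste(which(is.na(consequence_kinds)), collapse = ", "))
  }
  keep <- passes_somatic_filter(records, thresholds)$pass &
    consequence_kinds %in% keep_kinds
  records[keep, , drop = FALSE]
}
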