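#' Cohort manifest
#'
#' @param donor_id Character vector of unique donor ids.
#' @param tumour_type Tumour type per donor (tissue of origin).
#' @param alleles List of character vectors (HLA alleles per donor), or a
#'   single character vector recycled to every donor.
#' @return A `data.frame` with a list-column `alleles`.
#' @export
cohort_manifest <- function(donor_id, tumour_type, alleles) {
  if (anyDuplicated(donor_id)) stop("donor ids must be unique")
  if (!is.list(alleles)) alleles <- rep(list(alleles), length(donor_id))
  stopifnot(length(tumour_type) == length(donor_id),
            length(alleles) == length(donor_id))
  out <- data.frame(donor_id = as.character(donor_id),
                    tumour_type = as.character(tumour_type),
                    stringsAsFactors = FALSE)
  out$alleles <- alleles
  out
}

#' Read/write a cohort manifest TSV
#'
#' Columns: donor_id, tumour_type, alleles (semicolon-separated).
#'
#' @param path File path.
#' @return For read: a manifest `data.frame`; for write: `path` invisibly.
#' @export
read_manifest <- function(path) {
  df <- read_neoscan_tsv(path)
  cohort_manifest(df$donor_id, df$tumour_type,
                  strsplit(df$alleles, ";", fixed = TRUE))
}

#' @rdname read_manifest
#' @param manifest A manifest `data.frame` from [cohort_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(donor_id = manifest$donor_id,
                   tumour_type = manifest$tumour_type,
                   alleles = vapply(manifest$alleles, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_neoscan_tsv(df, path)
}

#' Cohort recurrence of mutations
#'
#' Counts, for each mutation key (gene, chrom, pos, ref>alt, protein
#' change), the number of *distinct* donors carrying it — a donor reporting
#' the same mutation twice (e.g. on two transcripts) counts once. Rows are
#' sorted by count descending, ties broken lexicographically by (gene,
#' protein change).
#'
#' @param records A `data.frame` with columns `gene_symbol`, `chrom`, `pos`,
#'   `ref`, `alt`, `protein_change`, `donor_id`.
#' @param n_donors Cohort size (the denominator); must be at least the
#'   number of distinct donors observed.
#' @return A `data.frame` with the key columns plus `count`, `denominator`
#'   and a rendered `frequency` ("count out of N").
#' @export
mutation_frequency <- function(records, n_donors) {
  empty <- data.frame(gene_symbol = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      protein_change = character(), count = integer(),
                      denominator = integer(), frequency = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  if (n_donors < length(unique(records$donor_id))) {
    stop("n_donors smaller than the number of distinct donors observed")
  }
  key_cols <- c("gene_symbol", "chrom", "pos", "ref", "alt", "protein_change")
  dedup <- unique(records[, c(key_cols, "donor_id")])
  key <- do.call(paste, c(dedup[key_cols], sep = "\r"))
  counts <- table(key)
  first <- dedup[!duplicated(key), key_cols, drop = FALSE]
  first$count <- as.integer(counts[do.call(paste, c(first[key_cols], sep = "\r"))])
  ord <- order(-first$count, first$gene_symbol, first$protein_change)
  out <- first[ord, , drop = FALSE]
  out$denominator <- as.integer(n_donors)
  out$frequency <- sprintf("%d out of %d", out$count, out$denominator)
  rownames(out) <- NULL
  out
}

#' Neoantigen load per HLA allele
#'
#' Restricted to mutant binders (mutant binding class strong or weak);
#' reports per allele the total number of binder records and the mean per
#' donor carrying that allele. Records for alleles carried by no donor in
#' the manifest are excluded with a warning.
#'
#' @param bindings Binding-comparison table (needs `allele`, `mt_class`,
#'   `donor_id`).
#' @param manifest A [cohort_manifest()].
#' @param specific_only Count only mutant-specific records.
#' @return A `data.frame` with `allele`, `total`, `n_donors_with_allele`,
#'   `mean_per_donor`, plus attribute `overall_mean_per_donor` (average
#'   binder records per donor across the cohort).
#' @export
neoantigen_load_per_allele <- function(bindings, manifest,
                                       specific_only = FALSE) {
  b <- bindings[bindings$mt_class != "non_binding", , drop = FALSE]
  if (specific_only) b <- b[b$mutant_specific, , drop = FALSE]
  carriers <- table(unlist(lapply(seq_len(nrow(manifest)), function(i)
    unique(manifest$alleles[[i]]))))
  known <- names(carriers)
  orphan <- setdiff(unique(b$allele), known)
  if (length(orphan)) {
    warning("binding records for allele(s) carried by no donor, excluded: ",
            paste(orphan, collapse = ", "))
    b <- b[!b$allele %in% orphan, , drop = FALSE]
  }
  alleles <- sort(unique(c(known, b$allele)))
  tot <- table(factor(b$allele, levels = alleles))
  out <- data.frame(
    allele = alleles,
    total = as.integer(tot),
    n_donors_with_allele = as.integer(carriers[alleles]),
    stringsAsFactors = FALSE
  )
  out$mean_per_donor <- ifelse(out$n_donors_with_allele > 0,
                               out$total / out$n_donors_with_allele, 0)
  ord <- order(-out$total, out$allele)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overall_mean_per_donor") <-
    if (nrow(manifest)) nrow(b) / nrow(manifest) else 0
  out
}

# Lower-interpolation quantile convention (stats::quantile type 1), so
# integer fixtures give exact integer expected values.
.quart <- function(x, p) unname(stats::quantile(x, p, type = 1))

#' Neoantigen load per tumour type
#'
#' Summarises per-donor neoantigen counts within each tumour type: number of
#' donors, mean, and lower-interpolation median/quartiles. Donors with zero
#' neoantigens are included as zeros; by default a neoantigen is one
#' mutant-specific binder record (peptide x allele), `unit = "peptides"`
#' counts unique mutant peptides instead.
#'
#' @param bindings Binding-comparison table (needs `donor_id`, `mt_class`,
#'   `mutant_specific`, `mt_peptide`).
#' @param manifest A [cohort_manifest()] assigning every donor a type.
#' @param unit `"records"` or `"peptides"`.
#' @param specific_only Count only mutant-specific records (default TRUE).
#' @return A `data.frame` with `tumour_type`, `n_donors`, `mean`, `median`,
#'   `q1`, `q3`; attribute `per_donor` holds the underlying per-donor
#'   counts.
#' @export
neoantigen_load_per_type <- function(bindings, manifest,
                                     unit = c("records", "peptides"),
                                     specific_only = TRUE) {
  unit <- match.arg(unit)
  b <- bindings[bindings$mt_class != "non_binding", , drop = FALSE]
  if (specific_only) b <- b[b$mutant_specific, , drop = FALSE]
  unknown <- setdiff(unique(b$donor_id), manifest$donor_id)
  if (length(unknown)) {
    stop("donor(s) missing from manifest: ", paste(unknown, collapse = ", "))
  }
  per_donor <- vapply(manifest$donor_id, function(d) {
    bd <- b[b$donor_id == d, , drop = FALSE]
    if (unit == "records") nrow(bd) else length(unique(bd$mt_peptide))
  }, integer(1))
  types <- sort(unique(manifest$tumour_type))
  out <- do.call(rbind, lapply(types, function(tt) {
    x <- per_donor[manifest$tumour_type == tt]
    data.frame(tumour_type = tt, n_donors = length(x), mean = mean(x),
               median = .quart(x, 0.5), q1 = .quart(x, 0.25),
               q3 = .quart(x, 0.75), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_donor") <- data.frame(
    donor_id = manifest$donor_id, tumour_type = manifest$tumour_type,
    count = unname(per_donor), stringsAsFactors = FALSE)
  out
}
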