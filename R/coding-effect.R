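#' The standard genetic code as a codon lookup table
#'
#' Named character vector mapping the 64 codons to one-letter amino acids,
#' with `*` for the three stop codons (taken from the standard table shipped
#' with Biostrings).
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  stopifnot(length(gc) == 64L, sum(gc == "*") == 3L)
  gc
}

.revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a CDS, halting at the first stop codon
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`T`.
#' @param code Codon table from [genetic_code()].
#' @return The amino-acid string up to (not including) the first stop codon,
#'   with attributes `no_stop_found` (no stop before the end of `seq`) and
#'   `trailing_partial` (a partial trailing codon was ignored, also raised as
#'   a warning).
#' @export
#' @examples
#' translate_cds("ATGAAATAG")  # "MK"
translate_cds <- function(seq, code = genetic_code()) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside {A,C,G,T}")
  }
  n <- nchar(seq)
  partial <- n %% 3L != 0L
  if (partial) warning("trailing partial codon ignored")
  starts <- seq.int(1L, n - n %% 3L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    prot <- paste(aa[seq_len(stop_at[1L] - 1L)], collapse = "")
    no_stop <- FALSE
  } else {
    prot <- paste(aa, collapse = "")
    no_stop <- TRUE
  }
  structure(prot, no_stop_found = no_stop, trailing_partial = partial)
}

#' Project a genomic position onto transcript CDS coordinates
#'
#' Walks the CDS segments in translation order; on the `-` strand the CDS
#' coordinate counts from the genomically 3'-most base. Positions in introns,
#' UTRs or outside the transcript return `NA` ("outside").
#'
#' @param tx A [transcript_model()].
#' @param gpos 1-based genomic position on `tx$chrom`.
#' @return 1-based CDS coordinate, or `NA_integer_` when outside the CDS.
#' @export
project_genomic_to_cds <- function(tx, gpos) {
  off <- 0L
  for (i in seq_len(nrow(tx$cds_segments))) {
    s <- tx$cds_segments[i, "start"]; e <- tx$cds_segments[i, "end"]
    if (gpos >= s && gpos <= e) {
      return(unname(off + if (tx$strand == "+") gpos - s + 1L else e - gpos + 1L))
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

.non_coding <- function(tx, reason) {
  structure(list(
    kind = "non_coding", transcript_id = tx$transcript_id,
    gene_symbol = tx$gene_symbol, protein_id = tx$transcript_id,
    wt_residue = NA_character_, mt_residue = NA_character_,
    protein_pos = NA_integer_, wt_protein = NA_character_,
    mt_protein = NA_character_, novel_span = NULL,
    protein_change = NA_character_, no_stop_found = FALSE,
    note = reason
  ), class = "protein_consequence")
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][1:n]; bv <- strsplit(b, "")[[1L]][1:n]
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

.common_suffix_len <- function(a, b, max_len) {
  na <- nchar(a); nb <- nchar(b); n <- min(na, nb, max_len)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1L]])[1:n]; bv <- rev(strsplit(b, "")[[1L]])[1:n]
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

#' Apply one somatic variant to a transcript and call its protein consequence
#'
#' SNVs substitute a codon (reverse-complemented onto the sense strand for
#' `-` strand transcripts) and are classified synonymous, missense or
#' stop-gain. INDELs follow the VCF anchor-base convention (REF `AG`, ALT `A`
#' deletes the `G` at pos+1): length not divisible by 3 yields a frameshift
#' whose mutant protein is the re-translated shifted frame continuing into
#' the downstream UTR sequence until a stop; length divisible by 3 yields an
#' in-frame indel. The full mutant protein is always materialised.
#'
#' Start-loss, stop-loss and indels crossing a CDS boundary are unsupported
#' and returned as `non_coding` with a warning; a frameshift that exhausts
#' the available sequence without reaching a stop is flagged
#' `no_stop_found`.
#'
#' @param tx A [transcript_model()].
#' @param pos 1-based genomic position of the variant (VCF POS).
#' @param ref,alt VCF alleles on the forward genomic strand.
#' @param code Codon table from [genetic_code()].
#' @return An object of class `protein_consequence` with fields `kind`
#'   (`"synonymous"`, `"missense"`, `"stop_gain"`, `"frameshift"`,
#'   `"inframe_indel"` or `"non_coding"`), `protein_pos`, `wt_residue`,
#'   `mt_residue`, full `wt_protein` and `mt_protein`, `novel_span`
#'   (first/last 1-based mutant residues absent from the wild type, for
#'   indels) and a `protein_change` label such as `"G12V"`.
#' @export
apply_variant <- function(tx, pos, ref, alt, code = genetic_code()) {
  wt_protein <- translate_cds(tx$cds_sequence, code)
  n_ref <- nchar(ref); n_alt <- nchar(alt)
  cds <- tx$cds_sequence

  if (n_ref == 1L && n_alt == 1L) {
    cpos <- project_genomic_to_cds(tx, pos)
    if (is.na(cpos)) return(.non_coding(tx, "outside_cds"))
    sense_ref <- if (tx$strand == "+") ref else .revcomp(ref)
    sense_alt <- if (tx$strand == "+") alt else .revcomp(alt)
    if (substr(cds, cpos, cpos) != sense_ref) {
      stop("reference allele mismatch at CDS position ", cpos,
           " of transcript ", tx$transcript_id)
    }
    new_cds <- cds
    substr(new_cds, cpos, cpos) <- sense_alt
    codon_i <- as.integer(ceiling(cpos / 3))
    codon_start <- (codon_i - 1L) * 3L + 1L
    wt_aa <- unname(code[substr(cds, codon_start, codon_start + 2L)])
    mt_aa <- unname(code[substr(new_cds, codon_start, codon_start + 2L)])
    if (wt_aa == mt_aa) {
      kind <- "synonymous"; mt_protein <- wt_protein
      change <- paste0(if (wt_aa == "*") "*" else wt_aa, codon_i, "=")
    } else if (wt_aa == "*") {
      warning("stop-loss variant unsupported on transcript ", tx$transcript_id)
      return(.non_coding(tx, "stop_loss"))
    } else if (codon_i == 1L) {
      warning("start-loss variant unsupported on transcript ", tx$transcript_id)
      return(.non_coding(tx, "start_loss"))
    } else if (mt_aa == "*") {
      kind <- "stop_gain"
      mt_protein <- substr(wt_protein, 1L, codon_i - 1L)
      change <- paste0(wt_aa, codon_i, "*")
    } else {
      kind <- "missense"
      mt_protein <- wt_protein
      substr(mt_protein, codon_i, codon_i) <- mt_aa
      change <- paste0(wt_aa, codon_i, mt_aa)
    }
    return(structure(list(
      kind = kind, transcript_id = tx$transcript_id,
      gene_symbol = tx$gene_symbol, protein_id = tx$transcript_id,
      wt_residue = if (kind == "missense") wt_aa else NA_character_,
      mt_residue = if (kind == "missense") mt_aa else NA_character_,
      protein_pos = codon_i,
      wt_protein = as.character(wt_protein),
      mt_protein = as.character(mt_protein),
      novel_span = NULL, protein_change = change, no_stop_found = FALSE,
      note = NA_character_
    ), class = "protein_consequence"))
  }

  # INDEL, anchor-base convention
  if (substr(ref, 1, 1) != substr(alt, 1, 1) || (n_ref > 1L && n_alt > 1L)) {
    warning("complex substitution unsupported on transcript ", tx$transcript_id)
    return(.non_coding(tx, "complex_substitution"))
  }

  if (n_ref > n_alt) {             # deletion of ref[2..] at pos+1 .. pos+nd
    nd <- n_ref - 1L
    del_gpos <- pos + seq_len(nd)
    cp <- vapply(del_gpos, function(g) project_genomic_to_cds(tx, g), integer(1))
    if (anyNA(cp)) {
      warning("indel outside or crossing CDS boundary on transcript ",
              tx$transcript_id)
      return(.non_coding(tx, "indel_crosses_cds_boundary"))
    }
    lo <- min(cp); hi <- max(cp)
    if (hi - lo + 1L != nd) {
      warning("indel spans an intron on transcript ", tx$transcript_id)
      return(.non_coding(tx, "indel_spans_intron"))
    }
    del_sense <- if (tx$strand == "+") substr(ref, 2L, n_ref) else
      .revcomp(substr(ref, 2L, n_ref))
    if (substr(cds, lo, hi) != del_sense) {
      stop("reference allele mismatch for deletion at CDS ", lo, "-", hi,
           " of transcript ", tx$transcript_id)
    }
    new_cds <- paste0(substr(cds, 1L, lo - 1L), substr(cds, hi + 1L, nchar(cds)))
    indel_len <- nd
  } else {                         # insertion of alt[2..] after pos
    ins <- substr(alt, 2L, n_alt)
    cpos <- project_genomic_to_cds(tx, pos)
    if (is.na(cpos)) return(.non_coding(tx, "outside_cds"))
    if (tx$strand == "+") {
      after <- cpos; ins_sense <- ins
    } else {
      after <- cpos - 1L; ins_sense <- .revcomp(ins)
    }
    new_cds <- paste0(substr(cds, 1L, after), ins_sense,
                      substr(cds, after + 1L, nchar(cds)))
    indel_len <- n_alt - 1L
  }

  mt_trans <- translate_cds(
    paste0(new_cds, tx$downstream_utr_sequence), code)
  mt_protein <- as.character(mt_trans)
  no_stop <- isTRUE(attr(mt_trans, "no_stop_found"))
  wt <- as.character(wt_protein)

  if (identical(mt_protein, wt)) {
    return(structure(list(
      kind = "synonymous", transcript_id = tx$transcript_id,
      gene_symbol = tx$gene_symbol, protein_id = tx$transcript_id,
      wt_residue = NA_character_, mt_residue = NA_character_,
      protein_pos = NA_integer_, wt_protein = wt, mt_protein = mt_protein,
      novel_span = NULL, protein_change = NA_character_,
      no_stop_found = FALSE, note = "indel_without_protein_change"
    ), class = "protein_consequence"))
  }

  frameshift <- indel_len %% 3L != 0L
  p <- .common_prefix_len(wt, mt_protein)
  if (frameshift) {
    s <- 0L
  } else {
    s <- .common_suffix_len(wt, mt_protein, min(nchar(wt), nchar(mt_protein)) - p)
  }
  first <- min(p + 1L, nchar(mt_protein))
  last <- max(first, nchar(mt_protein) - s)
  anchor_aa <- if (p < nchar(wt)) substr(wt, p + 1L, p + 1L) else
    substr(mt_protein, first, first)
  kind <- if (frameshift) "frameshift" else "inframe_indel"
  structure(list(
    kind = kind, transcript_id = tx$transcript_id,
    gene_symbol = tx$gene_symbol, protein_id = tx$transcript_id,
    wt_residue = NA_character_, mt_residue = NA_character_,
    protein_pos = p + 1L, wt_protein = wt, mt_protein = mt_protein,
    novel_span = c(first, last),
    protein_change = paste0(anchor_aa, p + 1L, if (frameshift) "fs" else "indel"),
    no_stop_found = no_stop, note = NA_character_
  ), class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s %s on %s (%s)\n", x$kind,
              ifelse(is.na(x$protein_change), "", x$protein_change),
              x$protein_id, x$gene_symbol))
  invisible(x)
}

#' Annotate variant records against a transcript set
#'
#' Applies every record to every transcript on the same chromosome whose CDS
#' contains the variant anchor position, reporting one consequence per
#' (record, overlapping transcript); isoform selection is left to
#' aggregation.
#'
#' @param records Record table (see [somatic_variants()]).
#' @param transcripts Named list of [transcript_model()] objects.
#' @param code Codon table.
#' @return A `data.frame` with one row per (record, transcript) consequence;
#'   records hitting no transcript get a single `non_coding` row with
#'   `transcript_id = NA`. The full consequence objects are attached as the
#'   `consequence` attribute (a list parallel to the rows).
#' @export
annotate_records <- function(records, transcripts, code = genetic_code()) {
  rows <- list(); objs <- list(); k <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    hit <- FALSE
    for (tx in transcripts) {
      if (tx$chrom != r$chrom) next
      anchor <- project_genomic_to_cds(tx, r$pos)
      # indel bases start at pos+1; an anchor just upstream still overlaps
      if (is.na(anchor) && nchar(r$ref) > 1L) {
        anchor <- project_genomic_to_cds(tx, r$pos + 1L)
      }
      if (is.na(anchor)) next
      hit <- TRUE
      cons <- apply_variant(tx, r$pos, r$ref, r$alt, code)
      k <- k + 1L
      objs[[k]] <- cons
      rows[[k]] <- data.frame(
        record_index = i, donor_id = r$donor_id, chrom = r$chrom,
        pos = r$pos, ref = r$ref, alt = r$alt,
        transcript_id = tx$transcript_id, gene_symbol = tx$gene_symbol,
        kind = cons$kind, protein_change = cons$protein_change,
        protein_pos = cons$protein_pos, stringsAsFactors = FALSE
      )
    }
    if (!hit) {
      k <- k + 1L
      objs[[k]] <- NULL
      rows[[k]] <- data.frame(
        record_index = i, donor_id = r$donor_id, chrom = r$chrom,
        pos = r$pos, ref = r$ref, alt = r$alt,
        transcript_id = NA_character_, gene_symbol = NA_character_,
        kind = "non_coding", protein_change = NA_character_,
        protein_pos = NA_integer_, stringsAsFactors = FALSE
      )
      objs[[k]] <- list(kind = "non_coding")
    }
  }
  df <- if (k) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(record_index = integer(), donor_id = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), transcript_id = character(),
               gene_symbol = character(), kind = character(),
               protein_change = character(), protein_pos = integer(),
               stringsAsFactors = FALSE)
  attr(df, "consequence") <- objs
  df
}
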