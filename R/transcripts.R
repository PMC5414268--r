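#' Construct a transcript model
#'
#' A minimal transcript representation sufficient for coding-consequence
#' calling: the ordered CDS segments in genomic coordinates, the spliced CDS
#' sequence on the mRNA sense strand, and the downstream (3' UTR) sense-strand
#' sequence used when a frameshift reads through the stop codon.
#'
#' @param transcript_id,gene_symbol Identifiers.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_segments Two-column matrix (start, end), 1-based inclusive
#'   genomic coordinates, rows in translation order (for `-` strand the first
#'   row is the genomically 3'-most segment).
#' @param cds_sequence Spliced CDS on the sense strand: starts `ATG`, ends in
#'   a stop codon, length divisible by 3 and equal to the summed segment
#'   lengths.
#' @param downstream_utr_sequence Sense-strand sequence 3' of the stop codon
#'   (may be empty).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand,
                             cds_segments, cds_sequence,
                             downstream_utr_sequence = "") {
  stopifnot(strand %in% c("+", "-"))
  cds_segments <- matrix(as.integer(cds_segments), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  if (any(cds_segments[, "start"] > cds_segments[, "end"])) {
    stop("segment start must not exceed end")
  }
  seg_len <- sum(cds_segments[, "end"] - cds_segments[, "start"] + 1L)
  if (seg_len != nchar(cds_sequence)) {
    stop("total segment length (", seg_len, ") != CDS length (",
         nchar(cds_sequence), ")")
  }
  if (nchar(cds_sequence) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (substr(cds_sequence, 1, 3) != "ATG") stop("CDS must begin with ATG")
  last_codon <- substr(cds_sequence, nchar(cds_sequence) - 2, nchar(cds_sequence))
  if (!last_codon %in% c("TAA", "TAG", "TGA")) stop("CDS must end with a stop codon")
  structure(list(
    transcript_id = transcript_id, gene_symbol = gene_symbol,
    chrom = chrom, strand = strand, cds_segments = cds_segments,
    cds_sequence = cds_sequence,
    downstream_utr_sequence = downstream_utr_sequence
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand, CDS %d nt in %d segment(s), UTR3 %d nt\n",
              x$transcript_id, x$gene_symbol, x$chrom, x$strand,
              nchar(x$cds_sequence), nrow(x$cds_segments),
              nchar(x$downstream_utr_sequence)))
  invisible(x)
}

#' Write transcript models as a flat table plus CDS FASTA
#'
#' The transcript table is a TSV (transcript_id, gene_symbol, chrom, strand,
#' segments as `start-end;start-end` in translation order); sequences go to a
#' FASTA with one `<id>` entry per CDS and an optional `<id>.utr3` entry for
#' the downstream sequence.
#'
#' @param transcripts A list of [transcript_model()] objects.
#' @param tsv_path,fasta_path Output paths.
#' @return `tsv_path`, invisibly.
#' @export
write_transcripts <- function(transcripts, tsv_path, fasta_path) {
  df <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    gene_symbol = vapply(transcripts, `[[`, "", "gene_symbol"),
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    strand = vapply(transcripts, `[[`, "", "strand"),
    segments = vapply(transcripts, function(tx) {
      paste(sprintf("%d-%d", tx$cds_segments[, "start"], tx$cds_segments[, "end"]),
            collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
  write_neoscan_tsv(df, tsv_path)
  seqs <- character()
  for (tx in transcripts) {
    seqs[tx$transcript_id] <- tx$cds_sequence
    if (nzchar(tx$downstream_utr_sequence)) {
      seqs[paste0(tx$transcript_id, ".utr3")] <- tx$downstream_utr_sequence
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  invisible(tsv_path)
}

#' Read transcript models written by [write_transcripts()]
#'
#' @param tsv_path,fasta_path Input paths.
#' @return A named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(tsv_path, fasta_path) {
  df <- read_neoscan_tsv(tsv_path)
  fa <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- setNames(as.character(fa), names(fa))
  out <- vector("list", nrow(df))
  names(out) <- df$transcript_id
  for (i in seq_len(nrow(df))) {
    segs <- do.call(rbind, lapply(
      strsplit(df$segments[i], ";", fixed = TRUE)[[1L]],
      function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
    ))
    id <- df$transcript_id[i]
    if (!id %in% names(seqs)) stop("no CDS sequence in FASTA for transcript ", id)
    utr <- seqs[paste0(id, ".utr3")]
    out[[i]] <- transcript_model(
      id, df$gene_symbol[i], df$chrom[i], df$strand[i], segs,
      unname(seqs[id]),
      if (is.na(utr)) "" else unname(utr)
    )
  }
  out
}
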