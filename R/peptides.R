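#' Peptide window parameters
#'
#' Defaults follow class I presentation: a 21-residue mutation context (10
#' residues either side of the mutated site) and candidate peptides of 8-11
#' residues.
#'
#' @param flank Residues kept upstream and downstream of the mutation.
#' @param kmin,kmax Candidate peptide length range (inclusive).
#' @return An object of class `window_params`.
#' @export
window_params <- function(flank = 10L, kmin = 8L, kmax = 11L) {
  flank <- as.integer(flank); kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  stopifnot(flank > 0L, kmin > 0L, kmin <= kmax, kmax <= 2L * flank + 1L)
  structure(list(flank = flank, kmin = kmin, kmax = kmax),
            class = "window_params")
}

#' Extract the mutation context from a protein consequence
#'
#' For a missense variant the context is the window `[pos - flank,
#' pos + flank]` on the mutant protein, clipped (never padded) at the protein
#' termini, with the matching window of the wild-type protein as reference;
#' an interior site therefore yields a 21-mer with the mutation at index 11.
#' For frameshifts (and in-frame indels) the context runs from `flank`
#' residues before the first novel residue through the mutant C-terminus and
#' has no wild-type reference.
#'
#' @param consequence A `protein_consequence` from [apply_variant()] with
#'   kind missense, frameshift or inframe_indel.
#' @param params A [window_params()].
#' @return A list with elements `mt` and `wt` (the latter `NULL` for
#'   indels), each a list with `protein_id`, `sequence`, `mut_index`
#'   (scalar for missense, length-2 span for indels) and `protein_offset`
#'   (position in the full protein of the first context residue).
#' @export
extract_context <- function(consequence, params = window_params()) {
  kind <- consequence$kind
  if (!kind %in% c("missense", "frameshift", "inframe_indel")) {
    stop("no peptide context for consequence kind '", kind, "'")
  }
  fl <- params$flank
  if (kind == "missense") {
    pos <- consequence$protein_pos
    len <- nchar(consequence$mt_protein)
    from <- max(1L, pos - fl); to <- min(len, pos + fl)
    mt <- list(protein_id = consequence$protein_id,
               sequence = substr(consequence$mt_protein, from, to),
               mut_index = pos - from + 1L, protein_offset = from)
    wt <- mt
    wt$sequence <- substr(consequence$wt_protein, from, to)
    return(list(mt = mt, wt = wt))
  }
  span <- consequence$novel_span
  len <- nchar(consequence$mt_protein)
  from <- max(1L, span[1L] - fl)
  mt <- list(protein_id = consequence$protein_id,
             sequence = substr(consequence$mt_protein, from, len),
             mut_index = c(span[1L] - from + 1L, span[2L] - from + 1L),
             protein_offset = from)
  list(mt = mt, wt = NULL)
}

#' Enumerate all candidate peptides overlapping the mutated site
#'
#' Emits exactly the substrings of the context with length in
#' `[kmin, kmax]` whose span covers the mutated index (or intersects the
#' mutated span), in (length ascending, offset ascending) order. For a full
#' 21-mer missense context at the defaults this is 8 + 9 + 10 + 11 = 38
#' candidates.
#'
#' @param context The `mt` element of [extract_context()] output.
#' @param params A [window_params()].
#' @return A `data.frame` with columns `sequence`, `length`, `offset`
#'   (1-based start within the context).
#' @export
enumerate_candidates <- function(context, params = window_params()) {
  L <- nchar(context$sequence)
  span <- context$mut_index
  if (length(span) == 1L) span <- c(span, span)
  empty <- data.frame(sequence = character(), length = integer(),
                      offset = integer(), stringsAsFactors = FALSE)
  if (L < params$kmin) {
    warning("context shorter than kmin; no candidates")
    return(empty)
  }
  rows <- list()
  for (k in params$kmin:params$kmax) {
    if (k > L) next
    for (o in seq_len(L - k + 1L)) {
      if (o <= span[2L] && o + k - 1L >= span[1L]) {
        rows[[length(rows) + 1L]] <-
          data.frame(sequence = substr(context$sequence, o, o + k - 1L),
                     length = k, offset = o, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pair mutant candidate peptides with their wild-type references
#'
#' For missense contexts the wild-type peptide is the same offset/length
#' window of the wild-type context; for frameshift/indel contexts there is
#' no wild-type counterpart and `wt_peptide` is `NA`. Duplicate mutant
#' peptide strings at different offsets are all kept; deduplication happens
#' at prediction time.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param wt_context The `wt` element of [extract_context()] output, or
#'   `NULL`.
#' @return A `data.frame` of peptide pairs: `mt_peptide`, `wt_peptide`,
#'   `length`, `offset`, `contains_mut` (always `TRUE`).
#' @export
pair_with_wildtype <- function(candidates, wt_context = NULL) {
  wt <- rep(NA_character_, nrow(candidates))
  if (!is.null(wt_context)) {
    wt <- substr(rep(wt_context$sequence, nrow(candidates)),
                 candidates$offset, candidates$offset + candidates$length - 1L)
    if (any(wt == candidates$sequence)) {
      stop("mutant and wild-type windows identical; inconsistent annotation")
    }
  }
  data.frame(mt_peptide = candidates$sequence, wt_peptide = wt,
             length = candidates$length, offset = candidates$offset,
             contains_mut = TRUE, stringsAsFactors = FALSE)
}

#' Peptide pairs for a list of consequences
#'
#' Convenience wrapper running [extract_context()], [enumerate_candidates()]
#' and [pair_with_wildtype()] over protein-altering consequences; others are
#' skipped.
#'
#' @param consequences List of `protein_consequence` objects.
#' @param meta Optional `data.frame` with one row per consequence (donor,
#'   gene, ...), columns copied onto the output rows.
#' @param params A [window_params()].
#' @return A `data.frame` of peptide pairs with `protein_id`,
#'   `protein_change` and any `meta` columns attached.
#' @export
peptides_for_consequences <- function(consequences, meta = NULL,
                                      params = window_params()) {
  out <- list()
  for (i in seq_along(consequences)) {
    cons <- consequences[[i]]
    if (!cons$kind %in% c("missense", "frameshift", "inframe_indel")) next
    ctx <- extract_context(cons, params)
    cand <- suppressWarnings(enumerate_candidates(ctx$mt, params))
    if (!nrow(cand)) next
    pairs <- pair_with_wildtype(cand, ctx$wt)
    pairs$protein_id <- cons$protein_id
    pairs$gene_symbol <- cons$gene_symbol
    pairs$protein_change <- cons$protein_change
    pairs$kind <- cons$kind
    if (!is.null(meta)) {
      for (cn in names(meta)) pairs[[cn]] <- meta[[cn]][i]
    }
    out[[length(out) + 1L]] <- pairs
  }
  if (!length(out)) {
    return(data.frame(mt_peptide = character(), wt_peptide = character(),
                      length = integer(), offset = integer(),
                      contains_mut = logical(), protein_id = character(),
                      gene_symbol = character(), protein_change = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
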