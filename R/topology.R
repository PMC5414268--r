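#' Parse transmembrane topology predictions (TMHMM v2.0 long format)
#'
#' Long-format lines are `<id>\tTMHMM2.0\t<inside|outside|TMhelix>\t<start>
#' \t<end>`; `#`-prefixed header lines carry `Length:`. Segments of each
#' protein must tile `[1, length]` contiguously.
#'
#' @param text Path to a file, or a character vector of lines.
#' @return Named list of topologies; each has `protein_id`, `length` and a
#'   `segments` data.frame (`region`, `start`, `end`).
#' @export
parse_tmhmm_long <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  regions <- c("inside", "outside", "TMhelix")
  lengths <- list(); segs <- list()
  for (i in seq_along(text)) {
    line <- text[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*(\\S+)\\s+Length:\\s*([0-9]+)", line))[[1L]]
      if (length(m) == 3L) lengths[[m[2L]]] <- as.integer(m[3L])
      next
    }
    tok <- strsplit(line, "[\t ]+")[[1L]]
    if (length(tok) != 5L) {
      stop("malformed topology line ", i, ": expected 5 fields")
    }
    if (!tok[3L] %in% regions) {
      stop("unknown region label '", tok[3L], "' at line ", i)
    }
    id <- tok[1L]
    segs[[id]] <- rbind(segs[[id]], data.frame(
      region = tok[3L], start = as.integer(tok[4L]), end = as.integer(tok[5L]),
      stringsAsFactors = FALSE))
  }
  out <- vector("list", length(segs)); names(out) <- names(segs)
  for (id in names(segs)) {
    s <- segs[[id]][order(segs[[id]]$start), , drop = FALSE]
    rownames(s) <- NULL
    if (s$start[1L] != 1L) {
      stop("topology of ", id, " does not start at residue 1")
    }
    if (nrow(s) > 1L) {
      gaps <- which(s$start[-1L] != s$end[-nrow(s)] + 1L)
      if (length(gaps)) {
        stop("gap or overlap in topology of ", id, " between residues ",
             s$end[gaps[1L]], " and ", s$start[gaps[1L] + 1L])
      }
    }
    len <- if (!is.null(lengths[[id]])) lengths[[id]] else s$end[nrow(s)]
    if (s$end[nrow(s)] != len) {
      stop("topology of ", id, " ends at ", s$end[nrow(s)],
           " but protein length is ", len)
    }
    out[[id]] <- structure(list(protein_id = id, length = len, segments = s),
                           class = "protein_topology")
  }
  out
}

#' Write topologies back to the TMHMM v2.0 long format
#'
#' @param topologies List of topologies from [parse_tmhmm_long()].
#' @param path Output path, or `NULL` to return the lines.
#' @return The lines (invisibly when `path` is given).
#' @export
write_tmhmm_long <- function(topologies, path = NULL) {
  lines <- character()
  for (tp in topologies) {
    lines <- c(lines,
               sprintf("# %s Length: %d", tp$protein_id, tp$length),
               sprintf("%s\tTMHMM2.0\t%s\t%d\t%d", tp$protein_id,
                       tp$segments$region, tp$segments$start, tp$segments$end))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Region of a topology at one residue position
#'
#' @param topology A topology from [parse_tmhmm_long()].
#' @param pos 1-based residue index.
#' @return `"inside"`, `"outside"` or `"TMhelix"`.
#' @export
region_at <- function(topology, pos) {
  if (pos < 1L || pos > topology$length) {
    stop("position ", pos, " outside protein of length ", topology$length)
  }
  s <- topology$segments
  s$region[pos >= s$start & pos <= s$end][1L]
}

#' Default amino-acid polarity classification
#'
#' Four classes: nonpolar, polar uncharged, acidic, basic; all 20 standard
#' residues mapped exactly once. The table is configuration and can be
#' overridden in [polarity_change()].
#'
#' @return Named character vector (residue -> class).
#' @export
polarity_table <- function() {
  c(A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
    P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
    G = "nonpolar",
    S = "polar_uncharged", T = "polar_uncharged", C = "polar_uncharged",
    Y = "polar_uncharged", N = "polar_uncharged", Q = "polar_uncharged",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic")
}

#' Does a substitution change amino-acid polarity class?
#'
#' @param wt,mt Single-letter residues (vectorised).
#' @param table Polarity classification, as from [polarity_table()].
#' @return Logical vector.
#' @export
#' @examples
#' polarity_change("H", "Q")  # TRUE: basic -> polar uncharged
polarity_change <- function(wt, mt, table = polarity_table()) {
  if (any(!wt %in% names(table)) || any(!mt %in% names(table))) {
    stop("nonstandard residue in polarity lookup")
  }
  unname(table[wt] != table[mt])
}

#' Map missense mutations to extracellular regions of membrane proteins
#'
#' Emits one record per missense consequence whose protein is a listed
#' membrane protein and whose mutated residue lies in an `outside`
#' (extracellular) topology segment; a polarity-change flag is annotated,
#' never used as a filter.
#'
#' @param consequence_df Annotation table from [annotate_records()] (needs
#'   `kind`, `protein_id`/`transcript_id`, `protein_pos`, `gene_symbol`,
#'   `protein_change`, `donor_id`).
#' @param topologies Named list of topologies covering the membrane proteins.
#' @param membrane_ids Character vector of membrane protein ids.
#' @param table Polarity table.
#' @return A `data.frame` of extracellular mutation records: `gene_symbol`,
#'   `protein_id`, `protein_change`, `donor_id`, `region` (always
#'   `"outside"`), `polarity_changed`.
#' @export
map_extracellular_mutations <- function(consequence_df, topologies,
                                        membrane_ids,
                                        table = polarity_table()) {
  df <- consequence_df
  df$protein_id <- if ("protein_id" %in% names(df)) df$protein_id else df$transcript_id
  cand <- df[df$kind == "missense" & df$protein_id %in% membrane_ids, ,
             drop = FALSE]
  missing <- setdiff(unique(cand$protein_id), names(topologies))
  if (length(missing)) {
    stop("membrane protein(s) lacking topology: ",
         paste(missing, collapse = ", "))
  }
  empty <- data.frame(gene_symbol = character(), protein_id = character(),
                      protein_change = character(), donor_id = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      region = character(), polarity_changed = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    reg <- region_at(topologies[[r$protein_id]], r$protein_pos)
    if (reg != "outside") next
    wt <- substr(r$protein_change, 1L, 1L)
    mt <- substr(r$protein_change, nchar(r$protein_change),
                 nchar(r$protein_change))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_symbol = r$gene_symbol, protein_id = r$protein_id,
      protein_change = r$protein_change, donor_id = r$donor_id,
      chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      region = reg, polarity_changed = polarity_change(wt, mt, table),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
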