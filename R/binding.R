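#' The default 16-allele HLA class I panel
#'
#' The class I alleles with population frequency above 5% in the 1000
#' Genomes reference panel: five HLA-A, four HLA-B and seven HLA-C alleles.
#'
#' @return Character vector of 16 allele names in standard nomenclature.
#' @export
default_allele_panel <- function() {
  c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01", "HLA-A*24:02",
    "HLA-B*07:02", "HLA-B*35:01", "HLA-B*40:01", "HLA-B*51:01",
    "HLA-C*01:02", "HLA-C*03:03", "HLA-C*03:04", "HLA-C*04:01",
    "HLA-C*06:02", "HLA-C*07:01", "HLA-C*07:02")
}

#' Validate HLA class I allele names
#'
#' @param alleles Character vector, e.g. `"HLA-A*02:01"`.
#' @return `alleles`, invisibly; error on malformed names.
#' @export
check_hla_alleles <- function(alleles) {
  ok <- grepl("^HLA-[ABC]\\*[0-9]{2,}:[0-9]{2,}$", alleles)
  if (!all(ok)) {
    stop("malformed HLA allele name(s): ", paste(alleles[!ok], collapse = ", "))
  }
  invisible(alleles)
}

#' Convert between standard and NetMHCpan allele spellings
#'
#' NetMHCpan drops the `*` separator (`HLA-A02:01`); the mapping is
#' bidirectional and lossless for class I names.
#'
#' @param alleles Character vector of allele names.
#' @param to `"netmhcpan"` or `"standard"`.
#' @return Converted character vector.
#' @export
hla_dialect <- function(alleles, to = c("netmhcpan", "standard")) {
  to <- match.arg(to)
  if (to == "netmhcpan") gsub("*", "", alleles, fixed = TRUE)
  else sub("^HLA-([ABC])", "HLA-\\1*", alleles)
}

#' IC50 binding-class thresholds
#'
#' Strong binding below 150 nM, weak binding between 150 and 500 nM
#' (closed interval, so the three classes tile the positive axis), and
#' non-binding above 500 nM.
#'
#' @param strong_max_excl Exclusive upper IC50 bound (nM) of the strong class.
#' @param binder_max_incl Inclusive upper IC50 bound (nM) of the weak class.
#' @return An object of class `binding_thresholds`.
#' @export
binding_thresholds <- function(strong_max_excl = 150, binder_max_incl = 500) {
  stopifnot(strong_max_excl > 0, strong_max_excl < binder_max_incl)
  structure(list(strong_max_excl = strong_max_excl,
                 binder_max_incl = binder_max_incl),
            class = "binding_thresholds")
}

#' Classify an IC50 affinity into strong / weak / non-binding
#'
#' @param ic50_nm Positive IC50 values in nM (vectorised).
#' @param thresholds A [binding_thresholds()] object.
#' @return Character vector over `"strong"`, `"weak"`, `"non_binding"`.
#' @export
#' @examples
#' classify_affinity(c(100, 350, 8000))
classify_affinity <- function(ic50_nm, thresholds = binding_thresholds()) {
  if (any(!is.finite(ic50_nm)) || any(ic50_nm <= 0)) {
    stop("IC50 values must be positive and finite")
  }
  ifelse(ic50_nm < thresholds$strong_max_excl, "strong",
         ifelse(ic50_nm <= thresholds$binder_max_incl, "weak", "non_binding"))
}

# Pinned anchors of the toy backend: literature peptide-allele pairs with
# published IC50s, so pipeline tests exercise known binding classes.
.toy_anchors <- function() {
  data.frame(
    peptide = c("GMNWRPILTII", "GMNRRPILTII",
                "KLVVVGADGV", "KLVVVGAVGV", "KLVVVGAV", "TEYKLVVVGAV",
                "GAVGVGKSAL", "GAVGVGKSAL",
                "ARHGGWTTKM", "ARHGGWTTKM", "ARHGGWTTKM", "STRDPLSEITK"),
    allele = c("HLA-A*02:01", "HLA-A*02:01",
               "HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01", "HLA-B*40:01",
               "HLA-C*03:04", "HLA-C*03:03",
               "HLA-C*07:02", "HLA-C*06:02", "HLA-C*07:01", "HLA-A*11:01"),
    ic50_nm = c(350, 8000, 214, 112, 163, 90, 172, 172, 218, 457, 249, 81),
    stringsAsFactors = FALSE
  )
}

#' Deterministic toy affinity backend
#'
#' A pure function of (peptide, allele) producing IC50 values in
#' `[1, 50000]` nM via a documented integer string hash, so the whole
#' pipeline runs offline and reproducibly. A pinned anchor table forces
#' selected literature peptides into their published affinities (e.g. the
#' TP53 R248W mutant 11-mer `GMNWRPILTII` to 350 nM on HLA-A*02:01, its
#' wild-type counterpart to a non-binding 8000 nM).
#'
#' @param peptide Amino-acid string of length 8-11.
#' @param allele HLA allele name in standard nomenclature.
#' @return IC50 in nM (scalar).
#' @export
toy_backend <- function(peptide, allele) {
  anchors <- .toy_anchors()
  hit <- anchors$peptide == peptide & anchors$allele == allele
  if (any(hit)) return(anchors$ic50_nm[which(hit)[1L]])
  1 + .neoscan_hash(paste(peptide, allele, sep = "|")) %% 50000
}

#' Predict binding affinities for peptide pairs across alleles
#'
#' Calls the backend once per unique (peptide, allele) pair — duplicates
#' reuse the cached value — and classifies each IC50. Peptides outside the
#' supported 8-11 length range are skipped with a warning.
#'
#' @param pairs Peptide-pair table from [pair_with_wildtype()] /
#'   [peptides_for_consequences()].
#' @param alleles Character vector of HLA alleles.
#' @param backend A function `(peptide, allele) -> IC50 nM`; defaults to
#'   [toy_backend()].
#' @param thresholds A [binding_thresholds()] object.
#' @param backend_id Label recorded on each prediction.
#' @return A `data.frame` of predictions: `peptide`, `allele`, `ic50_nm`,
#'   `binding_class`, `backend_id`, one row per unique (peptide, allele).
#' @export
predict_affinities <- function(pairs, alleles, backend = toy_backend,
                               thresholds = binding_thresholds(),
                               backend_id = "toy") {
  check_hla_alleles(alleles)
  peps <- unique(c(pairs$mt_peptide, pairs$wt_peptide))
  peps <- peps[!is.na(peps)]
  bad <- nchar(peps) < 8L | nchar(peps) > 11L
  if (any(bad)) {
    warning("skipping ", sum(bad), " peptide(s) with unsupported length")
    peps <- peps[!bad]
  }
  grid <- expand.grid(peptide = peps, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!nrow(grid)) {
    return(data.frame(peptide = character(), allele = character(),
                      ic50_nm = numeric(), binding_class = character(),
                      backend_id = character(), stringsAsFactors = FALSE))
  }
  ic50 <- mapply(function(p, a) {
    v <- backend(p, a)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("affinity backend returned an invalid value for (", p, ", ", a, ")")
    }
    v
  }, grid$peptide, grid$allele, USE.NAMES = FALSE)
  data.frame(peptide = grid$peptide, allele = grid$allele, ic50_nm = ic50,
             binding_class = classify_affinity(ic50, thresholds),
             backend_id = backend_id, stringsAsFactors = FALSE)
}

#' Parse NetMHCpan v2.8 tabular output
#'
#' Data lines carry (position, allele, peptide, identity, 1-log50k score,
#' affinity in nM, percentile rank, ...); header, comment and separator
#' lines are skipped. Affinities are classified with the default thresholds.
#'
#' @param text Character vector of output lines, or a single string with
#'   embedded newlines.
#' @param thresholds A [binding_thresholds()] object.
#' @return A prediction `data.frame` as from [predict_affinities()] with
#'   `backend_id = "netmhcpan-2.8"`.
#' @export
parse_netmhcpan_output <- function(text, thresholds = binding_thresholds()) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  rows <- list()
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, "-")) next
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (tok[1L] %in% c("pos", "Pos", "Protein", "Number")) next
    if (!grepl("^[0-9]+$", tok[1L])) next
    if (length(tok) < 6L) {
      stop("malformed NetMHCpan output at line ", i, ": too few columns")
    }
    aff <- suppressWarnings(as.numeric(tok[6L]))
    if (is.na(aff)) {
      stop("malformed NetMHCpan output at line ", i,
           ": non-numeric affinity '", tok[6L], "'")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = tok[3L], allele = hla_dialect(tok[2L], "standard"),
      ic50_nm = aff, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), allele = character(),
                      ic50_nm = numeric(), binding_class = character(),
                      backend_id = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  df$binding_class <- classify_affinity(df$ic50_nm, thresholds)
  df$backend_id <- "netmhcpan-2.8"
  df
}

#' Compare wild-type and mutant binding for one peptide pair on one allele
#'
#' A mutant peptide is called mutant-specific when it binds (strong or weak)
#' while its wild-type counterpart does not bind or does not exist
#' (frameshift peptides). All mutant binders are retained regardless of
#' specificity; the flag distinguishes them.
#'
#' @param mt Prediction row (list or single-row data.frame) for the mutant
#'   peptide.
#' @param wt Prediction for the wild-type peptide, or `NULL` when no
#'   wild-type counterpart exists.
#' @return A list with `mt`, `wt` and logical `mutant_specific`.
#' @export
compare_wt_mt <- function(mt, wt = NULL) {
  if (!is.null(wt)) {
    if (wt$allele != mt$allele) {
      stop("wild-type and mutant predictions are for different alleles")
    }
    if (nchar(wt$peptide) != nchar(mt$peptide)) {
      stop("wild-type and mutant peptides differ in length")
    }
  }
  specific <- mt$binding_class != "non_binding" &&
    (is.null(wt) || wt$binding_class == "non_binding")
  list(mt = mt, wt = wt, mutant_specific = specific)
}

#' Binding comparison table for all peptide pairs and alleles
#'
#' Joins per-(peptide, allele) predictions back onto the peptide pairs and
#' applies the mutant-specificity rule of [compare_wt_mt()] row-wise.
#'
#' @param pairs Peptide-pair table (may carry donor/gene annotation columns).
#' @param predictions Prediction table from [predict_affinities()].
#' @param alleles Alleles to evaluate per pair.
#' @return A `data.frame` with one row per (pair, allele): pair annotation
#'   columns plus `allele`, `mt_ic50`, `wt_ic50`, `mt_class`, `wt_class`,
#'   `mutant_specific`.
#' @export
compare_bindings <- function(pairs, predictions, alleles) {
  key <- paste(predictions$peptide, predictions$allele, sep = "\r")
  ic <- setNames(predictions$ic50_nm, key)
  cl <- setNames(predictions$binding_class, key)
  out <- list()
  for (a in alleles) {
    block <- pairs
    block$allele <- a
    mk <- paste(pairs$mt_peptide, a, sep = "\r")
    wk <- paste(pairs$wt_peptide, a, sep = "\r")
    block$mt_ic50 <- unname(ic[mk])
    block$mt_class <- unname(cl[mk])
    block$wt_ic50 <- ifelse(is.na(pairs$wt_peptide), NA_real_, unname(ic[wk]))
    block$wt_class <- ifelse(is.na(pairs$wt_peptide), NA_character_, unname(cl[wk]))
    out[[length(out) + 1L]] <- block
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[!is.na(res$mt_class), , drop = FALSE]   # length-skipped peptides
  res$mutant_specific <- res$mt_class != "non_binding" &
    (is.na(res$wt_class) | res$wt_class == "non_binding")
  res
}
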