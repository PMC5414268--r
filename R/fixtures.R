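#' Specification of a synthetic fixture cohort
#'
#' Defines the toy cohort the generator emits: per donor, four passing
#' missense variants (one shared across all donors and lying in an
#' extracellular segment of a membrane protein), one synonymous and one
#' frameshift variant; the first donor additionally carries five variants
#' each violating exactly one somatic-filter criterion, plus missense sites
#' near the N-terminus, at the C-terminus and inside a transmembrane helix.
#' Each donor is typed with six class I alleles (two per locus) drawn from
#' the default 16-allele panel. All randomness is fixed by `seed`.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_donors Number of donors (>= 1).
#' @param n_transcripts Number of toy transcripts (>= 4).
#' @param n_interior_missense Passing missense variants per donor.
#' @param n_synonymous,n_frameshift Per-donor counts of those kinds.
#' @param membrane_fraction Fraction of transcripts that are membrane
#'   proteins with a generated topology.
#' @param alleles_per_donor HLA alleles typed per donor (2 per locus when 6).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_donors = 5L, n_transcripts = 8L,
                         n_interior_missense = 4L, n_synonymous = 1L,
                         n_frameshift = 1L, membrane_fraction = 0.5,
                         alleles_per_donor = 6L) {
  stopifnot(n_donors >= 1L, n_transcripts >= 4L, n_interior_missense >= 1L,
            n_synonymous >= 0L, n_frameshift >= 0L,
            membrane_fraction > 0, membrane_fraction <= 1)
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 n_transcripts = as.integer(n_transcripts),
                 n_interior_missense = as.integer(n_interior_missense),
                 n_synonymous = as.integer(n_synonymous),
                 n_frameshift = as.integer(n_frameshift),
                 membrane_fraction = membrane_fraction,
                 alleles_per_donor = as.integer(alleles_per_donor)),
            class = "fixture_spec")
}

# Random CDS of n_codons sense codons: ATG, interior non-stop codons, stop.
.random_cds <- function(n_codons, code) {
  non_stop <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  paste0("ATG",
         paste(sample(non_stop, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

# Candidate-window count for a context of length L with mutated span (s1,s2).
.window_count <- function(L, s1, s2, kmin = 8L, kmax = 11L) {
  total <- 0L
  for (k in kmin:kmax) {
    if (k > L) next
    lo <- max(1L, s1 - k + 1L)
    hi <- min(s2, L - k + 1L)
    if (hi >= lo) total <- total + (hi - lo + 1L)
  }
  total
}

# Missense candidate-window count on a protein of length len mutated at pos.
.missense_window_count <- function(len, pos, flank = 10L) {
  from <- max(1L, pos - flank); to <- min(len, pos + flank)
  .window_count(to - from + 1L, pos - from + 1L, pos - from + 1L)
}

# Find an SNV at protein position p of tx giving the wanted kind
# ("missense"/"synonymous"); returns list(gpos, ref, alt) or NULL.
.plant_snv <- function(tx, p, want, code) {
  genome_base <- function(cpos) {
    # genomic position and forward-strand base for a CDS coordinate
    seg <- tx$cds_segments[1L, ]
    if (tx$strand == "+") {
      g <- seg["start"] + cpos - 1L
      b <- substr(tx$cds_sequence, cpos, cpos)
    } else {
      g <- seg["end"] - cpos + 1L
      b <- .revcomp(substr(tx$cds_sequence, cpos, cpos))
    }
    list(gpos = unname(g), base = b)
  }
  for (off in 3:1) {             # third base first: favours synonymous hits
    cpos <- (p - 1L) * 3L + off
    sense_ref <- substr(tx$cds_sequence, cpos, cpos)
    for (alt_sense in setdiff(c("A", "C", "G", "T"), sense_ref)) {
      codon_start <- (p - 1L) * 3L + 1L
      codon <- substr(tx$cds_sequence, codon_start, codon_start + 2L)
      mt_codon <- codon
      substr(mt_codon, off, off) <- alt_sense
      wt_aa <- unname(code[codon]); mt_aa <- unname(code[mt_codon])
      kind <- if (wt_aa == mt_aa) "synonymous"
              else if (mt_aa == "*") "stop_gain" else "missense"
      if (kind != want) next
      gb <- genome_base(cpos)
      alt_fwd <- if (tx$strand == "+") alt_sense else .revcomp(alt_sense)
      return(list(gpos = gb$gpos, ref = gb$base, alt = alt_fwd))
    }
  }
  NULL
}

# 1-bp frameshift deletion inside codon p of tx (anchor-base convention).
.plant_deletion <- function(tx, p) {
  cpos <- (p - 1L) * 3L + 2L     # delete the middle base of codon p
  seg <- tx$cds_segments[1L, ]
  if (tx$strand == "+") {
    gd <- unname(seg["start"] + cpos - 1L)
    anchor <- substr(tx$cds_sequence, cpos - 1L, cpos - 1L)
    delbase <- substr(tx$cds_sequence, cpos, cpos)
    list(gpos = gd - 1L, ref = paste0(anchor, delbase), alt = anchor)
  } else {
    gd <- unname(seg["end"] - cpos + 1L)
    # forward-strand bases at gd-1 and gd
    fwd <- function(g) .revcomp(substr(tx$cds_sequence, seg["end"] - g + 1L,
                                       seg["end"] - g + 1L))
    list(gpos = gd - 1L, ref = paste0(fwd(gd - 1L), fwd(gd)), alt = fwd(gd - 1L))
  }
}

#' Generate a synthetic fixture cohort on disk
#'
#' Writes everything the pipeline consumes — transcript table + CDS FASTA,
#' one paired tumour-normal VCF per donor, a TMHMM-long topology file, a
#' membrane-protein id list, a cohort manifest — plus an expected-count
#' ledger derived from the planted ground truth (records written, records
#' passing the somatic filter, protein-altering passing records, candidate
#' peptide rows, binding rows, extracellular records). Counts in the ledger
#' come from the construction (closed-form window arithmetic on the planted
#' sites), so a pipeline run over the files provides an independent
#' re-count.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the expected-count
#'   ledger (`data.frame` stage/count).
#' @export
generate_fixture_cohort <- function(spec = fixture_spec(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)
  code <- genetic_code()

  # --- transcripts -------------------------------------------------------
  n_tx <- spec$n_transcripts
  prot_len <- sample(45:75, n_tx, replace = TRUE)
  strands <- rep(c("+", "-"), length.out = n_tx)
  utr_tail <- "TTAATTAATTAA"       # stop codons in all three frames
  txs <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    cds <- .random_cds(prot_len[i] + 2L, code)   # protein + start-adjust + stop
    utr <- paste0(paste(sample(c("A", "C", "G", "T"), 40L, replace = TRUE),
                        collapse = ""), utr_tail)
    id <- sprintf("TX%02d", i)
    txs[[i]] <- transcript_model(
      id, sprintf("GENE%02d", i), sprintf("chr%d", i), strands[i],
      matrix(c(1001L, 1000L + nchar(cds)), ncol = 2), cds, utr)
  }
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  prot_len <- vapply(txs, function(tx) nchar(translate_cds(tx$cds_sequence, code)),
                     integer(1))

  # --- membrane proteins and topologies ---------------------------------
  n_mem <- max(1L, ceiling(spec$membrane_fraction * n_tx))
  mem_ids <- names(txs)[seq_len(n_mem)]
  topologies <- list()
  for (id in mem_ids) {
    L <- prot_len[[id]]
    o_end <- max(25L, floor(L * 0.5))        # generous extracellular head
    t_end <- min(L - 5L, o_end + 15L)
    topologies[[id]] <- structure(list(
      protein_id = id, length = L,
      segments = data.frame(
        region = c("outside", "TMhelix", "inside"),
        start = c(1L, o_end + 1L, t_end + 1L),
        end = c(o_end, t_end, L), stringsAsFactors = FALSE)),
      class = "protein_topology")
  }

  # --- planted variants --------------------------------------------------
  used <- character()      # "tx:protein_pos" reservations
  reserve <- function(id, p) {
    key <- paste(id, p, sep = ":")
    if (key %in% used) return(FALSE)
    used <<- c(used, key); TRUE
  }
  pass_depths <- function() {
    td <- sample(80:200, 1L); ta <- round(td * stats::runif(1, 0.15, 0.40))
    list(td = td, ta = ta, nd = sample(30:60, 1L), na = 0L)
  }

  # shared extracellular missense on the first membrane transcript
  sh_tx <- txs[[mem_ids[1L]]]
  sh_pos <- 15L                      # inside the outside segment, interior
  stopifnot(reserve(sh_tx$transcript_id, sh_pos))
  shared <- .plant_snv(sh_tx, sh_pos, "missense", code)
  stopifnot(!is.null(shared))

  tm_tx <- sh_tx                     # TMhelix missense for donor 1
  tm_pos <- topologies[[sh_tx$transcript_id]]$segments$start[2L] + 2L
  stopifnot(reserve(tm_tx$transcript_id, tm_pos))

  records <- list(); ledger_pep <- 0L
  add_rec <- function(donor, tx, plant, depths) {
    records[[length(records) + 1L]] <<- data.frame(
      donor_id = donor, chrom = tx$chrom, pos = plant$gpos,
      ref = plant$ref, alt = plant$alt,
      tumour_depth = depths$td, tumour_alt_reads = depths$ta,
      normal_depth = depths$nd, normal_alt_reads = depths$na,
      stringsAsFactors = FALSE)
  }

  donors <- sprintf("D%03d", seq_len(spec$n_donors))
  n_pass <- 0L; n_coding <- 0L; n_extra <- 0L; n_records <- 0L
  pep_per_donor <- setNames(integer(spec$n_donors), donors)

  count_extracellular <- function(tx_id, p) {
    tx_id %in% mem_ids &&
      region_at(topologies[[tx_id]], p) == "outside"
  }

  for (d in seq_along(donors)) {
    donor <- donors[d]
    miss_sites <- list(list(tx = sh_tx$transcript_id, p = sh_pos,
                            plant = shared))
    if (d == 1L) {
      # near-N-terminal, C-terminal and TM-helix missense
      nt_tx <- txs[[n_mem + 1L]]
      ct_tx <- txs[[min(n_tx, n_mem + 2L)]]
      specials <- list(list(tx = nt_tx, p = 2L),
                       list(tx = ct_tx, p = prot_len[[ct_tx$transcript_id]]),
                       list(tx = tm_tx, p = tm_pos))
      for (sp in specials) {
        if (!reserve(sp$tx$transcript_id, sp$p) &&
            !identical(sp$tx$transcript_id, tm_tx$transcript_id)) next
        pl <- .plant_snv(sp$tx, sp$p, "missense", code)
        if (is.null(pl)) {   # fall back one residue inward
          sp$p <- max(2L, sp$p - 1L); reserve(sp$tx$transcript_id, sp$p)
          pl <- .plant_snv(sp$tx, sp$p, "missense", code)
        }
        miss_sites[[length(miss_sites) + 1L]] <-
          list(tx = sp$tx$transcript_id, p = sp$p, plant = pl)
      }
    } else {
      needed <- spec$n_interior_missense - 1L
      tries <- 0L
      while (needed > 0L && tries < 500L) {
        tries <- tries + 1L
        ti <- sample(n_tx, 1L); tx <- txs[[ti]]
        p <- sample(12:(prot_len[[ti]] - 11L), 1L)
        if (!reserve(tx$transcript_id, p)) next
        pl <- .plant_snv(tx, p, "missense", code)
        if (is.null(pl)) next
        miss_sites[[length(miss_sites) + 1L]] <-
          list(tx = tx$transcript_id, p = p, plant = pl)
        needed <- needed - 1L
      }
    }

    for (ms in miss_sites) {
      add_rec(donor, txs[[ms$tx]], ms$plant, pass_depths())
      n_records <- n_records + 1L; n_pass <- n_pass + 1L
      n_coding <- n_coding + 1L
      pep_per_donor[donor] <- pep_per_donor[donor] +
        .missense_window_count(prot_len[[ms$tx]], ms$p)
      if (count_extracellular(ms$tx, ms$p)) n_extra <- n_extra + 1L
    }

    # synonymous (passes the read filter, dropped at the coding step)
    syn_done <- 0L; tries <- 0L
    while (syn_done < spec$n_synonymous && tries < 500L) {
      tries <- tries + 1L
      ti <- sample(n_tx, 1L); tx <- txs[[ti]]
      p <- sample(5:(prot_len[[ti]] - 4L), 1L)
      if (!reserve(tx$transcript_id, p)) next
      pl <- .plant_snv(tx, p, "synonymous", code)
      if (is.null(pl)) next
      add_rec(donor, tx, pl, pass_depths())
      n_records <- n_records + 1L; n_pass <- n_pass + 1L
      syn_done <- syn_done + 1L
    }

    # frameshift deletion
    fs_done <- 0L; tries <- 0L
    while (fs_done < spec$n_frameshift && tries < 500L) {
      tries <- tries + 1L
      ti <- sample(n_tx, 1L); tx <- txs[[ti]]
      p <- sample(10:(prot_len[[ti]] - 8L), 1L)
      if (!reserve(tx$transcript_id, p)) next
      pl <- .plant_deletion(tx, p)
      cons <- apply_variant(tx, pl$gpos, pl$ref, pl$alt, code)
      if (cons$kind != "frameshift" || cons$no_stop_found) next
      add_rec(donor, tx, pl, pass_depths())
      n_records <- n_records + 1L; n_pass <- n_pass + 1L
      n_coding <- n_coding + 1L
      ctx_from <- max(1L, cons$novel_span[1L] - 10L)
      Lc <- nchar(cons$mt_protein) - ctx_from + 1L
      pep_per_donor[donor] <- pep_per_donor[donor] +
        .window_count(Lc, cons$novel_span[1L] - ctx_from + 1L, Lc)
      fs_done <- fs_done + 1L
    }

    if (d == 1L) {
      # one record violating each filter criterion in isolation
      fails <- list(
        list(td = 10L,  ta = 6L,  nd = 50L, na = 0L),  # tumour depth at bound
        list(td = 100L, ta = 20L, nd = 6L,  na = 0L),  # normal depth at bound
        list(td = 50L,  ta = 5L,  nd = 50L, na = 0L),  # alt reads at bound
        list(td = 200L, ta = 10L, nd = 50L, na = 0L),  # tumour VAF at bound
        list(td = 100L, ta = 20L, nd = 50L, na = 2L)   # contaminated normal
      )
      for (fl in fails) {
        ti <- sample(n_tx, 1L); tx <- txs[[ti]]
        p <- NULL
        repeat {
          p <- sample(12:(prot_len[[ti]] - 11L), 1L)
          if (reserve(tx$transcript_id, p)) break
        }
        pl <- .plant_snv(tx, p, "missense", code)
        if (is.null(pl)) next
        add_rec(donor, tx, pl, fl)
        n_records <- n_records + 1L
      }
    }
  }

  all_records <- do.call(rbind, c(records, list(make.row.names = FALSE)))

  # --- per-donor alleles and manifest -----------------------------------
  panel <- default_allele_panel()
  by_locus <- split(panel, substr(panel, 5L, 5L))
  alleles <- lapply(seq_len(spec$n_donors), function(i) {
    if (spec$alleles_per_donor == 6L) {
      sort(c(sample(by_locus$A, 2L), sample(by_locus$B, 2L),
             sample(by_locus$C, 2L)))
    } else {
      sort(sample(panel, spec$alleles_per_donor))
    }
  })
  tumour_types <- rep(c("lung", "skin", "colorectal"),
                      length.out = spec$n_donors)
  manifest <- cohort_manifest(donors, tumour_types, alleles)

  n_bindings <- sum(pep_per_donor * spec$alleles_per_donor)

  # --- write everything --------------------------------------------------
  paths <- list(
    transcripts_tsv = file.path(outdir, "transcripts.tsv"),
    cds_fasta = file.path(outdir, "cds.fasta"),
    tmhmm = file.path(outdir, "topology.tmhmm"),
    membrane_list = file.path(outdir, "membrane_ids.txt"),
    manifest = file.path(outdir, "manifest.tsv"),
    vcf_dir = file.path(outdir, "vcf"),
    ledger = file.path(outdir, "expected_counts.tsv")
  )
  dir.create(paths$vcf_dir, showWarnings = FALSE)
  write_transcripts(txs, paths$transcripts_tsv, paths$cds_fasta)
  write_tmhmm_long(topologies, paths$tmhmm)
  writeLines(mem_ids, paths$membrane_list)
  write_manifest(manifest, paths$manifest)
  for (donor in donors) {
    dr <- all_records[all_records$donor_id == donor, , drop = FALSE]
    dr <- dr[order(dr$chrom, dr$pos), , drop = FALSE]
    recs <- somatic_variants(dr$chrom, dr$pos, dr$ref, dr$alt,
                             dr$tumour_depth, dr$normal_depth,
                             dr$tumour_alt_reads, dr$normal_alt_reads,
                             donor_id = donor)
    write_paired_vcf(recs, file.path(paths$vcf_dir, paste0(donor, ".vcf")))
  }
  ledger <- data.frame(
    stage = c("records", "pass_filter", "coding", "peptides", "bindings",
              "extracellular"),
    count = c(n_records, n_pass, n_coding, sum(pep_per_donor), n_bindings,
              n_extra),
    stringsAsFactors = FALSE)
  write_neoscan_tsv(ledger, paths$ledger)
  invisible(list(paths = paths, ledger = ledger,
                 peptides_per_donor = pep_per_donor))
}
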