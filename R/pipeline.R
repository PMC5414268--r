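#' Pipeline configuration
#'
#' Collects every input path and tunable of the prediction pipeline. The
#' allele panel is `"manifest"` (each donor's typed alleles, the default),
#' `"default16"` (the fixed 16-allele panel for every donor) or an explicit
#' character vector.
#'
#' @param vcf_dir Directory holding one paired VCF per donor, named
#'   `<donor_id>.vcf`.
#' @param transcripts_tsv,cds_fasta Transcript model files
#'   (see [write_transcripts()]).
#' @param tmhmm Topology file, TMHMM v2.0 long format.
#' @param membrane_list Membrane protein id list, one id per line.
#' @param manifest Cohort manifest TSV (see [read_manifest()]).
#' @param out_dir Output directory.
#' @param tumour_sample,normal_sample Sample column names in the VCFs.
#' @param filter A [filter_thresholds()] object.
#' @param windows A [window_params()] object.
#' @param binding A [binding_thresholds()] object.
#' @param backend `"toy"` or a backend function `(peptide, allele) -> nM`.
#' @param allele_panel `"manifest"`, `"default16"` or a character vector.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf_dir, transcripts_tsv, cds_fasta, tmhmm,
                            membrane_list, manifest, out_dir,
                            tumour_sample = "TUMOUR",
                            normal_sample = "NORMAL",
                            filter = filter_thresholds(),
                            windows = window_params(),
                            binding = binding_thresholds(),
                            backend = "toy",
                            allele_panel = "manifest") {
  structure(list(
    vcf_dir = vcf_dir, transcripts_tsv = transcripts_tsv,
    cds_fasta = cds_fasta, tmhmm = tmhmm, membrane_list = membrane_list,
    manifest = manifest, out_dir = out_dir,
    tumour_sample = tumour_sample, normal_sample = normal_sample,
    filter = filter, windows = windows, binding = binding,
    backend = backend, allele_panel = allele_panel
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML schema mirrors [pipeline_config()]; threshold blocks are nested
#' maps. A written configuration reloads to an equal value (round-trip).
#'
#' @param path YAML file path.
#' @return For read: a `pipeline_config`; for write: `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    vcf_dir = y$vcf_dir, transcripts_tsv = y$transcripts_tsv,
    cds_fasta = y$cds_fasta, tmhmm = y$tmhmm,
    membrane_list = y$membrane_list, manifest = y$manifest,
    out_dir = y$out_dir,
    tumour_sample = y$tumour_sample %||% "TUMOUR",
    normal_sample = y$normal_sample %||% "NORMAL",
    filter = do.call(filter_thresholds, y$filter %||% list()),
    windows = do.call(window_params, y$windows %||% list()),
    binding = do.call(binding_thresholds, y$binding %||% list()),
    backend = y$backend %||% "toy",
    allele_panel = unlist(y$allele_panel %||% "manifest")
  )
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` (function backends cannot be
#'   serialised; the name `"toy"` is written instead).
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$filter <- unclass(y$filter)
  y$windows <- unclass(y$windows)
  y$binding <- unclass(y$binding)
  if (is.function(y$backend)) y$backend <- "toy"
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Severity order for picking one consequence kind per variant record when a
# record overlaps several transcripts.
.kind_priority <- c(frameshift = 1, missense = 2, inframe_indel = 3,
                    stop_gain = 4, synonymous = 5, non_coding = 6)

#' Run the neoantigen prediction pipeline over a cohort
#'
#' For every donor in the manifest: read the paired VCF, annotate coding
#' consequences against the transcript set, apply the somatic filter,
#' enumerate mutant/wild-type candidate peptides, predict and compare HLA
#' binding, and map passing missense mutations to extracellular membrane
#' regions. Cohort tables (mutation recurrence, per-allele and
#' per-tumour-type neoantigen load) are computed at the end. All outputs are
#' TSVs with a `#` header line, written atomically; a run log records the
#' package version, a config hash and per-stage record counts. With the toy
#' backend a re-run over identical inputs is byte-identical.
#'
#' @param config A [pipeline_config()] or path to its YAML form.
#' @return Invisibly, a list of the stage tables plus `counts` (named
#'   per-stage totals) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config

  inputs <- c(cfg$vcf_dir, cfg$transcripts_tsv, cfg$cds_fasta, cfg$tmhmm,
              cfg$membrane_list, cfg$manifest)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "filtered_vcf"), showWarnings = FALSE)

  manifest <- read_manifest(cfg$manifest)
  transcripts <- read_transcripts(cfg$transcripts_tsv, cfg$cds_fasta)
  topologies <- parse_tmhmm_long(cfg$tmhmm)
  membrane_ids <- readLines(cfg$membrane_list)
  backend <- if (is.function(cfg$backend)) cfg$backend else toy_backend
  backend_id <- if (is.function(cfg$backend)) "custom" else cfg$backend

  log_lines <- c(
    sprintf("tool: neoscan %s", as.character(utils::packageVersion("neoscan"))),
    sprintf("config_hash: %d",
            .neoscan_hash(paste(utils::capture.output(utils::str(unclass(cfg))),
                                collapse = "\n"))))
  stage_log <- function(stage, donor, n_in, n_out) {
    log_lines <<- c(log_lines, sprintf("stage=%s donor=%s in=%d out=%d",
                                       stage, donor, n_in, n_out))
  }

  all_records <- list(); all_cons <- list(); all_peps <- list()
  all_bind <- list(); all_extra <- list()

  for (i in seq_len(nrow(manifest))) {
    donor <- manifest$donor_id[i]
    vcf_path <- file.path(cfg$vcf_dir, paste0(donor, ".vcf"))
    if (!file.exists(vcf_path)) stop("no VCF for donor ", donor)

    recs <- filter_vcf_file(
      vcf_path, cfg$tumour_sample, cfg$normal_sample,
      out_vcf = file.path(cfg$out_dir, "filtered_vcf", paste0(donor, ".vcf")),
      out_audit = file.path(cfg$out_dir, "filtered_vcf",
                            paste0(donor, ".rejected.tsv")),
      thresholds = cfg$filter, donor_id = donor)
    stage_log("somatic_filter", donor, nrow(recs), sum(recs$pass))

    ann <- annotate_records(recs, transcripts)
    objs <- attr(ann, "consequence")
    ann$pass <- recs$pass[ann$record_index]
    keep <- ann$pass & ann$kind %in% c("missense", "frameshift")
    cons_df <- ann[keep, , drop = FALSE]
    stage_log("coding_consequence", donor, nrow(ann), nrow(cons_df))

    keep_idx <- which(keep)
    peps <- peptides_for_consequences(
      objs[keep_idx],
      meta = ann[keep_idx, c("donor_id", "chrom", "pos", "ref", "alt"),
                 drop = FALSE],
      params = cfg$windows)
    stage_log("peptide_windows", donor, nrow(cons_df), nrow(peps))

    alleles <- if (identical(cfg$allele_panel, "manifest")) {
      manifest$alleles[[i]]
    } else if (identical(cfg$allele_panel, "default16")) {
      default_allele_panel()
    } else cfg$allele_panel
    if (nrow(peps)) {
      preds <- predict_affinities(peps, alleles, backend, cfg$binding,
                                  backend_id)
      bind <- compare_bindings(peps, preds, alleles)
    } else {
      bind <- compare_bindings(peps, predict_affinities(peps, alleles,
                                                        backend, cfg$binding,
                                                        backend_id), alleles)
    }
    stage_log("mhc_binding", donor, nrow(peps), nrow(bind))

    extra <- map_extracellular_mutations(cons_df, topologies, membrane_ids)
    stage_log("extracellular", donor, nrow(cons_df), nrow(extra))

    all_records[[donor]] <- recs
    all_cons[[donor]] <- cons_df
    all_peps[[donor]] <- peps
    all_bind[[donor]] <- bind
    all_extra[[donor]] <- extra
  }

  rbind_all <- function(lst) do.call(rbind, c(unname(lst),
                                              list(make.row.names = FALSE)))
  cons_df <- rbind_all(all_cons)
  peps_df <- rbind_all(all_peps)
  bind_df <- rbind_all(all_bind)
  extra_df <- rbind_all(all_extra)

  freq <- mutation_frequency(cons_df, n_donors = nrow(manifest))
  load_allele <- neoantigen_load_per_allele(bind_df, manifest)
  load_type <- neoantigen_load_per_type(bind_df, manifest)

  outs <- list(
    consequences = cons_df[, setdiff(names(cons_df), "pass")],
    peptides = peps_df, bindings = bind_df, extracellular = extra_df,
    frequency = freq, load_per_allele = load_allele,
    load_per_type = load_type)
  for (nm in names(outs)) {
    write_neoscan_tsv(outs[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  counts <- c(records = sum(vapply(all_records, nrow, 0L)),
              pass_filter = sum(vapply(all_records,
                                       function(x) sum(x$pass), 0L)),
              coding = nrow(cons_df), peptides = nrow(peps_df),
              bindings = nrow(bind_df), extracellular = nrow(extra_df))
  invisible(c(outs, list(counts = counts, out_dir = cfg$out_dir,
                         manifest = manifest)))
}
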