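## pipeline: staged orchestration with provenance and seed fan-out ---------

pipeline_default_config <- function() {
  list(
    seed = 1L,
    out_dir = "tribescope_out",
    simulate = list(),             # sim_config() overrides
    call = list(min_phred = 31L, min_alt_reads = 2L,
                conditions = c("agoTRIBE", "ADARonly")),
    rank = list(K_top = 1000L, K_bg = 1000L),
    compare = list(universe = NULL)
  )
}

merge_config <- function(user, defaults) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]]) &&
                         k %in% c("simulate", "call", "rank", "compare")) {
      d <- defaults[[k]]
      d[names(user[[k]])] <- user[[k]]
      d
    } else user[[k]]
  }
  defaults
}

write_provenance <- function(out_dir, stage, config, seed, inputs = list()) {
  prov <- list(
    tool = "tribescope",
    version = as.character(utils::packageVersion("tribescope")),
    stage = stage, seed = seed,
    config = config,
    input_checksums = lapply(inputs, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  )
  jsonlite::write_json(prov,
                       file.path(out_dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the editing-to-targets pipeline end to end
#'
#' Orchestrates the stages `simulate` (synthetic reference, annotation,
#' databases and per-condition alignments), `call` (pileup, mismatch
#' calling, database exclusion, editing events per condition), `rank`
#' (per-UTR aggregation and residual ranking) and `compare` (recovered
#' targets against the planted truth). Each stage writes TSV outputs plus
#' a provenance JSON (tool version, config, stage seed, input checksums)
#' into `out_dir`; a single global seed fans out to per-stage seeds by
#' stable hashing of stage names, so rerunning with an identical config
#' reproduces identical outputs.
#'
#' @param config Named list (or YAML/JSON file path) overriding
#'   the defaults: top-level `seed`, `out_dir`, and per-stage blocks
#'   `simulate` (any [sim_config()] argument), `call` (`min_phred`,
#'   `min_alt_reads`, `conditions`), `rank` (`K_top`, `K_bg`), `compare`
#'   (`universe`). Unknown keys are rejected.
#' @param stages Ordered subset of
#'   `c("simulate", "call", "rank", "compare")`; an empty vector is a
#'   no-op. Later stages require the outputs of earlier ones (from this or
#'   a previous run in the same `out_dir`).
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "call", "rank", "compare")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(config, pipeline_default_config())
  known <- c("simulate", "call", "rank", "compare")
  if (length(stages) && any(!stages %in% known))
    stopf("unknown stage(s): %s",
          paste(setdiff(stages, known), collapse = ", "))
  if (!length(stages)) return(invisible(list()))
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "effective_config.yaml"))
  results <- list()

  path <- function(...) file.path(out_dir, ...)
  require_file <- function(p, needed_by, produced_by) {
    if (!file.exists(p))
      stopf("stage '%s' requires '%s'; run stage '%s' first", needed_by,
            p, produced_by)
  }

  if ("simulate" %in% stages) {
    sc_args <- cfg$simulate
    sc_args$seed <- stage_seed(cfg$seed, "simulate")
    scfg <- do.call(sim_config, sc_args)
    sim <- gen_reference_and_annotation(scfg)
    write_reference(sim$reference, path("reference.fa"))
    write_annotation(sim$annotation, path("annotation.bed"),
                     path("biotypes.tsv"))
    write_site_vcf(sim$truth$snp_sites, path("snp_sites.vcf"))
    write_site_tsv(sim$truth$known_editing_sites, path("known_editing.tsv"))
    fwrite(sim$truth$edited_sites, path("truth_edited_sites.tsv"),
           sep = "\t")
    write_gene_list(sim$truth$target_genes, path("truth_targets.txt"))
    for (cond in cfg$call$conditions) {
      reads <- gen_bulk_alignments(scfg, sim, cond)
      write_sam(reads, sim$reference, path(paste0(cond, ".sam")))
    }
    results$simulate <- sim
    write_provenance(out_dir, "simulate", cfg, scfg$seed)
  }

  if ("call" %in% stages) {
    for (f in c("reference.fa", "annotation.bed", "biotypes.tsv",
                "snp_sites.vcf", "known_editing.tsv"))
      require_file(path(f), "call", "simulate")
    reference <- Biostrings::readDNAStringSet(path("reference.fa"))
    annotation <- load_annotation(path("annotation.bed"),
                                  biotype_table = path("biotypes.tsv"))
    snp_db <- load_site_db(path("snp_sites.vcf"), "SNP")
    edit_db <- load_site_db(path("known_editing.tsv"), "known-editing")
    for (cond in cfg$call$conditions) {
      require_file(path(paste0(cond, ".sam")), "call", "simulate")
      pl <- pileup_from_alignments(path(paste0(cond, ".sam")), reference)
      calls <- call_mismatches(pl, cfg$call$min_phred,
                               cfg$call$min_alt_reads)
      calls <- exclude_known_sites(calls, snp_db, edit_db)
      ev <- editing_events(calls, annotation)
      write_editing_events(ev, path(paste0(cond, ".events.tsv")))
    }
    results$call <- cfg$call$conditions
    write_provenance(out_dir, "call", cfg, stage_seed(cfg$seed, "call"),
                     inputs = as.list(path(paste0(cfg$call$conditions,
                                                  ".sam"))))
  }

  if ("rank" %in% stages) {
    for (cond in cfg$call$conditions)
      require_file(path(paste0(cond, ".events.tsv")), "rank", "call")
    require_file(path("annotation.bed"), "rank", "simulate")
    annotation <- load_annotation(path("annotation.bed"),
                                  biotype_table = path("biotypes.tsv"))
    events <- lapply(cfg$call$conditions, function(cond)
      read_editing_events(path(paste0(cond, ".events.tsv"))))
    names(events) <- cfg$call$conditions
    mat <- aggregate_utr_editing(events, annotation)
    ranked <- rank_residuals(mat, test_condition = "agoTRIBE",
                             background_condition = "ADARonly")
    sel <- select_top_background(ranked, cfg$rank$K_top, cfg$rank$K_bg)
    fwrite(sel$ranked, path("ranked_targets.tsv"), sep = "\t")
    write_gene_list(sel$targets, path("targets.txt"))
    write_gene_list(sel$background, path("background.txt"))
    results$rank <- sel
    write_provenance(out_dir, "rank", cfg, stage_seed(cfg$seed, "rank"))
  }

  if ("compare" %in% stages) {
    require_file(path("targets.txt"), "compare", "rank")
    require_file(path("truth_targets.txt"), "compare", "simulate")
    targets <- read_gene_list(path("targets.txt"))
    truth <- read_gene_list(path("truth_targets.txt"))
    universe <- cfg$compare$universe %||%
      nrow(fread(path("ranked_targets.tsv")))
    ob <- overlap_binomial(targets, truth, universe)
    cmp <- data.frame(
      jaccard = jaccard(targets, truth),
      observed_overlap = ob$observed, expected_overlap = ob$expected,
      fold = ob$fold, p.value = ob$p.value, universe = universe,
      recovered_fraction = length(intersect(targets, truth)) /
        length(truth))
    fwrite(cmp, path("compare.tsv"), sep = "\t")
    results$compare <- cmp
    write_provenance(out_dir, "compare", cfg,
                     stage_seed(cfg$seed, "compare"))
  }
  invisible(results)
}
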