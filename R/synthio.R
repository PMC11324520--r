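## synthio: self-contained synthetic experiments with ground truth ---------

#' Linker sequence used by the synthetic single-cell generator
#'
#' A fixed 60-nt stand-in for the artificial linker joining the effector
#' and editing domains of the fusion construct; reads matching it report
#' per-cell transfection. Synthetic, not the real construct sequence.
#' @export
TRIBE_LINKER <- paste0("ACGGTCAGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       "GATCTCGTATGCCGTCTTCT")

#' Build and validate a simulation configuration
#'
#' The configuration fixes the study conditions every generator emulates:
#' paired fusion-protein vs deaminase-only bulk samples with elevated
#' editing in a planted target subset, SNP and sequencing-error
#' confounders, derepressed targets after global miRNA inhibition, and
#' single cells spanning cell-cycle phases with linker reads and spike-ins.
#' Editing rates are per adenosine per read; no published per-adenosine
#' rate exists for the assay, so defaults are chosen for statistical power
#' at desk scale (see the methods vignette). The seed fully determines all
#' outputs.
#'
#' @param n_genes Number of genes (one transcript and contig each).
#' @param utr_length_range 3'UTR length range in bp (min >= 40 so that ten
#'   sense adenosines can always be planted).
#' @param cds_length Length of the non-UTR transcript body, bp.
#' @param editing_rate_target Per-adenosine, per-read editing probability
#'   at planted target genes in the fusion-protein condition.
#' @param editing_rate_background Per-adenosine background editing rate
#'   (all genes in the deaminase-only condition; non-target genes in the
#'   fusion condition).
#' @param known_editing_fraction Fraction of UTR adenosines that are
#'   "known" endogenous editing sites (edited in every condition and listed
#'   in the known-editing database).
#' @param known_editing_rate Editing rate at known sites, all conditions.
#' @param snp_density Per-bp probability of a heterozygous SNP (alt allele
#'   present in half the reads in every condition).
#' @param seq_error_rate Per-base sequencing error probability.
#' @param low_qual_fraction Fraction of base qualities drawn at
#'   `phred_low`; the rest are `phred_high` (two-valued qualities make
#'   Phred-threshold behavior crisply testable).
#' @param phred_low,phred_high The two base-quality values.
#' @param read_length Read length, bp.
#' @param depth_mean Mean reads per gene (Poisson).
#' @param n_target_genes Number of planted target genes.
#' @param excluded_biotype_fraction Fraction of genes assigned an excluded
#'   transcript biotype (see [EXCLUDED_BIOTYPES]).
#' @param nb_size Negative-binomial size (inverse dispersion) for count
#'   tables.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of baseline gene
#'   expression means in bulk count tables.
#' @param derepression_log2fc Planted log2 fold change of target genes in
#'   the miRNA-inhibition scenario.
#' @param n_cells Number of single cells.
#' @param transfected_fraction Fraction of cells carrying the construct.
#' @param linker_expression_mean Mean linker reads per transfected cell.
#' @param linker_false_hit_rate Probability an untransfected cell shows one
#'   spurious linker read.
#' @param linker_mismatch_prob Probability a synthetic linker read carries
#'   one mismatched base.
#' @param spikein_total Mean spike-in reads per cell.
#' @param sc_mean Log-normal median of per-gene single-cell expression.
#' @param sc_edit_rate Mean editing events per gene per transfected cell.
#' @param sc_edit_background Same, untransfected cells.
#' @param n_phase_markers Genes per cell-cycle marker set (S and G2/M).
#' @param phase_marker_boost Expression multiplier of markers in their own
#'   phase.
#' @param seed Integer seed determining all generator outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       utr_length_range = c(150L, 250L),
                       cds_length = 150L,
                       editing_rate_target = 0.30,
                       editing_rate_background = 0.05,
                       known_editing_fraction = 0.02,
                       known_editing_rate = 0.20,
                       snp_density = 0.002,
                       seq_error_rate = 0.001,
                       low_qual_fraction = 0.10,
                       phred_low = 20L, phred_high = 37L,
                       read_length = 75L,
                       depth_mean = 30,
                       n_target_genes = 50L,
                       excluded_biotype_fraction = 0.10,
                       nb_size = 25,
                       expr_meanlog = log(400), expr_sdlog = 1,
                       derepression_log2fc = 0.18,
                       n_cells = 100L,
                       transfected_fraction = 0.8,
                       linker_expression_mean = 20,
                       linker_false_hit_rate = 0,
                       linker_mismatch_prob = 0.2,
                       spikein_total = 500,
                       sc_mean = 20,
                       sc_edit_rate = 0.33,
                       sc_edit_background = 0.02,
                       n_phase_markers = 50L,
                       phase_marker_boost = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("editing_rate_target", "editing_rate_background",
              "known_editing_fraction", "known_editing_rate", "snp_density",
              "seq_error_rate", "low_qual_fraction", "transfected_fraction",
              "linker_false_hit_rate", "linker_mismatch_prob"))
    if (!is_prob(cfg[[p]])) stopf("'%s' must be a probability in [0,1]", p)
  if (cfg$editing_rate_target < cfg$editing_rate_background)
    stopf("editing_rate_target must not be below editing_rate_background")
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1)
    stopf("n_genes must be a positive count")
  if (length(cfg$utr_length_range) != 2L ||
      cfg$utr_length_range[1] > cfg$utr_length_range[2])
    stopf("utr_length_range must be an increasing bp interval")
  if (cfg$utr_length_range[1] < 40)
    stopf(paste0("utr_length_range too small to guarantee 10 adenosines ",
                 "per UTR (minimum 40 bp)"))
  if (cfg$read_length > cfg$cds_length + cfg$utr_length_range[1])
    stopf("read_length exceeds the shortest possible transcript")
  if (cfg$n_target_genes > cfg$n_genes)
    stopf("n_target_genes exceeds n_genes")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference, 3'UTR annotation and truth manifest
#'
#' One contig per gene, holding a transcript made of a body plus a 3'UTR.
#' Strands are random; every UTR carries at least ten transcript-sense
#' adenosines (reference `A` on plus-strand genes, `T` on minus-strand
#' genes) so editing can always be planted. A configurable fraction of
#' genes receives excluded biotypes; planted targets are drawn from the
#' protein-coding remainder. SNP positions and known-editing sites are
#' recorded in the truth manifest for database exclusion downstream.
#'
#' @param config A [sim_config()].
#' @return list with `reference` (`DNAStringSet`), `annotation`
#'   ([utr_set()]), and `truth` (edited sites with per-condition rates, SNP
#'   sites, known-editing sites, target genes, per-gene table).
#' @export
gen_reference_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(stage_seed(config$seed, "reference"))
  n <- config$n_genes
  gid <- sprintf("G%05d", seq_len(n))
  tid <- sprintf("T%05d", seq_len(n))
  ctg <- sprintf("ctg%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  utr_len <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                    n, replace = TRUE)
  L <- config$cds_length + utr_len

  n_excl <- round(n * config$excluded_biotype_fraction)
  biotype <- rep("protein_coding", n)
  excl_idx <- if (n_excl > 0) sample(n, n_excl) else integer()
  biotype[excl_idx] <- rep_len(EXCLUDED_BIOTYPES, n_excl)
  coding_idx <- setdiff(seq_len(n), excl_idx)
  if (config$n_target_genes > length(coding_idx))
    stopf("not enough protein-coding genes for n_target_genes")
  target_idx <- sort(sample(coding_idx, config$n_target_genes))

  seqs <- character(n)
  utr_start <- ifelse(strand == "+", config$cds_length + 1L, 1L)
  utr_end <- ifelse(strand == "+", L, utr_len)
  sense_a <- ifelse(strand == "+", "A", "T")
  edited <- vector("list", n)
  snps <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample(c("A", "C", "G", "T"), L[i], replace = TRUE)
    upos <- utr_start[i]:utr_end[i]
    a_in_utr <- upos[s[upos] == sense_a[i]]
    if (length(a_in_utr) < 10L) {
      fill <- sample(setdiff(upos, a_in_utr), 10L - length(a_in_utr))
      s[fill] <- sense_a[i]
      a_in_utr <- sort(c(a_in_utr, fill))
    }
    # heterozygous SNPs anywhere on the contig
    sp <- which(runif(L[i]) < config$snp_density)
    if (length(sp)) {
      alts <- vapply(s[sp], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                       b), 1L), "")
      snps[[i]] <- data.table(contig = ctg[i], pos = sp, ref = s[sp],
                              alt = alts)
      a_in_utr <- setdiff(a_in_utr, sp)
    }
    known <- a_in_utr[runif(length(a_in_utr)) < config$known_editing_fraction]
    plain <- setdiff(a_in_utr, known)
    edited[[i]] <- data.table(
      gene_id = gid[i], contig = ctg[i],
      pos = c(plain, known), strand = strand[i],
      known = rep(c(FALSE, TRUE), c(length(plain), length(known))))
    seqs[i] <- paste(s, collapse = "")
  }
  reference <- Biostrings::DNAStringSet(stats::setNames(seqs, ctg))

  genes <- data.table(gene_id = gid, transcript_id = tid, contig = ctg,
                      strand = strand, biotype = biotype, length = L,
                      utr_start = utr_start, utr_end = utr_end,
                      is_target = seq_len(n) %in% target_idx)
  annotation <- utr_set(genes[, .(gene_id, transcript_id, contig,
                                  start = utr_start, end = utr_end,
                                  strand, biotype)])
  ed <- rbindlist(edited)
  ed[, is_target := gene_id %in% gid[target_idx]]
  ed[, rate_agoTRIBE := fifelse(known, config$known_editing_rate,
                                fifelse(is_target, config$editing_rate_target,
                                        config$editing_rate_background))]
  ed[, rate_ADARonly := fifelse(known, config$known_editing_rate,
                                config$editing_rate_background)]
  ed[, rate_control := fifelse(known, config$known_editing_rate, 0)]
  truth <- list(
    edited_sites = ed[known == FALSE],
    known_editing_sites = ed[known == TRUE,
                             .(contig, pos, gene_id, strand)],
    snp_sites = rbindlist(snps[!vapply(snps, is.null, TRUE)]),
    target_genes = gid[target_idx],
    genes = genes
  )
  list(reference = reference, annotation = annotation, truth = truth)
}

#' Generate synthetic bulk alignments for one condition
#'
#' Ungapped reads (pure match CIGAR) drawn uniformly along each transcript
#' contig at Poisson depth. Reads carry planted edits at
#' condition-appropriate per-site rates, SNP alternate alleles at allele
#' fraction 0.5 in every condition, uniform sequencing errors, and
#' two-valued base qualities.
#'
#' @param config A [sim_config()].
#' @param sim Output of [gen_reference_and_annotation()].
#' @param condition `"agoTRIBE"`, `"ADARonly"` or `"control"`.
#' @return `data.table` of SAM fields (`qname`, `flag`, `contig`, `pos`,
#'   `mapq`, `seq`, `qual`), coordinate-sorted; write with [write_sam()].
#' @export
gen_bulk_alignments <- function(config, sim,
                                condition = c("agoTRIBE", "ADARonly",
                                              "control")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  withr::local_seed(stage_seed(config$seed, paste0("bulk_", condition)))
  genes <- sim$truth$genes
  rl <- config$read_length
  n_reads <- rpois(nrow(genes), config$depth_mean)
  gidx <- rep(seq_len(nrow(genes)), n_reads)
  total <- length(gidx)
  if (total == 0L)
    return(data.table(qname = character(), flag = integer(),
                      contig = character(), pos = integer(),
                      mapq = integer(), seq = character(),
                      qual = character()))
  maxstart <- genes$length[gidx] - rl + 1L
  start <- 1L + floor(runif(total) * maxstart)
  refchar <- as.character(sim$reference)[genes$contig[gidx]]
  seqs <- substring(refchar, start, start + rl - 1L)

  reads <- data.table(rid = seq_len(total), contig = genes$contig[gidx],
                      start = start, end = start + rl - 1L)
  rate_col <- paste0("rate_", condition)
  ed <- sim$truth$edited_sites
  kn <- sim$truth$known_editing_sites
  sites <- rbind(
    if (nrow(ed)) ed[, .(contig, pos, alt = fifelse(strand == "+", "G", "C"),
                         rate = get(rate_col))],
    if (nrow(kn)) kn[, .(contig, pos, alt = fifelse(strand == "+", "G", "C"),
                         rate = config$known_editing_rate)],
    if (nrow(sim$truth$snp_sites))
      sim$truth$snp_sites[, .(contig, pos, alt, rate = 0.5)]
  )
  if (!is.null(sites) && nrow(sites)) {
    sites <- sites[rate > 0]
    hits <- merge(reads, sites, by = "contig", allow.cartesian = TRUE,
                  sort = FALSE)
    hits <- hits[pos >= start & pos <= end]
    hits <- hits[runif(.N) < rate]
    if (nrow(hits)) {
      off <- hits$pos - hits$start + 1L
      for (j in seq_len(nrow(hits)))
        substr(seqs[hits$rid[j]], off[j], off[j]) <- hits$alt[j]
    }
  }
  # uniform sequencing errors
  n_err <- rbinom(1L, total * rl, config$seq_error_rate)
  if (n_err > 0L) {
    erid <- sample.int(total, n_err, replace = TRUE)
    eoff <- sample.int(rl, n_err, replace = TRUE)
    for (j in seq_len(n_err)) {
      cur <- substr(seqs[erid[j]], eoff[j], eoff[j])
      substr(seqs[erid[j]], eoff[j], eoff[j]) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  qlow <- rawToChar(as.raw(33L + config$phred_low))
  qhigh <- rawToChar(as.raw(33L + config$phred_high))
  qm <- matrix(ifelse(runif(total * rl) < config$low_qual_fraction,
                      qlow, qhigh), nrow = rl)
  quals <- do.call(paste0, asplit(qm, 1L))

  out <- data.table(
    qname = sprintf("%s_r%07d", condition, seq_len(total)),
    flag = sample(c(0L, 16L), total, replace = TRUE),
    contig = reads$contig, pos = reads$start, mapq = 60L,
    seq = seqs, qual = quals)
  setorder(out, contig, pos)
  out[]
}

#' Write synthetic alignments as a coordinate-sorted SAM file
#'
#' @param reads `data.table` from [gen_bulk_alignments()].
#' @param reference `DNAStringSet` providing the `@SQ` header lines.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  body <- if (nrow(reads)) {
    cigar <- sprintf("%dM", nchar(reads$seq))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$qname, reads$flag, reads$contig, reads$pos, reads$mapq,
            cigar, reads$seq, reads$qual)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the reference as FASTA
#' @param reference `DNAStringSet`.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' Generate a gene-by-sample count table for the derepression scenarios
#'
#' Negative-binomial counts with log-normal baseline means shared between
#' scenarios (so the two scenarios are comparable), library sizes varied up
#' to threefold to exercise TMM normalization, and planted target genes
#' multiplied by `2^derepression_log2fc` in the miRNA-inhibition (`T6B`)
#' scenario.
#'
#' @param config A [sim_config()].
#' @param scenario `"T6B"` (miRNA inhibition) or `"control"`.
#' @param annotation,truth Optional; when given, gene identifiers and the
#'   planted target set come from the reference simulation, otherwise they
#'   are synthesized from the config alone.
#' @param n_samples Replicates per scenario.
#' @return Integer matrix genes x samples with `target_genes` attribute.
#' @export
gen_expression_counts <- function(config, scenario = c("T6B", "control"),
                                  annotation = NULL, truth = NULL,
                                  n_samples = 2L) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  if (!is.null(annotation)) {
    genes <- sort(unique(annotation$gene_id))
    targets <- truth$target_genes
  } else {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    targets <- NULL
  }
  # baseline means and target set are scenario-independent
  withr::local_seed(stage_seed(config$seed, "expr_base"))
  mu0 <- rlnorm(length(genes), config$expr_meanlog, config$expr_sdlog)
  if (is.null(targets))
    targets <- sort(sample(genes, config$n_target_genes))
  withr::local_seed(stage_seed(config$seed, paste0("expr_", scenario)))
  libfac <- runif(n_samples, 1, 3)
  mu <- mu0
  if (scenario == "T6B")
    mu[genes %in% targets] <- mu[genes %in% targets] *
      2^config$derepression_log2fc
  counts <- matrix(0L, length(genes), n_samples,
                   dimnames = list(genes,
                                   paste0(scenario, "_", seq_len(n_samples))))
  for (s in seq_len(n_samples))
    counts[, s] <- rnbinom(length(genes), mu = mu * libfac[s],
                           size = config$nb_size)
  attr(counts, "target_genes") <- targets
  counts
}

#' Generate a synthetic single-cell experiment
#'
#' Cells are assigned cell-cycle phases; designated S and G2/M marker genes
#' are boosted in their own phase. A fixed subset of cells is transfected:
#' those receive linker reads (emitted as raw read sequences embedding
#' [TRIBE_LINKER], with occasional single mismatches) and elevated
#' per-gene editing-event counts; untransfected cells receive background
#' editing and (by default) zero linker reads. Every cell receives
#' spike-in reads. Read counts are scaled roughly 100-fold down from real
#' plate-based single-cell depth; QC thresholds are meant to be scaled
#' accordingly.
#'
#' @param config A [sim_config()].
#' @param sim Optional output of [gen_reference_and_annotation()]; when
#'   given, gene identifiers come from its annotation.
#' @param phase_edit_genes Optional genes receiving extra editing only in
#'   `phase_edit_phase` (in transfected cells) — planted differential
#'   targeting across the cycle.
#' @param phase_edit_phase Phase for `phase_edit_genes` (`"G1"`, `"S"`,
#'   `"G2M"`).
#' @param phase_edit_lambda Mean extra events per such gene per cell.
#' @return list: `cells` (metadata: `cell_id`, `transfected`, `phase`,
#'   `detected_genes`, `total_reads`, `dedup_reads`, `linker_raw`,
#'   `spike_reads`, `editing_events`), `counts` (gene x cell),
#'   `editing` (gene x cell event counts), `linker_reads` (per-cell
#'   character vectors), `s_markers`, `g2m_markers`, `truth`.
#' @export
gen_single_cells <- function(config, sim = NULL, phase_edit_genes = NULL,
                             phase_edit_phase = "S",
                             phase_edit_lambda = 5) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(stage_seed(config$seed, "cells"))
  genes <- if (!is.null(sim)) sort(unique(sim$annotation$gene_id)) else
    sprintf("G%05d", seq_len(config$n_genes))
  ng <- length(genes)
  nc <- config$n_cells
  nm <- min(config$n_phase_markers, floor(ng / 4))
  s_markers <- genes[seq_len(nm)]
  g2m_markers <- genes[nm + seq_len(nm)]

  cell_id <- sprintf("cell%04d", seq_len(nc))
  phase <- sample(c("G1", "S", "G2M"), nc, replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
  n_tr <- round(nc * config$transfected_fraction)
  transfected <- logical(nc)
  if (n_tr > 0) transfected[sample(nc, n_tr)] <- TRUE

  mu0 <- rlnorm(ng, log(config$sc_mean), 1)
  # marker panels emulate canonical cycle genes: moderately expressed with
  # modest spread, so no single marker dominates a mean-based module score
  midx <- match(c(s_markers, g2m_markers), genes)
  mu0[midx] <- rlnorm(length(midx), log(config$sc_mean), 0.5)
  cell_scale <- rlnorm(nc, 0, 0.2)
  boost <- matrix(1, ng, nc)
  boost[match(s_markers, genes), phase == "S"] <- config$phase_marker_boost
  boost[match(g2m_markers, genes), phase == "G2M"] <- config$phase_marker_boost
  mu <- (mu0 %o% cell_scale) * boost
  counts <- matrix(rnbinom(ng * nc, mu = mu, size = 10), ng, nc,
                   dimnames = list(genes, cell_id))

  lam <- matrix(rep(ifelse(transfected, config$sc_edit_rate,
                           config$sc_edit_background), each = ng), ng, nc)
  if (!is.null(phase_edit_genes)) {
    sel <- phase == phase_edit_phase & transfected
    lam[match(phase_edit_genes, genes), sel] <-
      lam[match(phase_edit_genes, genes), sel] + phase_edit_lambda
  }
  editing <- matrix(rpois(ng * nc, lam), ng, nc,
                    dimnames = list(genes, cell_id))

  linker_raw <- ifelse(transfected, rpois(nc, config$linker_expression_mean),
                       rbinom(nc, 1L, config$linker_false_hit_rate))
  linker_reads <- lapply(seq_len(nc), function(i)
    make_linker_reads(linker_raw[i], config$read_length,
                      config$linker_mismatch_prob))
  spike_reads <- rpois(nc, config$spikein_total)
  total_reads <- colSums(counts) + linker_raw + spike_reads
  dedup_reads <- rbinom(nc, total_reads, 0.85)
  cells <- data.table(
    cell_id = cell_id, transfected = transfected, phase = phase,
    detected_genes = colSums(counts > 0), total_reads = total_reads,
    dedup_reads = dedup_reads, linker_raw = linker_raw,
    spike_reads = spike_reads, editing_events = colSums(editing))
  list(cells = cells, counts = counts, editing = editing,
       linker_reads = stats::setNames(linker_reads, cell_id),
       s_markers = s_markers, g2m_markers = g2m_markers,
       truth = list(transfected = stats::setNames(transfected, cell_id),
                    phase = stats::setNames(phase, cell_id),
                    phase_edit_genes = phase_edit_genes,
                    phase_edit_phase = phase_edit_phase))
}

make_linker_reads <- function(n, read_length, mismatch_prob) {
  if (n == 0L) return(character())
  bases <- c("A", "C", "G", "T")
  lk <- TRIBE_LINKER
  ll <- nchar(lk)
  out <- character(n)
  for (i in seq_len(n)) {
    if (read_length >= ll) {
      nfl <- read_length - ll
      lfl <- sample.int(nfl + 1L, 1L) - 1L
      rd <- paste0(paste(sample(bases, lfl, TRUE), collapse = ""), lk,
                   paste(sample(bases, nfl - lfl, TRUE), collapse = ""))
    } else {
      s <- sample.int(ll - read_length + 1L, 1L)
      rd <- substr(lk, s, s + read_length - 1L)
    }
    if (runif(1) < mismatch_prob) {
      p <- sample.int(nchar(rd), 1L)
      substr(rd, p, p) <- sample(setdiff(bases, substr(rd, p, p)), 1L)
    }
    if (runif(1) < 0.5) rd <- revcomp(rd)
    out[i] <- rd
  }
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}
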