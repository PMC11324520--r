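test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(utr_length_range = c(20, 30)),
               "guarantee 10 adenosines")
  expect_error(sim_config(editing_rate_target = 0.01,
                          editing_rate_background = 0.2),
               "editing_rate_target")
  expect_error(sim_config(snp_density = 1.5), "probability")
  expect_error(sim_config(n_target_genes = 10, n_genes = 5), "exceeds")
  # the zero-rate degenerate case is a legal configuration
  expect_s3_class(sim_config(editing_rate_target = 0,
                             editing_rate_background = 0),
                  "sim_config")
})

test_that("generator outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 5, n_target_genes = 2, seed = 1)
  a <- gen_reference_and_annotation(cfg)
  b <- gen_reference_and_annotation(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$edited_sites, b$truth$edited_sites)
  ra <- gen_bulk_alignments(cfg, a, "agoTRIBE")
  rb <- gen_bulk_alignments(cfg, b, "agoTRIBE")
  expect_identical(ra, rb)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(ra, a$reference, f1); write_sam(rb, b$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("excluded-biotype fraction and planted-site bases are exact", {
  cfg <- sim_config(n_genes = 100, excluded_biotype_fraction = 0.2,
                    n_target_genes = 10, seed = 3)
  sim <- gen_reference_and_annotation(cfg)
  expect_equal(sum(sim$truth$genes$biotype %in% EXCLUDED_BIOTYPES), 20)
  # every planted site sits on A for + strand genes, T for - strand genes
  ed <- sim$truth$edited_sites
  refchar <- as.character(sim$reference)
  base_at <- substring(refchar[ed$contig], ed$pos, ed$pos)
  expect_true(all(base_at[ed$strand == "+"] == "A"))
  expect_true(all(base_at[ed$strand == "-"] == "T"))
  # planted sites lie inside the annotated UTR of their gene
  ann <- data.table::as.data.table(sim$annotation)
  m <- merge(ed, ann, by = "gene_id")
  expect_true(all(m$pos >= m$start & m$pos <= m$end))
  # every UTR carries at least 10 sense adenosines
  n_sense <- sapply(seq_len(nrow(ann)), function(i) {
    s <- strsplit(refchar[ann$contig[i]], "")[[1]][ann$start[i]:ann$end[i]]
    sum(s == if (ann$strand[i] == "+") "A" else "T")
  })
  expect_true(all(n_sense >= 10))
})

test_that("zero editing rates leave only SNP and error mismatches", {
  cfg <- sim_config(n_genes = 20, n_target_genes = 5,
                    editing_rate_target = 0, editing_rate_background = 0,
                    known_editing_fraction = 0, seed = 5)
  sim <- gen_reference_and_annotation(cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(gen_bulk_alignments(cfg, sim, "agoTRIBE"), sim$reference, sam)
  calls <- call_mismatches(pileup_from_alignments(sam, sim$reference))
  calls <- exclude_known_sites(calls, site_db(sim$truth$snp_sites, "SNP"))
  # after removing SNPs no multi-read-supported mismatch remains at
  # planted-editable sites (errors are independent and almost never agree)
  key <- paste0(calls$contig, ":", calls$pos)
  truth_key <- paste0(sim$truth$edited_sites$contig, ":",
                      sim$truth$edited_sites$pos)
  expect_length(intersect(key, truth_key), 0)
})

test_that("observed per-site editing support matches the configured rate", {
  cfg <- sim_config(n_genes = 15, n_target_genes = 15, depth_mean = 50,
                    editing_rate_target = 0.5, seq_error_rate = 0,
                    low_qual_fraction = 0, snp_density = 0,
                    known_editing_fraction = 0,
                    excluded_biotype_fraction = 0, seed = 11)
  sim <- gen_reference_and_annotation(cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(gen_bulk_alignments(cfg, sim, "agoTRIBE"), sim$reference, sam)
  pl <- pileup_from_alignments(sam, sim$reference)
  ed <- sim$truth$edited_sites
  key <- paste0(pl$contig, ":", pl$pos)
  at_truth <- pl[key %in% paste0(ed$contig, ":", ed$pos)]
  edited <- at_truth$base != at_truth$ref
  # pooled binomial check at 3 sigma around p = 0.5
  n <- nrow(at_truth); phat <- mean(edited)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
  # control condition carries no editing at those sites
  sam2 <- tempfile(fileext = ".sam")
  write_sam(gen_bulk_alignments(cfg, sim, "control"), sim$reference, sam2)
  pl2 <- pileup_from_alignments(sam2, sim$reference)
  at2 <- pl2[paste0(pl2$contig, ":", pl2$pos) %in%
               paste0(ed$contig, ":", ed$pos)]
  expect_equal(sum(at2$base != at2$ref), 0)
})

test_that("expression generator plants the derepression effect and nothing else", {
  cfg0 <- sim_config(n_genes = 500, n_target_genes = 25,
                     derepression_log2fc = 0, seed = 8)
  t6b <- gen_expression_counts(cfg0, "T6B", n_samples = 3)
  ctl <- gen_expression_counts(cfg0, "control", n_samples = 3)
  expect_true(all(t6b >= 0), all(t6b == floor(t6b)))
  expect_identical(attr(t6b, "target_genes"), attr(ctl, "target_genes"))
  # null effect: depth-adjusted means agree in expectation
  rel_t <- rowMeans(sweep(t6b, 2, colSums(t6b), "/"))
  rel_c <- rowMeans(sweep(ctl, 2, colSums(ctl), "/"))
  expect_lt(abs(median(log2(rel_t / rel_c))), 0.05)

  cfg1 <- sim_config(n_genes = 2000, n_target_genes = 100,
                     derepression_log2fc = 0.18, seed = 8)
  t6b1 <- gen_expression_counts(cfg1, "T6B")
  ctl1 <- gen_expression_counts(cfg1, "control")
  bg <- setdiff(rownames(t6b1), attr(t6b1, "target_genes"))
  rel_t <- rowMeans(sweep(t6b1, 2, colSums(t6b1), "/"))
  rel_c <- rowMeans(sweep(ctl1, 2, colSums(ctl1), "/"))
  expect_lt(abs(median(log2(rel_t[bg] / rel_c[bg]))), 0.05)
})

test_that("single-cell generator separates transfected and untransfected cells", {
  cfg <- sim_config(n_genes = 200, n_target_genes = 10, n_cells = 100,
                    transfected_fraction = 0.8, seed = 13)
  sc <- gen_single_cells(cfg)
  expect_equal(sum(sc$truth$transfected), 80)
  # exactly the truth-flagged cells show elevated planted editing
  ev <- sc$cells$editing_events
  tr <- sc$cells$transfected
  expect_gt(min(ev[tr]), max(ev[!tr]))
  # untransfected cells have zero linker reads by default
  expect_true(all(sc$cells$linker_raw[!tr] == 0))
  cfg0 <- sim_config(n_genes = 200, n_cells = 30, transfected_fraction = 0,
                     n_target_genes = 10, seed = 13)
  sc0 <- gen_single_cells(cfg0)
  expect_true(all(sc0$cells$linker_raw == 0))
})

test_that("phase-specific planted editing is recovered after spike-in scaling", {
  cfg <- sim_config(n_genes = 300, n_target_genes = 10, n_cells = 120,
                    transfected_fraction = 1, seed = 17)
  g <- "G00100"
  sc <- gen_single_cells(cfg, phase_edit_genes = g, phase_edit_phase = "S",
                         phase_edit_lambda = 4)
  phase <- sc$truth$phase
  pooled <- pool_by_substage(sc$editing[g, , drop = FALSE], phase)
  spk <- tapply(sc$cells$spike_reads, phase, sum)[colnames(pooled)]
  ncl <- table(phase)[colnames(pooled)]
  nm <- pseudobulk_spikein_normalize(pooled, spk, stats::setNames(
    as.numeric(ncl), names(ncl)))
  expect_gt(nm[g, "S"], nm[g, "G1"])
  expect_gt(nm[g, "S"], nm[g, "G2M"])
})
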