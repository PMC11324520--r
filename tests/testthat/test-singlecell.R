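test_that("linker counting tolerates one mismatch in either orientation", {
  lk <- TRIBE_LINKER
  flank <- strrep("A", 8)
  exact <- paste0(flank, lk, flank)
  expect_equal(count_linker_reads(exact, lk), 1L)
  # two mismatches at the only alignment offset -> rejected
  two_mm <- lk
  substr(two_mm, 5, 5) <- if (substr(two_mm, 5, 5) == "A") "C" else "A"
  substr(two_mm, 9, 9) <- if (substr(two_mm, 9, 9) == "A") "C" else "A"
  expect_equal(count_linker_reads(two_mm, lk), 0L)
  one_mm <- lk
  substr(one_mm, 5, 5) <- if (substr(one_mm, 5, 5) == "A") "C" else "A"
  expect_equal(count_linker_reads(one_mm, lk), 1L)
  # reverse-complement orientation matches too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exact)))
  expect_equal(count_linker_reads(rc, lk), 1L)
  # read shorter than the linker slides along it
  expect_equal(count_linker_reads(substr(lk, 11, 40), lk), 1L)
  expect_error(count_linker_reads("ACGT", ""), "non-empty")
})

test_that("linker counting equals a brute-force Hamming scan", {
  hamming_hit <- function(read, lk, mm) {
    orientations <- c(read, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(read))))
    for (r in orientations) {
      short <- if (nchar(r) <= nchar(lk)) r else lk
      long <- if (nchar(r) <= nchar(lk)) lk else r
      ns <- nchar(short); nl <- nchar(long)
      for (o in 0:(nl - ns)) {
        w <- substr(long, o + 1, o + ns)
        d <- sum(strsplit(w, "")[[1]] != strsplit(short, "")[[1]])
        if (d <= mm) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(61)
  lk <- substr(TRIBE_LINKER, 1, 20)
  reads <- c(
    replicate(10, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                        collapse = "")),
    vapply(1:10, function(i) {
      r <- paste0(strrep("T", 5), lk, strrep("G", 5))
      p <- sample(6:25, 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      r
    }, ""),
    replicate(5, substr(lk, sample(1:5, 1), sample(12:20, 1))))
  want <- sum(vapply(reads, hamming_hit, TRUE, lk = lk, mm = 1L))
  expect_equal(count_linker_reads(reads, lk), want)
  # symmetric under reverse-complementing the whole read set
  rc_reads <- vapply(reads, function(r) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(r))), "",
    USE.NAMES = FALSE)
  expect_equal(count_linker_reads(rc_reads, lk),
               count_linker_reads(reads, lk))
})

mk_cells <- function(...) {
  data.frame(...)
}

test_that("QC thresholds are strict and the joint linker/editing rule needs both", {
  cells <- data.frame(
    cell_id = c("under_genes", "at_genes", "under_reads", "low_linker_high_edit",
                "low_linker_low_edit"),
    detected_genes = c(8999, 9000, 9500, 9500, 9500),
    dedup_reads = c(2e5, 2e5, 149999, 2e5, 2e5),
    total_reads = c(1e6, 1e6, 1e6, 1e6, 1e6),
    linker_raw = c(100, 100, 100, 30, 30),     # (30+1)/1e6 -> log10 ~ -4.51
    editing_events = c(2000, 2000, 2000, 1500, 999))
  kept <- qc_filter_cells(cells, mode = "hek")
  expect_setequal(kept$cell_id, c("at_genes", "low_linker_high_edit"))
  # k562 mode: one linker read means transfected
  k <- data.frame(cell_id = c("a", "b"), detected_genes = 9500,
                  dedup_reads = 2e5, total_reads = 1e6,
                  linker_raw = c(0, 1), editing_events = 10)
  kk <- qc_filter_cells(k, mode = "k562")
  expect_equal(kk$cell_id, "b")
})

test_that("tightening any QC threshold never admits a new cell", {
  set.seed(71)
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    detected_genes = sample(8000:10000, 40, TRUE),
    dedup_reads = sample(1e5:2e5, 40, TRUE),
    total_reads = sample(5e5:2e6, 40, TRUE),
    linker_raw = sample(0:200, 40, TRUE),
    editing_events = sample(0:3000, 40, TRUE))
  base <- qc_filter_cells(cells, mode = "hek")$cell_id
  tighter <- list(
    qc_filter_cells(cells, min_genes = 9500, mode = "hek"),
    qc_filter_cells(cells, min_dedup_reads = 180000, mode = "hek"),
    qc_filter_cells(cells, linker_log10_min = -3.8, mode = "hek"),
    qc_filter_cells(cells, min_editing = 2500, mode = "hek"))
  for (t in tighter) expect_true(all(t$cell_id %in% base))
})

test_that("module scores are null for constant data and separate planted cells", {
  genes <- sprintf("g%03d", 1:120)
  cells <- sprintf("c%02d", 1:40)
  flat <- matrix(100, 120, 40, dimnames = list(genes, cells))
  sc <- module_score(flat, genes[1:10], seed = 1)
  expect_true(all(abs(sc) < 1e-10))
  # planted 2x upregulation of the set in half the cells
  set.seed(81)
  expr <- matrix(rlnorm(120 * 40, log(50), 0.2), 120, 40,
                 dimnames = list(genes, cells))
  hot <- 1:20
  expr[genes[1:10], hot] <- expr[genes[1:10], hot] * 2
  sc2 <- module_score(expr, genes[1:10], seed = 2)
  expect_gt(min(sc2[hot]), max(sc2[-hot]))
  # locality: perturbing genes outside set and controls leaves scores alone
  expect_error(module_score(expr, c("nope1", "nope2")), "no genes")
})

test_that("phase assignment follows the argmax rule with G1 fallback", {
  sc <- data.frame(cell_id = c("a", "b", "c", "d"),
                   s_score = c(10, -1, 60, 5),
                   g2m_score = c(-5, -2, 70, 8))
  ph <- assign_phase(sc)
  expect_equal(ph$phase, c("S", "G1", "G2M", "G2M"))
  expect_message(ph2 <- assign_phase(sc, rule = "both-high-g1"), "G1 rule")
  expect_equal(ph2$phase[3], "G1")     # both scores above 50 forced to G1
})

test_that("substages split each phase into near-equal halves, extra cell early", {
  set.seed(91)
  n <- 25
  sc <- data.frame(cell_id = sprintf("c%02d", 1:n),
                   s_score = rnorm(n, 5), g2m_score = rnorm(n, -5))
  ph <- assign_phase(sc)
  tab <- table(ph$phase, ph$substage)
  for (p in rownames(tab)) {
    d <- tab[p, "early"] - tab[p, "late"]
    expect_true(d %in% c(0, 1))
  }
})

test_that("spike-in scaling follows the stated algebra and flattens per-cell signal", {
  pooled <- matrix(c(100, 100), 1, 2, dimnames = list("g", c("A", "B")))
  spikes <- c(A = 1000, B = 2000)       # B has twice the spike depth/cell
  ncells <- c(A = 10, B = 10)
  # literal pooled/factor form: B half of A
  lit <- pseudobulk_spikein_normalize(pooled, spikes, ncells,
                                      per_cell = FALSE)
  expect_equal(unname(lit[1, "B"] / lit[1, "A"]), 0.5)
  expect_equal(unname(lit[1, "A"]), 100 * 10 / 1000)  # pooled * n / spike
  # per-cell form divides out unequal substage sizes
  pooled2 <- matrix(c(500, 100), 1, 2, dimnames = list("g", c("big", "small")))
  sp2 <- c(big = 5000, small = 1000)    # same per-cell spike depth (100)
  nc2 <- c(big = 50, small = 10)        # same per-cell expression (10)
  flat <- pseudobulk_spikein_normalize(pooled2, sp2, nc2)
  expect_equal(unname(flat[1, "big"]), unname(flat[1, "small"]))
  expect_error(pseudobulk_spikein_normalize(pooled, c(A = 0, B = 10),
                                            ncells), "zero spike")
})

test_that("differential targeting flags the planted stage-specific gene", {
  set.seed(101)
  ngene <- 200
  stages <- c("G1", "S", "G2M")
  ed <- matrix(rpois(ngene * 3, 20), ngene, 3,
               dimnames = list(sprintf("g%03d", 1:ngene), stages))
  ed["g001", ] <- c(20, 120, 20)     # S-specific planted signal
  expo <- c(G1 = 5000, S = 5000, G2M = 5000)
  res <- differential_targeting(ed, expo)
  expect_equal(res$gene_id[1], "g001")
  expect_equal(res$max_stage[1], "S")
  expect_lt(res$padj[1], 0.01)
  # identical counts across stages: fold 1, adjusted p near 1
  same <- matrix(30, 4, 3, dimnames = list(letters[1:4], stages))
  res2 <- differential_targeting(same, expo)
  expect_true(all(res2$fold_change == 1))
  expect_true(all(res2$padj > 0.95))
  # Benjamini-Hochberg equals the hand step-up on the computed p-values
  p <- res$p.value[1:10]
  n <- length(p); o <- order(p)
  stepup <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  want <- numeric(n); want[o] <- stepup
  expect_equal(p.adjust(p, "BH"), want)
})

test_that("end-to-end transfected-cell calling is essentially perfect", {
  cfg <- sim_config(n_genes = 150, n_target_genes = 10, n_cells = 100,
                    transfected_fraction = 0.8, seed = 19)
  sc <- gen_single_cells(cfg)
  # scan-based linker counting on the raw reads agrees with the planted raw
  # counts up to the mismatch tolerance
  counted <- vapply(sc$linker_reads, count_linker_reads, 0L)
  expect_equal(unname(counted), sc$cells$linker_raw)
  qc <- qc_filter_cells(sc$cells, min_genes = 50, min_dedup_reads = 100,
                        mode = "k562")
  called <- sc$cells$cell_id %in% qc$cell_id
  acc <- mean(called == sc$truth$transfected)
  expect_gte(acc, 0.95)
})
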