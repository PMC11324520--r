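mk_col <- function(pos, ref, bases, quals, contig = "c1") {
  data.table::data.table(contig = contig, pos = pos, ref = ref,
                         base = bases, qual = quals,
                         strand = "+", read = paste0("r", seq_along(bases)))
}

test_that("quality and depth filters act per supporting read", {
  # no mismatching reads -> no call
  expect_equal(nrow(call_mismatches(mk_col(1, "A", rep("A", 5),
                                           rep(40L, 5)))), 0)
  # one high-quality G is not enough
  one <- mk_col(2, "A", c("A", "A", "G"), c(40L, 40L, 40L))
  expect_equal(nrow(call_mismatches(one)), 0)
  # two Gs above Phred 30 make the call
  two <- mk_col(3, "A", c("A", "G", "G"), c(40L, 35L, 33L))
  out <- call_mismatches(two)
  expect_equal(nrow(out), 1)
  expect_equal(out$alt_support, 2L)
  expect_equal(out$depth, 3L)
  expect_equal(out$min_alt_phred, 33L)
  # Phred exactly 30 is not "greater than 30"
  boundary <- mk_col(4, "A", c("G", "G"), c(30L, 30L))
  expect_equal(nrow(call_mismatches(boundary)), 0)
  expect_equal(nrow(call_mismatches(mk_col(5, "A", c("G", "G"),
                                           c(31L, 31L)))), 1)
  # two different alt bases passing -> two calls
  multi <- mk_col(6, "A", c("G", "G", "C", "C"), rep(40L, 4))
  expect_equal(nrow(call_mismatches(multi)), 2)
  # N in read or reference is ignored
  expect_equal(nrow(call_mismatches(mk_col(7, "A", c("N", "N"),
                                           c(40L, 40L)))), 0)
  expect_equal(nrow(call_mismatches(mk_col(8, "N", c("G", "G"),
                                           c(40L, 40L)))), 0)
})

test_that("caller agrees with a brute-force recount on random columns", {
  pl <- random_pileup(120, seed = 42)
  got <- call_mismatches(pl)
  want <- brute_force_calls(pl)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$pos, want$pos)
  expect_equal(got$alt, want$alt)
  expect_equal(got$alt_support, want$alt_support)
  expect_equal(got$depth, want$depth)
})

test_that("raising thresholds never increases the number of calls", {
  pl <- random_pileup(150, seed = 99)
  base_n <- nrow(call_mismatches(pl, 31L, 2L))
  for (mp in c(33L, 36L, 41L))
    expect_lte(nrow(call_mismatches(pl, mp, 2L)), base_n)
  for (mar in c(3L, 4L, 6L))
    expect_lte(nrow(call_mismatches(pl, 31L, mar)), base_n)
})

test_that("database exclusion is an order-preserving idempotent set difference", {
  pl <- random_pileup(100, seed = 7)
  calls <- call_mismatches(pl)
  expect_identical(exclude_known_sites(calls, NULL, NULL), calls)
  snp <- site_db(paste0("c1:", seq(1, 100, by = 3)), "SNP")
  red <- site_db(paste0("c1:", seq(2, 100, by = 7)), "known-editing")
  once <- exclude_known_sites(calls, snp, red)
  twice <- exclude_known_sites(once, snp, red)
  expect_identical(once, twice)
  # equals the set-difference oracle
  bad <- union(snp$keys, red$keys)
  keep <- !(paste0(calls$contig, ":", calls$pos) %in% bad)
  expect_equal(once$pos, calls$pos[keep])
  expect_equal(once$alt, calls$alt[keep])
})

test_that("editing events are strand-aware and gene-annotated", {
  ann <- utr_set(data.frame(
    gene_id = c("gPlus", "gMinus"), transcript_id = c("tP", "tM"),
    contig = c("c1", "c1"), start = c(1L, 50L), end = c(40L, 90L),
    strand = c("+", "-"), biotype = "protein_coding"))
  calls <- data.table::data.table(
    contig = "c1",
    pos = c(10L, 60L, 60L, 10L, 200L),
    ref = c("A", "T", "A", "T", "A"),
    alt = c("G", "C", "G", "C", "G"),
    depth = 10L, alt_support = 3L, min_alt_phred = 35L)
  ev <- editing_events(calls, ann)
  # A>G in + UTR kept; T>C in - UTR kept; A>G in - UTR and T>C in + UTR
  # dropped; call outside any feature dropped
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$gene_id), c("gMinus", "gPlus"))
  expect_true(all((ev$strand == "+" & ev$ref == "A" & ev$alt == "G") |
                    (ev$strand == "-" & ev$ref == "T" & ev$alt == "C")))
  # outside calls kept with inferred strand when not restricted
  ev2 <- editing_events(calls, ann, restrict_to_utr = FALSE)
  expect_equal(nrow(ev2), 3)
  expect_true(any(is.na(ev2$gene_id)))
})

test_that("a call inside overlapping opposite-strand features is duplicated", {
  ann <- utr_set(data.frame(
    gene_id = c("gF", "gR"), transcript_id = c("tF", "tR"),
    contig = "c1", start = c(1L, 1L), end = c(50L, 50L),
    strand = c("+", "-"), biotype = "protein_coding"))
  calls <- data.table::data.table(contig = "c1", pos = 20L, ref = "A",
                                  alt = "G", depth = 8L, alt_support = 2L,
                                  min_alt_phred = 33L)
  ev <- editing_events(calls, ann)
  expect_equal(nrow(ev), 1)          # A>G only matches the + feature
  expect_equal(ev$gene_id, "gF")
  calls_t <- data.table::data.table(contig = "c1", pos = 20L, ref = "T",
                                    alt = "C", depth = 8L, alt_support = 2L,
                                    min_alt_phred = 33L)
  expect_equal(editing_events(calls_t, ann)$gene_id, "gR")
})

test_that("A>G dominates the substitution spectrum only under editing", {
  ts <- tiny_sim(seed = 51, n_genes = 25, n_targets = 25)
  for (cond in c("agoTRIBE", "control")) {
    sam <- tempfile(fileext = ".sam")
    write_sam(gen_bulk_alignments(ts$cfg, ts$sim, cond),
              ts$sim$reference, sam)
    calls <- call_mismatches(pileup_from_alignments(sam, ts$sim$reference))
    calls <- exclude_known_sites(
      calls, site_db(ts$sim$truth$snp_sites, "SNP"),
      site_db(ts$sim$truth$known_editing_sites, "known-editing"))
    spec <- substitution_spectrum(calls)
    n_ag <- spec$n[spec$class == "A>G"] + spec$n[spec$class == "T>C"]
    n_other <- max(spec$n[!spec$class %in% c("A>G", "T>C")])
    if (cond == "agoTRIBE") expect_gt(n_ag, n_other)
    else expect_lte(n_ag, max(n_other, 2L))
  }
})
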