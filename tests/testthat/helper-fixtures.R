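# shared fixtures: all built in code, no files shipped

phred_char <- function(q) vapply(q, function(z) rawToChar(as.raw(33L + z)), "")

# hand-written SAM file from a list of read specs
manual_sam <- function(reads, contigs, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- vapply(reads, function(r) {
    qual <- r$qual %||% paste(rep("F", nchar(r$seq)), collapse = "")
    cigar <- r$cigar %||% sprintf("%dM", nchar(r$seq))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            r$qname %||% "r", r$flag %||% 0L, r$contig, r$pos,
            r$mapq %||% 60L, cigar, r$seq, qual)
  }, "")
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_of <- function(contigs) Biostrings::DNAStringSet(contigs)

# random pileup columns for caller oracle tests: one observation per row
random_pileup <- function(n_cols, seed, max_depth = 12L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rows <- lapply(seq_len(n_cols), function(i) {
      ref <- sample(bases, 1L)
      depth <- sample(2:max_depth, 1L)
      obs <- sample(c(ref, bases), depth, replace = TRUE,
                    prob = c(6, rep(1, 4)))
      data.table::data.table(
        contig = "c1", pos = i, ref = ref, base = obs,
        qual = sample(c(20L, 28L, 30L, 31L, 35L, 40L), depth,
                      replace = TRUE),
        strand = sample(c("+", "-"), depth, replace = TRUE),
        read = sprintf("p%d_%d", i, seq_len(depth)))
    })
    data.table::rbindlist(rows)
  })
}

# literal per-column recount: >= min_alt reads of one alt base, each Phred > 30
brute_force_calls <- function(pileup, min_phred = 31L, min_alt = 2L) {
  out <- list()
  for (key in unique(paste(pileup$contig, pileup$pos))) {
    col <- pileup[paste(pileup$contig, pileup$pos) == key, ]
    for (alt in setdiff(unique(col$base), c(col$ref[1L], "N"))) {
      if (col$ref[1L] == "N") next
      support <- sum(col$base == alt & col$qual >= min_phred)
      if (support >= min_alt)
        out[[length(out) + 1L]] <- data.frame(
          contig = col$contig[1L], pos = col$pos[1L], ref = col$ref[1L],
          alt = alt, depth = nrow(col), alt_support = support)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  res[order(res$contig, res$pos, res$alt), ]
}

# independent naive DTS statistic straight from the definition
naive_dts <- function(x, y) {
  t <- sort(unique(c(x, y)))
  if (length(t) < 2L) return(0)
  Ex <- stats::ecdf(x); Ey <- stats::ecdf(y); H <- stats::ecdf(c(x, y))
  s <- 0
  for (i in seq_len(length(t) - 1L)) {
    h <- H(t[i])
    if (h > 0 && h < 1)
      s <- s + abs(Ex(t[i]) - Ey(t[i])) * (t[i + 1L] - t[i]) /
        sqrt(h * (1 - h))
  }
  s
}

# small simulation shared by several suites
tiny_sim <- function(seed = 7, n_genes = 30, n_targets = 3, ...) {
  cfg <- sim_config(n_genes = n_genes, n_target_genes = n_targets,
                    depth_mean = 15, seed = seed,
                    excluded_biotype_fraction = 0, ...)
  list(cfg = cfg, sim = gen_reference_and_annotation(cfg))
}
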