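## editcall: mismatch calling, database exclusion, editing events ----------

#' Call mismatches from a pileup
#'
#' Applies the two filtering steps of the variant-calling scheme: a
#' per-read Phred quality filter and a supporting-read-depth filter. A call
#' is emitted for a site and alternate base iff at least `min_alt_reads`
#' observations of that base each pass the quality threshold ("Phred
#' > 30" is read literally as quality >= 31). All twelve substitution
#' classes are callable; if two alternate bases pass at one site, two calls
#' are emitted. `N` bases are ignored.
#'
#' @param pileup A [pileup_from_alignments()] table.
#' @param min_phred Minimum Phred quality of a supporting read (default 31,
#'   i.e. strictly greater than 30).
#' @param min_alt_reads Minimum quality-passing reads supporting the
#'   alternate base (default 2).
#' @return `data.table`: `contig`, `pos`, `ref`, `alt`, `depth` (all
#'   observations at the column), `alt_support` (quality-passing alternate
#'   reads), `min_alt_phred`.
#' @export
call_mismatches <- function(pileup, min_phred = 31L, min_alt_reads = 2L) {
  stopifnot(min_phred >= 0L, min_alt_reads >= 1L)
  dt <- as.data.table(pileup)
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_support = integer(),
                      min_alt_phred = integer())
  if (!nrow(dt)) return(empty)
  depth_tab <- dt[, .(depth = .N), by = .(contig, pos)]
  mm <- dt[base != ref & base != "N" & ref != "N" & qual >= min_phred]
  if (!nrow(mm)) return(empty)
  calls <- mm[, .(alt_support = .N, min_alt_phred = min(qual)),
              by = .(contig, pos, ref, alt = base)]
  calls <- calls[alt_support >= min_alt_reads]
  calls <- merge(calls, depth_tab, by = c("contig", "pos"), sort = FALSE)
  setcolorder(calls, c("contig", "pos", "ref", "alt", "depth",
                       "alt_support", "min_alt_phred"))
  setorder(calls, contig, pos, alt)
  calls[]
}

#' Remove calls at known SNP or known editing positions
#'
#' Set difference against one or two position databases; call order is
#' preserved. Idempotent.
#'
#' @param calls Output of [call_mismatches()].
#' @param snp_db,editing_db [site_db()] objects (either may be NULL).
#' @return Filtered calls.
#' @export
exclude_known_sites <- function(calls, snp_db = NULL, editing_db = NULL) {
  dt <- as.data.table(calls)
  if (!nrow(dt)) return(dt)
  drop <- rep(FALSE, nrow(dt))
  if (!is.null(snp_db)) drop <- drop | has_site(snp_db, dt$contig, dt$pos)
  if (!is.null(editing_db))
    drop <- drop | has_site(editing_db, dt$contig, dt$pos)
  dt[!drop]
}

#' Report strand-aware A-to-I editing events
#'
#' Keeps A>G calls inside plus-strand features and T>C calls inside
#' minus-strand features (inosine reads as guanosine, so editing of a
#' minus-strand transcript appears as T>C on the reference strand). Each
#' event is annotated with the gene of the feature containing it; a call
#' inside overlapping features on both strands is reported once per
#' matching feature. With `restrict_to_utr = FALSE`, A>G / T>C calls
#' outside any feature are kept with strand inferred from the substitution
#' and no gene.
#'
#' @param calls Output of [call_mismatches()] (after database exclusion).
#' @param annotation A [utr_set()].
#' @param restrict_to_utr Drop calls outside annotated features (default
#'   TRUE).
#' @return `data.table`: `contig`, `pos`, `gene_id`, `strand`, `ref`,
#'   `alt`, `depth`, `alt_support`.
#' @export
editing_events <- function(calls, annotation, restrict_to_utr = TRUE) {
  dt <- as.data.table(calls)
  empty <- data.table(contig = character(), pos = integer(),
                      gene_id = character(), strand = character(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_support = integer())
  if (!nrow(dt)) return(empty)
  ag <- dt[(ref == "A" & alt == "G") | (ref == "T" & alt == "C")]
  if (!nrow(ag)) return(empty)
  gr_calls <- GenomicRanges::GRanges(ag$contig,
                                     IRanges::IRanges(ag$pos, ag$pos))
  gr_utr <- utr_granges(annotation)
  hits <- GenomicRanges::findOverlaps(gr_calls, gr_utr,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  fs <- as.character(BiocGenerics::strand(gr_utr))[sh]
  ok <- (fs == "+" & ag$ref[qh] == "A") | (fs == "-" & ag$ref[qh] == "T")
  inside <- if (any(ok)) {
    data.table(contig = ag$contig[qh[ok]], pos = ag$pos[qh[ok]],
               gene_id = gr_utr$gene_id[sh[ok]], strand = fs[ok],
               ref = ag$ref[qh[ok]], alt = ag$alt[qh[ok]],
               depth = ag$depth[qh[ok]], alt_support = ag$alt_support[qh[ok]])
  } else empty
  inside <- unique(inside)
  if (!restrict_to_utr) {
    out_idx <- setdiff(seq_len(nrow(ag)), unique(qh))
    if (length(out_idx)) {
      outside <- data.table(
        contig = ag$contig[out_idx], pos = ag$pos[out_idx],
        gene_id = NA_character_,
        strand = ifelse(ag$ref[out_idx] == "A", "+", "-"),
        ref = ag$ref[out_idx], alt = ag$alt[out_idx],
        depth = ag$depth[out_idx], alt_support = ag$alt_support[out_idx])
      inside <- rbind(inside, outside)
    }
  }
  setorder(inside, contig, pos)
  inside[]
}

#' Tabulate the substitution spectrum of a call set
#'
#' Counts calls per substitution class (all twelve), for
#' condition-comparison displays of which mismatch classes rise under
#' editing.
#'
#' @param calls Output of [call_mismatches()].
#' @return `data.table` with `class` (e.g. `"A>G"`) and `n`.
#' @export
substitution_spectrum <- function(calls) {
  dt <- as.data.table(calls)
  bases <- c("A", "C", "G", "T")
  all_cls <- unlist(lapply(bases, function(r)
    paste0(r, ">", setdiff(bases, r))))
  n <- if (nrow(dt)) {
    tab <- dt[, .N, by = .(class = paste0(ref, ">", alt))]
    stats::setNames(tab$N, tab$class)
  } else integer()
  data.table(class = all_cls,
             n = as.integer(ifelse(all_cls %in% names(n), n[all_cls], 0L)))
}

#' Write editing events as a VCF-like TSV
#' @param events Output of [editing_events()].
#' @param path Output path.
#' @export
write_editing_events <- function(events, path) {
  fwrite(as.data.table(events), path, sep = "\t")
  invisible(path)
}

#' Read editing events written by [write_editing_events()]
#' @param path TSV path.
#' @export
read_editing_events <- function(path) {
  fread(path, sep = "\t")
}
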