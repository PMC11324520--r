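## formats: annotation, site databases, pileups, gene quantification -------

#' Construct a 3'UTR annotation table
#'
#' The central annotation container: one row per 3'UTR interval, 1-based
#' inclusive coordinates (SAM/VCF convention; BED input is converted at the
#' boundary). Intervals of a transcript must be non-overlapping; strand must
#' be `+` or `-` (records with missing strand are invalid, since editing
#' calls are strand-aware).
#'
#' @param df data.frame with columns `gene_id`, `transcript_id`, `contig`,
#'   `start`, `end`, `strand`, `biotype`.
#' @return A `data.table` of class `utr_set`, sorted by contig/start.
#' @export
utr_set <- function(df) {
  need <- c("gene_id", "transcript_id", "contig", "start", "end",
            "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  dt <- as.data.table(df)[, need, with = FALSE]
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (nrow(dt)) {
    if (any(!dt$strand %in% c("+", "-")))
      stopf("annotation records with missing or invalid strand are rejected")
    if (any(dt$end < dt$start))
      stopf("annotation intervals must satisfy start <= end")
    setorder(dt, contig, start, end)
    ov <- dt[, {
      o <- order(start)
      s <- start[o]; e <- end[o]
      list(bad = length(s) > 1L && any(s[-1L] <= e[-length(e)]))
    }, by = transcript_id]
    if (any(ov$bad))
      stopf("overlapping intervals within transcript(s): %s",
            paste(ov$transcript_id[ov$bad], collapse = ", "))
  }
  setattr(dt, "class", c("utr_set", class(dt)))
  dt[]
}

#' @export
print.utr_set <- function(x, ...) {
  cat(sprintf("<utr_set> %d interval(s), %d transcript(s), %d gene(s)\n",
              nrow(x), length(unique(x$transcript_id)),
              length(unique(x$gene_id))))
  NextMethod()
}

#' Total 3'UTR length per transcript
#' @param annotation A [utr_set()].
#' @return Named integer vector of summed interval widths.
#' @export
utr_lengths <- function(annotation) {
  out <- as.data.table(annotation)[, sum(end - start + 1L),
                                   by = transcript_id]
  stats::setNames(out$V1, out$transcript_id)
}

#' Convert an annotation to GRanges
#' @param annotation A [utr_set()].
#' @return A `GRanges` with `gene_id`, `transcript_id`, `biotype` metadata.
#' @export
utr_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    gene_id = annotation$gene_id,
    transcript_id = annotation$transcript_id,
    biotype = annotation$biotype
  )
}

#' Load a 3'UTR annotation from BED12 or GTF
#'
#' BED12 carries one transcript per line with block structure (0-based
#' half-open, converted to 1-based on load); biotypes come from a companion
#' table. GTF input uses `three_prime_utr` features with `gene_id`,
#' `transcript_id` and (optionally) `transcript_biotype`/`gene_biotype`
#' attributes.
#'
#' @param path BED12 or GTF file.
#' @param biotype_table Optional data.frame or TSV path mapping
#'   `transcript_id` to `biotype` (and optionally `gene_id`); overrides any
#'   biotype found in the file. Transcripts absent from the table default to
#'   `protein_coding`.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return A [utr_set()].
#' @export
load_annotation <- function(path, biotype_table = NULL,
                            format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  bt <- NULL
  if (!is.null(biotype_table)) {
    bt <- if (is.character(biotype_table) && length(biotype_table) == 1L)
      fread(biotype_table, header = TRUE) else as.data.table(biotype_table)
    if (!all(c("transcript_id", "biotype") %in% names(bt)))
      stopf("biotype table needs columns transcript_id, biotype")
  }
  dt <- if (format == "bed") parse_bed12(path, bt) else parse_gtf_utr(path, bt)
  if (nrow(dt) == 0L) warnf("annotation '%s' contains no 3'UTR records", path)
  utr_set(dt)
}

parse_bed12 <- function(path, bt) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(data.table(gene_id = character(), transcript_id = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      biotype = character()))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stopf("BED12 parse error at line %d: %d field(s), expected 12", i,
            length(f))
    chromStart <- suppressWarnings(as.integer(f[2L]))
    nblk <- suppressWarnings(as.integer(f[10L]))
    if (is.na(chromStart) || is.na(nblk))
      stopf("BED12 parse error at line %d: non-integer coordinate", i)
    sizes <- suppressWarnings(as.integer(strsplit(f[11L], ",")[[1L]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12L], ",")[[1L]]))
    if (length(sizes) != nblk || length(starts) != nblk ||
        anyNA(sizes) || anyNA(starts))
      stopf("BED12 parse error at line %d: malformed block lists", i)
    if (!f[6L] %in% c("+", "-"))
      stopf("BED12 parse error at line %d: missing strand", i)
    out[[i]] <- data.table(
      transcript_id = f[4L],
      contig = f[1L],
      start = chromStart + starts + 1L,        # 0-based -> 1-based
      end = chromStart + starts + sizes,
      strand = f[6L]
    )
  }
  dt <- rbindlist(out)
  dt[, gene_id := transcript_id]
  dt[, biotype := "protein_coding"]
  apply_biotype_table(dt, bt)
}

parse_gtf_utr <- function(path, bt) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "three_prime_utr"]
  if (!length(gr))
    return(data.table(gene_id = character(), transcript_id = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      biotype = character()))
  if (any(as.character(BiocGenerics::strand(gr)) == "*"))
    stopf("GTF three_prime_utr records with missing strand are rejected")
  bio <- gr$transcript_biotype %||% gr$gene_biotype %||%
    rep("protein_coding", length(gr))
  bio[is.na(bio)] <- "protein_coding"
  dt <- data.table(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    biotype = bio
  )
  apply_biotype_table(dt, bt)
}

apply_biotype_table <- function(dt, bt) {
  if (is.null(bt) || !nrow(dt)) return(dt)
  idx <- match(dt$transcript_id, bt$transcript_id)
  dt[!is.na(idx), biotype := bt$biotype[idx[!is.na(idx)]]]
  if ("gene_id" %in% names(bt))
    dt[!is.na(idx), gene_id := bt$gene_id[idx[!is.na(idx)]]]
  dt
}

#' Write an annotation as BED12 plus a biotype table
#'
#' Inverse of [load_annotation()] for the BED12 dialect; coordinates are
#' converted back to 0-based half-open.
#'
#' @param annotation A [utr_set()].
#' @param bed_path,biotype_path Output paths.
#' @return Invisibly, `bed_path`.
#' @export
write_annotation <- function(annotation, bed_path, biotype_path = NULL) {
  dt <- as.data.table(annotation)
  per_tx <- dt[, {
    o <- order(start)
    s <- start[o] - 1L; e <- end[o]
    cs <- min(s); ce <- max(e)
    list(contig = contig[1L], chromStart = cs, chromEnd = ce,
         strand = strand[1L],
         blockCount = length(s),
         blockSizes = paste0(paste(e - s, collapse = ","), ","),
         blockStarts = paste0(paste(s - cs, collapse = ","), ","),
         gene_id = gene_id[1L], biotype = biotype[1L])
  }, by = transcript_id]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   per_tx$contig, per_tx$chromStart, per_tx$chromEnd,
                   per_tx$transcript_id, per_tx$strand,
                   per_tx$chromStart, per_tx$chromEnd,
                   per_tx$blockCount, per_tx$blockSizes, per_tx$blockStarts)
  writeLines(lines, bed_path)
  if (!is.null(biotype_path))
    fwrite(per_tx[, .(transcript_id, gene_id, biotype)], biotype_path,
           sep = "\t")
  invisible(bed_path)
}

## site databases ----------------------------------------------------------

#' Load a set of genomic positions to exclude (SNPs or known editing sites)
#'
#' Accepts a VCF (parsed with VariantAnnotation) or a two-column TSV of
#' contig and 1-based position; duplicated positions are collapsed. The
#' result supports exact membership queries via [has_site()].
#'
#' @param path VCF or TSV file.
#' @param source_tag `"SNP"` or `"known-editing"` (free-form allowed).
#' @return An object of class `site_db`.
#' @export
load_site_db <- function(path, source_tag = "SNP") {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) ||
    (length(first) && startsWith(first, "##fileformat=VCF"))
  if (is_vcf) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    keys <- paste0(as.character(GenomeInfoDb::seqnames(rr)), ":",
                   BiocGenerics::start(rr))
  } else {
    dt <- fread(path, header = FALSE, sep = "\t",
                colClasses = list(character = 1))
    if (nrow(dt) && is.na(suppressWarnings(as.integer(dt[[2L]][1L]))))
      dt <- dt[-1L]                                   # header row
    p <- suppressWarnings(as.integer(dt[[2L]]))
    if (anyNA(p) && nrow(dt))
      stopf("site db '%s': non-integer position at row %d", path,
            which(is.na(p))[1L])
    keys <- if (nrow(dt)) paste0(dt[[1L]], ":", p) else character()
  }
  site_db(keys, source_tag)
}

#' @rdname load_site_db
#' @param keys Character keys `"contig:pos"`, or a data.frame with columns
#'   `contig` and `pos`.
#' @export
site_db <- function(keys = character(), source_tag = "SNP") {
  if (is.data.frame(keys)) keys <- paste0(keys$contig, ":", keys$pos)
  structure(list(keys = sort(unique(keys)), source = source_tag),
            class = "site_db")
}

#' @export
print.site_db <- function(x, ...) {
  cat(sprintf("<site_db:%s> %d site(s)\n", x$source, length(x$keys)))
  invisible(x)
}

#' @export
length.site_db <- function(x) length(x$keys)

#' Exact membership query against a site database
#' @param db A [site_db()].
#' @param contig,pos Vectors of contigs and 1-based positions.
#' @return Logical vector.
#' @export
has_site <- function(db, contig, pos) {
  paste0(contig, ":", pos) %in% db$keys
}

#' Write positions as a minimal VCF
#' @param sites data.frame with `contig`, `pos`, optional `ref`, `alt`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_vcf <- function(sites, path) {
  ref <- sites$ref %||% rep("N", nrow(sites))
  alt <- sites$alt %||% rep("N", nrow(sites))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  sites$contig, as.integer(sites$pos), ref, alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write positions as a two-column TSV
#' @inheritParams write_site_vcf
#' @export
write_site_tsv <- function(sites, path) {
  fwrite(data.table(contig = sites$contig, pos = as.integer(sites$pos)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## pileups -----------------------------------------------------------------

read_alignments <- function(sam_path, min_mapq = 1L,
                            include_duplicates = FALSE, what = character()) {
  dest <- tempfile(fileext = "")
  bam <- suppressMessages(Rsamtools::asBam(sam_path, destination = dest,
                                           overwrite = TRUE,
                                           indexDestination = TRUE))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = what,
                                   mapqFilter = min_mapq)
  GenomicAlignments::readGAlignments(bam, param = param, use.names = TRUE)
}

#' Build a per-base pileup from a SAM file
#'
#' Every aligned base of every primary, non-duplicate alignment appears in
#' exactly one column. The pileup is a long table with one row per read
#' observation, carrying the reference base, the read base, its Phred
#' quality and the read strand — the substrate for [call_mismatches()].
#'
#' @param sam_path Coordinate-sortable SAM file (converted internally).
#' @param reference `DNAStringSet` or FASTA path with the contigs the reads
#'   were aligned to.
#' @param region Optional `GRanges` restricting the columns returned.
#' @param min_mapq Minimum mapping quality (default 1 excludes multimappers
#'   by the MAPQ-0 convention).
#' @param include_duplicates Keep duplicate-flagged reads (default FALSE;
#'   putative PCR duplicates are removed).
#' @return `data.table` of class `pileup` with columns `contig`, `pos`
#'   (1-based), `ref`, `base`, `qual` (integer Phred), `strand`, `read`.
#' @export
pileup_from_alignments <- function(sam_path, reference, region = NULL,
                                   min_mapq = 1L,
                                   include_duplicates = FALSE) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  ga <- read_alignments(sam_path, min_mapq, include_duplicates,
                        what = c("seq", "qual", "flag"))
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), base = character(),
                      qual = integer(), strand = character(),
                      read = character())
  if (!length(ga)) {
    setattr(empty, "class", c("pileup", class(empty)))
    return(empty)
  }
  cig <- GenomicAlignments::cigar(ga)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig)
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = BiocGenerics::start(ga))
  nblk <- lengths(ops)
  blocks <- data.table(
    ridx = rep(seq_along(ga), nblk),
    op = unlist(ops),
    qstart = unlist(BiocGenerics::start(qr)),
    rstart = unlist(BiocGenerics::start(rr)),
    width = unlist(BiocGenerics::width(qr))
  )
  blocks <- blocks[op %in% c("M", "=", "X") & width > 0L]
  row <- rep(seq_len(nrow(blocks)), blocks$width)
  off <- sequence(blocks$width) - 1L
  ridx <- blocks$ridx[row]
  qpos <- blocks$qstart[row] + off
  rpos <- blocks$rstart[row] + off

  seqchar <- as.character(S4Vectors::mcols(ga)$seq)
  base <- substring(seqchar[ridx], qpos, qpos)
  qual_list <- as(S4Vectors::mcols(ga)$qual, "IntegerList")
  uq <- unlist(qual_list, use.names = FALSE)
  qoff <- cumsum(c(0L, S4Vectors::elementNROWS(qual_list)))
  qual <- uq[qoff[ridx] + qpos]
  flags <- S4Vectors::mcols(ga)$flag
  strand <- ifelse(bitwAnd(flags[ridx], 16L) > 0L, "-", "+")
  contig <- as.character(GenomeInfoDb::seqnames(ga))[ridx]

  # reference base lookup through concatenated per-contig offsets
  clens <- Biostrings::width(reference)
  coffs <- stats::setNames(cumsum(c(0L, clens[-length(clens)])),
                           names(reference))
  refcat <- strsplit(paste(as.character(reference), collapse = ""), "")[[1L]]
  refb <- refcat[coffs[contig] + rpos]

  dt <- data.table(contig = contig, pos = rpos, ref = refb, base = base,
                   qual = qual, strand = strand,
                   read = names(ga)[ridx] %||% as.character(ridx))
  if (!is.null(region)) {
    reg <- as.data.table(region)[, .(contig = as.character(seqnames),
                                     start, end)]
    keep <- rep(FALSE, nrow(dt))
    for (i in seq_len(nrow(reg)))
      keep <- keep | (dt$contig == reg$contig[i] & dt$pos >= reg$start[i] &
                        dt$pos <= reg$end[i])
    dt <- dt[keep]
  }
  setorder(dt, contig, pos)
  setattr(dt, "class", c("pileup", class(dt)))
  dt[]
}

## gene quantification -----------------------------------------------------

#' Gene-level read counting with fractional multi-overlap assignment
#'
#' Counts primary alignments per gene. A read overlapping the annotated
#' intervals of k distinct genes contributes 1/k to each when `fractional`
#' is on, and is dropped otherwise. Read strand is ignored; gene identity
#' comes solely from the annotation.
#'
#' @param sam_path SAM file.
#' @param annotation A [utr_set()] (gene extents are the union of each
#'   gene's intervals).
#' @param fractional Split multi-gene reads 1/k (default TRUE).
#' @param min_mapq Minimum mapping quality.
#' @return Named numeric vector of per-gene counts (all annotated genes,
#'   zeros included).
#' @export
quantify_genes <- function(sam_path, annotation, fractional = TRUE,
                           min_mapq = 1L) {
  stopifnot(nrow(annotation) > 0L)
  ga <- read_alignments(sam_path, min_mapq, FALSE)
  genes <- sort(unique(annotation$gene_id))
  counts <- stats::setNames(numeric(length(genes)), genes)
  if (!length(ga)) return(counts)
  gr <- utr_granges(annotation)
  hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(ga), gr,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(counts)
  hdt <- unique(data.table(read = S4Vectors::queryHits(hits),
                           gene = gr$gene_id[S4Vectors::subjectHits(hits)]))
  hdt[, k := .N, by = read]
  if (!fractional) hdt <- hdt[k == 1L]
  if (nrow(hdt)) {
    agg <- hdt[, sum(1 / k), by = gene]
    counts[agg$gene] <- agg$V1
  }
  counts
}
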