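## Transcript models and the region partition that drives level assignment.
## All internal coordinates are 0-based half-open; GFF3/BED I/O converts at
## the boundary.

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with integer columns \code{start} and
#' \code{end}, 0-based half-open, sorted in genomic order.  This is the
#' in-memory currency for exons, CDS pieces, UTRs and introns.
#'
#' @param start,end integer vectors of equal length; \code{start < end}.
#' @return data.frame with columns \code{start}, \code{end}.
#' @export
intervals <- function(start = integer(), end = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(start >= end)) stop("interval with start >= end")
  df <- data.frame(start = start, end = end)
  df[order(df$start), , drop = FALSE]
}

iv_width <- function(iv) sum(iv$end - iv$start)

## membership of a single 0-based position
iv_contains <- function(iv, pos) {
  nrow(iv) > 0L && any(pos >= iv$start & pos < iv$end)
}

#' Construct a transcript model
#'
#' One model describes one transcript of one gene on one assembly: its exon
#' structure, CDS structure (empty for non-coding transcripts) and strand.
#' This is the analysis unit of the nomenclature (MANE-style: one standard
#' transcript per gene).
#'
#' @param gene_symbol,transcript_id,gene_id identifier strings.
#' @param contig reference sequence name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons,cds interval tables (see [intervals()]), 0-based half-open,
#'   genomic order.  \code{cds} may have zero rows for non-coding genes.
#' @param assembly assembly name this model's coordinates refer to.
#' @return object of class \code{TranscriptModel}.
#' @export
transcript_model <- function(gene_symbol, transcript_id, contig, strand,
                             exons, cds = intervals(), gene_id = gene_symbol,
                             assembly = "ref") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0L) stop("exon list empty for ", transcript_id)
  if (any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap or are unsorted in ", transcript_id)
  if (nrow(cds) > 0L) {
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(ok))
      stop("CDS interval outside exons in transcript ", transcript_id)
    if (iv_width(cds) %% 3L != 0L)
      warning("CDS length of ", transcript_id, " not divisible by 3")
  }
  structure(list(gene_symbol = gene_symbol, transcript_id = transcript_id,
                 gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds,
                 coding_flag = nrow(cds) > 0L, assembly = assembly),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%d-%d [%s] %d exon(s), %s\n",
              x$transcript_id, x$gene_symbol, x$contig,
              min(x$exons$start) + 1L, max(x$exons$end), x$strand,
              nrow(x$exons),
              if (x$coding_flag) sprintf("%d CDS interval(s)", nrow(x$cds))
              else "non-coding"))
  invisible(x)
}

#' Read transcript models from a GFF3 file
#'
#' Expects gene / (mRNA or *RNA) / exon / CDS features with 1-based closed
#' coordinates and standard \code{ID=}/\code{Parent=} links; emits one
#' model per transcript in internal 0-based half-open coordinates,
#' deterministically ordered by (contig, start, transcript_id).
#'
#' @param path GFF3 file.
#' @param assembly_name assembly label recorded on each model.
#' @return list of [transcript_model()] objects.
#' @export
read_gff <- function(path, assembly_name = "ref") {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- vapply(as.list(meta$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  is_tx <- grepl("RNA|transcript", type, ignore.case = TRUE) & !is.na(ids)
  tx_idx <- which(is_tx)
  if (!length(tx_idx)) stop("no transcript features in ", path)

  gene_name_of <- function(i) {
    nm <- meta$Name[i]
    if (!is.null(nm) && !is.na(nm)) return(as.character(nm))
    as.character(ids[i])
  }

  models <- lapply(tx_idx, function(i) {
    tid <- ids[i]
    gid <- parents[i]
    gsym <- tid
    if (!is.na(gid)) {
      gi <- which(ids == gid)
      if (!length(gi)) stop("transcript ", tid, " has unknown Parent ", gid)
      gsym <- gene_name_of(gi[1])
    } else gid <- tid
    kids <- which(parents == tid)
    if (!length(kids)) stop("transcript ", tid, " has no child features")
    ex <- kids[type[kids] == "exon"]
    cd <- kids[type[kids] == "CDS"]
    if (!length(ex)) stop("transcript ", tid, " has no exon features")
    to_iv <- function(j) intervals(BiocGenerics::start(gr)[j] - 1L,
                                   BiocGenerics::end(gr)[j])
    transcript_model(gene_symbol = gsym, transcript_id = tid,
                     gene_id = gid,
                     contig = as.character(GenomicRanges::seqnames(gr)[i]),
                     strand = as.character(BiocGenerics::strand(gr)[i]),
                     exons = to_iv(ex),
                     cds = if (length(cd)) to_iv(cd) else intervals(),
                     assembly = assembly_name)
  })
  key <- vapply(models, function(m)
    sprintf("%s\t%012d\t%s", m$contig, min(m$exons$start), m$transcript_id),
    character(1))
  models[order(key)]
}

#' Partition a gene into the regions that define haplotype levels
#'
#' Splits the gene body into 5'UTR, CDS, introns and 3'UTR, and attaches
#' upstream/downstream flank windows of exactly \code{flank} bp (default
#' 5000, the window in which U/D-level variants are recorded and to which
#' haplotype contigs are trimmed).  The exonic pieces tile the exons
#' exactly; introns tile the inter-exon gaps.  For non-coding transcripts
#' all exonic sequence is carried in the \code{utr5} slot (it is the
#' T-level block) and \code{cds}/\code{utr3} are empty.
#'
#' @param model a [transcript_model()].
#' @param flank flank length in bp.
#' @return object of class \code{RegionPartition} with interval tables
#'   \code{utr5}, \code{cds}, \code{introns}, \code{utr3} and single
#'   intervals \code{upstream}, \code{downstream}, \code{gene_body}.
#'   \code{upstream} is the 5' flank in the transcript's reading direction
#'   (genomically right of the gene on the minus strand).
#' @export
partition_regions <- function(model, flank = 5000L) {
  stopifnot(is(model, "TranscriptModel"))
  ex <- model$exons
  if (nrow(ex) == 0L) stop("exon list empty")
  flank <- as.integer(flank)
  gb <- c(min(ex$start), max(ex$end))

  introns <- if (nrow(ex) > 1L)
    intervals(ex$end[-nrow(ex)], ex$start[-1]) else intervals()

  iv_subtract <- function(a, b_start, b_end) {
    ## pieces of interval table a outside [b_start, b_end)
    out <- list()
    for (i in seq_len(nrow(a))) {
      s <- a$start[i]; e <- a$end[i]
      if (s < b_start) out[[length(out) + 1L]] <- c(s, min(e, b_start))
      if (e > b_end)   out[[length(out) + 1L]] <- c(max(s, b_end), e)
    }
    if (!length(out)) return(intervals())
    m <- do.call(rbind, out)
    intervals(m[, 1], m[, 2])
  }

  if (model$coding_flag) {
    cs <- min(model$cds$start); ce <- max(model$cds$end)
    noncod <- iv_subtract(ex, cs, ce)
    reiv <- function(df) if (nrow(df)) intervals(df$start, df$end)
            else intervals()
    left  <- reiv(noncod[noncod$end <= cs, , drop = FALSE])
    right <- reiv(noncod[noncod$start >= ce, , drop = FALSE])
    if (model$strand == "+") { utr5 <- left; utr3 <- right }
    else                     { utr5 <- right; utr3 <- left }
    cds <- model$cds
  } else {
    utr5 <- ex; utr3 <- intervals(); cds <- intervals()
  }

  up_gen <- c(gb[1] - flank, gb[1])   # genomically left flank
  dn_gen <- c(gb[2], gb[2] + flank)
  if (model$strand == "+") { upstream <- up_gen; downstream <- dn_gen }
  else                     { upstream <- dn_gen; downstream <- up_gen }

  structure(list(utr5 = utr5, cds = cds, introns = introns, utr3 = utr3,
                 upstream = upstream, downstream = downstream,
                 gene_body = gb, flank = flank, strand = model$strand,
                 contig = model$contig),
            class = "RegionPartition")
}

## full analysis window [gene_start - flank, gene_end + flank), 0-based
partition_window <- function(part) {
  c(part$gene_body[1] - part$flank, part$gene_body[2] + part$flank)
}

#' Export a region partition as BED6 for inspection
#'
#' @param part a [partition_regions()] result.
#' @param path output BED file.
#' @param name prefix for feature names.
#' @return invisibly, the path.
#' @export
write_partition_bed <- function(part, path, name = "gene") {
  rows <- list()
  add <- function(iv, label) {
    if (is.null(dim(iv))) iv <- data.frame(start = iv[1], end = iv[2])
    for (i in seq_len(nrow(iv)))
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = part$contig, start = iv$start[i], end = iv$end[i],
        name = paste0(name, "_", label), score = 0, strand = part$strand)
  }
  add(part$utr5, "utr5"); add(part$cds, "cds")
  add(part$introns, "intron"); add(part$utr3, "utr3")
  add(part$upstream, "upstream"); add(part$downstream, "downstream")
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## region label of one 0-based position within the analysis window:
## one of "cds", "utr5", "utr3", "intron", "upstream", "downstream"
region_of <- function(part, pos) {
  if (iv_contains(part$cds, pos)) return("cds")
  if (iv_contains(part$utr5, pos)) return("utr5")
  if (iv_contains(part$utr3, pos)) return("utr3")
  if (iv_contains(part$introns, pos)) return("intron")
  if (pos >= part$upstream[1] && pos < part$upstream[2]) return("upstream")
  if (pos >= part$downstream[1] && pos < part$downstream[2])
    return("downstream")
  stop("position ", pos, " outside gene window")
}

region_to_level <- c(cds = NA, utr5 = "T", utr3 = "T", intron = "G",
                     upstream = "U", downstream = "D")
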