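## File formats: GFF3/FASTA/SAM-BAM writers and readers, catalog
## TSV/JSON/FASTA exports, variant tables and the haplotype-dictionary
## BAM.  User-facing text coordinates are 1-based; everything internal is
## 0-based half-open.

#' Write a transcript model as GFF3
#'
#' @param model a [transcript_model()].
#' @param path output file.
#' @param contig_len declared contig length for the header.
#' @return invisibly, the path.
#' @export
write_gff <- function(model, path, contig_len = NULL) {
  gb <- c(min(model$exons$start), max(model$exons$end))
  line <- function(type, s, e, id, parent = NULL, name = NULL) {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    if (!is.null(name)) attrs <- paste0(attrs, ";Name=", name)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s", model$contig, "actghap",
            type, s + 1L, e, model$strand,
            if (type == "CDS") "0" else ".", attrs)
  }
  out <- c("##gff-version 3",
           if (!is.null(contig_len))
             sprintf("##sequence-region %s 1 %d", model$contig,
                     contig_len),
           line("gene", gb[1], gb[2], paste0("gene-", model$gene_id),
                name = model$gene_symbol),
           line(if (model$coding_flag) "mRNA" else "ncRNA",
                gb[1], gb[2], model$transcript_id,
                parent = paste0("gene-", model$gene_id)))
  for (i in seq_len(nrow(model$exons)))
    out <- c(out, line("exon", model$exons$start[i], model$exons$end[i],
                       sprintf("%s-exon%d", model$transcript_id, i),
                       parent = model$transcript_id))
  for (i in seq_len(nrow(model$cds)))
    out <- c(out, line("CDS", model$cds$start[i], model$cds$end[i],
                       sprintf("%s-cds%d", model$transcript_id, i),
                       parent = model$transcript_id))
  writeLines(out, path)
  invisible(path)
}

#' Read / write FASTA as named character vectors
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return invisibly the path (write) or a named character vector (read).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write contig alignments as SAM
#'
#' @param alignments list of [contig_alignment()].
#' @param reference_lengths named integer vector contig -> length.
#' @param path output .sam path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, reference_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                   as.integer(reference_lengths)))
  ord <- order(vapply(alignments, `[[`, 0L, "pos"))
  rec <- vapply(alignments[ord], function(a)
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*", a$qname, a$contig,
            a$pos + 1L, a$cigar, a$seq), character(1))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read contig alignments from SAM or BAM
#'
#' @param path .sam or .bam file.
#' @return list of [contig_alignment()] (unmapped records dropped).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path)) Rsamtools::asBam(
    path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  else path
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
  keep <- !is.na(res$pos)
  lapply(which(keep), function(i)
    contig_alignment(res$qname[i], as.character(res$rname[i]),
                     res$pos[i] - 1L, res$cigar[i],
                     as.character(res$seq[i])))
}

#' Write a classified variant table as TSV
#'
#' Columns: CHROM, POS (1-based), REF, ALT, LEVEL, FLAGS, SUPPORTING,
#' COVERING, VQV, RETAINED.
#'
#' @param variants classified, VQV-annotated variant data frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_variant_tsv <- function(variants, path) {
  df <- data.frame(CHROM = variants$contig, POS = variants$pos + 1L,
                   REF = variants$ref, ALT = variants$alt,
                   LEVEL = variants$level, FLAGS = variants$flags,
                   SUPPORTING = variants$supporting,
                   COVERING = variants$covering,
                   VQV = round(variants$vqv, 3),
                   RETAINED = variants$retained)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## order-insensitive 32-bit rolling hash of a sequence string (stable
## content fingerprint for TSV export; not cryptographic)
seq_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Write / read a haplotype catalog as TSV
#'
#' One row per (level, cluster): gene, transcript, version, level, id,
#' sequence_hash, sequence, count, per-population counts, assemblies and
#' member list.  The TSV round-trips through [read_catalog_tsv()] into a
#' catalog usable for code assignment and diversity statistics.
#'
#' @param catalog a [build_catalog()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  rows <- list()
  pops <- sort(unique(catalog$populations))
  for (lv in catalog_levels) {
    df <- catalog$levels[[lv]]
    for (i in seq_len(nrow(df))) {
      row <- data.frame(gene = catalog$gene,
                        transcript = catalog$transcript,
                        version = catalog$version, level = lv,
                        id = df$id[i], sequence_hash = seq_hash(
                          df$sequence[i]),
                        sequence = df$sequence[i], count = df$count[i],
                        assemblies = paste(df$in_assemblies[[i]],
                                           collapse = ","),
                        members = paste(df$members[[i]], collapse = ","),
                        stringsAsFactors = FALSE)
      for (p in pops) row[[paste0("n_", p)]] <- df[[paste0("n_", p)]][i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sequence = "character"))
  pops <- sub("^n_", "", grep("^n_", names(df), value = TRUE))
  levels <- lapply(catalog_levels, function(lv) {
    sub <- df[df$level == lv, , drop = FALSE]
    out <- data.frame(id = sub$id, sequence = sub$sequence,
                      count = sub$count, stringsAsFactors = FALSE)
    chr <- function(x) ifelse(is.na(x), "", as.character(x))
    out$members <- I(strsplit(chr(sub$members), ","))
    out$in_assemblies <- I(lapply(strsplit(chr(sub$assemblies), ","),
                                  setdiff, y = ""))
    for (p in pops) out[[paste0("n_", p)]] <- sub[[paste0("n_", p)]]
    out[order(out$id), , drop = FALSE]
  })
  names(levels) <- catalog_levels
  members <- unlist(lapply(levels, function(l) unlist(l$members)))
  assemblies <- unique(unlist(lapply(levels, function(l)
    unlist(l$in_assemblies))))
  structure(list(gene = df$gene[1], transcript = df$transcript[1],
                 version = as.character(df$version[1]),
                 sources = sort(unique(members)),
                 populations = setNames(
                   rep("ALL", length(unique(members))),
                   sort(unique(members))),
                 assemblies = assemblies %||0% character(0),
                 levels = levels),
            class = "HaplotypeCatalog")
}

`%||0%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Export one gene's catalog as JSON
#'
#' Self-describing, version-stamped machine-readable export: keys
#' \code{gene}, \code{transcript}, \code{version}, \code{levels} (each a
#' list of haplotypes with id, sequence, count, populations, assemblies).
#'
#' @param catalog a [build_catalog()] result.
#' @param path output .json file.
#' @return invisibly, the path.
#' @export
write_catalog_json <- function(catalog, path) {
  pops <- sort(unique(catalog$populations))
  lv_list <- lapply(catalog$levels, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      pc <- lapply(pops, function(p) df[[paste0("n_", p)]][i])
      names(pc) <- pops
      list(id = df$id[i], sequence = df$sequence[i], count = df$count[i],
           populations = pc, assemblies = df$in_assemblies[[i]])
    })
  })
  obj <- list(format = "actghap-catalog", schema_version = "1.0",
              gene = catalog$gene, transcript = catalog$transcript,
              version = catalog$version, levels = lv_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export per-level catalog sequences as FASTA
#'
#' Record ids are formatted codes at single-level depth (e.g.
#' \code{TOY1:a1}); the A level (amino acids) is skipped unless
#' \code{include_protein}.
#'
#' @param catalog a [build_catalog()] result.
#' @param path output file.
#' @param levels which levels to export.
#' @param include_protein also export the protein (A) sequences.
#' @return invisibly, the path.
#' @export
write_catalog_fasta <- function(catalog, path,
                                levels = c("C", "T", "G"),
                                include_protein = FALSE) {
  seqs <- character(0)
  for (lv in levels) {
    df <- catalog$levels[[lv]]
    if (!nrow(df)) next
    ids <- sprintf("%s:%s%d", catalog$gene, tolower(lv), df$id)
    s <- setNames(df$sequence, ids)
    seqs <- c(seqs, s)
  }
  write_fasta(seqs, path)
  if (include_protein && nrow(catalog$levels$A)) {
    df <- catalog$levels$A
    aa <- Biostrings::AAStringSet(setNames(df$sequence, sprintf(
      "%s:a%d", catalog$gene, df$id)))
    Biostrings::writeXStringSet(aa, sub("(\\.[^.]+)?$", ".protein.faa",
                                        path)[1])
  }
  invisible(path)
}

## ---- pipeline glue -------------------------------------------------------

#' Build a gene's haplotype catalog from contig alignments
#'
#' End-to-end per-gene pipeline: trim each haplotype contig alignment to
#' the gene window, call variants from CIGARs, pool across the panel,
#' classify, annotate VQV against the calibration, filter at the per-level
#' thresholds, derive per-haplotype level sequences from the retained
#' variants, and build the frequency-ranked catalog.
#'
#' @param model a [transcript_model()].
#' @param reference reference contig sequence string.
#' @param alignments list of [contig_alignment()] (one per haploid; use
#'   assembly names for reference assemblies).
#' @param calib a [qv_calibration()], or NULL for no-filter mode (all
#'   variants retained).
#' @param flank analysis window flank (default 5000).
#' @param thresholds per-level VQV thresholds.
#' @param populations,assemblies,version passed to [build_catalog()].
#' @return list with \code{catalog}, \code{variants} (pooled classified
#'   table) and \code{level_sequences} (per-haploid).
#' @export
build_gene_catalog <- function(model, reference, alignments, calib = NULL,
                               flank = 5000L,
                               thresholds = default_vqv_thresholds,
                               populations = NULL,
                               assemblies = character(0), version = "1") {
  part <- partition_regions(model, flank)
  w <- partition_window(part)
  var_list <- lapply(alignments, function(a) {
    tr <- trim_to_gene_window(a, model, flank)
    call_variants_from_alignment(tr, reference, w)
  })
  names(var_list) <- vapply(alignments, `[[`, "", "qname")
  if (is.null(calib)) {
    pooled <- pool_panel_variants(var_list, qv_calibration(data.frame(
      contig_id = "*", base = c("A", "C", "G", "T"), run_length = 1L,
      qv = 93)), reference)
    pooled <- classify_variants(pooled, part, model, reference)
    pooled$retained <- rep(TRUE, nrow(pooled))
  } else {
    pooled <- pool_panel_variants(var_list, calib, reference)
    pooled <- classify_variants(pooled, part, model, reference)
    pooled <- filter_variants(pooled, thresholds)
  }
  panel <- lapply(names(var_list), function(h) {
    keep <- pooled$retained & vapply(pooled$carriers, function(x)
      h %in% x, logical(1))
    derive_level_sequences(pooled[keep, , drop = FALSE], model, part,
                           reference, source = h)
  })
  catalog <- build_catalog(panel, populations, assemblies, version)
  list(catalog = catalog, variants = pooled, level_sequences = panel,
       partition = part)
}

## ---- haplotype-dictionary BAM --------------------------------------------

dict_tags <- c(A = "XA", C = "XC", T = "XT", G = "XG", U = "XU", D = "XD",
               code = "XS", pops = "XP")

#' Write the haplotype-dictionary BAM of a gene catalog
#'
#' One alignment record per distinct gene-window haplotype (one per
#' ACTG-level id combination), aligned to the reference with a CIGAR
#' reconstructed from its retained variants.  Custom tags carry the level
#' ids (XA/XC/XT/XG/XU/XD, integer), the formatted code (XS) and
#' per-population carrier counts (XP, \code{pop:count} pairs).  The file
#' is coordinate-sorted and indexed.
#'
#' @param build a [build_gene_catalog()] result.
#' @param reference reference contig sequence string.
#' @param path output .bam path.
#' @return invisibly, the BAM path.
#' @export
write_haplotype_dict_bam <- function(build, reference, path) {
  catalog <- build$catalog
  part <- build$partition
  w <- partition_window(part)
  pooled <- build$variants
  panel <- build$level_sequences
  codes <- lapply(panel, assign_code, catalog = catalog)
  combo <- vapply(codes, function(cd)
    paste(cd$a, cd$c, cd$t, cd$g, sep = "_"), character(1))
  reps <- !duplicated(combo)
  pops <- catalog$populations

  sam <- tempfile(fileext = ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", part$contig,
                       nchar(reference)),
               sprintf("@CO\tactghap haplotype dictionary: tags XA/XC/XT/XG/XU/XD = level ids, XS = code, XP = population counts; gene %s version %s",
                       catalog$gene, catalog$version)), con)
  ord <- which(reps)
  for (i in ord) {
    h <- panel[[i]]$source
    carriers <- vapply(panel, `[[`, "", "source")[combo == combo[i]]
    keep <- pooled$retained & vapply(pooled$carriers, function(x)
      h %in% x, logical(1))
    ed <- pooled[keep, c("contig", "pos", "ref", "alt"), drop = FALSE]
    ed <- ed[order(ed$pos), , drop = FALSE]
    aln <- edits_to_alignment(ed, w, reference, part$contig,
                              format_code(codes[[i]]))
    pc <- table(pops[carriers])
    tags <- c(sprintf("%s:i:%d", dict_tags[c("A", "C", "T", "G", "U",
                                             "D")],
                      c(codes[[i]]$a, codes[[i]]$c, codes[[i]]$t,
                        codes[[i]]$g, codes[[i]]$u, codes[[i]]$d)),
              sprintf("XS:Z:%s", format_code(codes[[i]])),
              sprintf("XP:Z:%s", paste(sprintf("%s:%d", names(pc),
                                               as.integer(pc)),
                                       collapse = ",")))
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\t%s",
                       aln$qname, aln$contig, aln$pos + 1L, aln$cigar,
                       aln$seq, paste(tags, collapse = "\t")), con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(bam)
}

#' Read back a haplotype-dictionary BAM
#'
#' @param path BAM written by [write_haplotype_dict_bam()].
#' @return data frame with qname (formatted code), pos, cigar and the
#'   level-id tags.
#' @export
read_haplotype_dict_bam <- function(path) {
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar"),
    tag = unname(dict_tags)))[[1]]
  df <- data.frame(qname = res$qname, pos = res$pos - 1L,
                   cigar = res$cigar, stringsAsFactors = FALSE)
  for (tg in unname(dict_tags)) {
    v <- res$tag[[tg]]
    df[[tg]] <- if (is.null(v)) NA else v
  }
  df
}
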