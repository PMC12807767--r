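## Variant calling from haplotype-contig alignments, consequence
## classification against the region partition, and the
## homopolymer-calibrated binomial variant quality value (VQV) filter.
##
## Variants use VCF-style representation in 0-based coordinates: SNVs are
## single-base ref/alt; indels keep one anchor base and are left-aligned
## against the reference.

#' Default per-level VQV retention thresholds
#'
#' Protein- and coding-level haplotypes demand error probability at most
#' 1e-10 (VQV 100); exonic non-coding, intronic and flank levels 1e-5
#' (VQV 50).
#' @export
default_vqv_thresholds <- c(A = 100, C = 100, T = 50, G = 50, U = 50, D = 50)

new_variant <- function(contig, pos, ref, alt, source = NA_character_) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             source_haplotype = source, stringsAsFactors = FALSE)
}

empty_variants <- function() new_variant(character(0), integer(0),
                                         character(0), character(0),
                                         character(0))

## ---- CIGAR machinery -----------------------------------------------------

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty CIGAR")
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

#' Construct an in-memory contig alignment record
#'
#' @param qname contig/haplotype name.
#' @param contig reference sequence name.
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string (M/=/X/I/D/S/H supported).
#' @param seq aligned contig sequence (as stored in SAM, soft clips
#'   included).
#' @return object of class \code{ContigAlignment}.
#' @export
contig_alignment <- function(qname, contig, pos, cigar, seq) {
  structure(list(qname = qname, contig = contig, pos = as.integer(pos),
                 cigar = cigar, seq = toupper(seq)),
            class = "ContigAlignment")
}

aln_ref_span <- function(aln) {
  ops <- parse_cigar(aln$cigar)
  aln$pos + sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
}

#' Trim a contig alignment to the analysis window of a gene
#'
#' Clips coordinates, CIGAR and sequence to
#' \code{[gene_start - flank, gene_end + flank)}.  The window is the scope
#' within which haplotype variants are recorded.
#'
#' @param aln a [contig_alignment()].
#' @param model a [transcript_model()].
#' @param flank flank length in bp (default 5000).
#' @return a trimmed \code{ContigAlignment}.
#' @export
trim_to_gene_window <- function(aln, model, flank = 5000L) {
  part <- partition_regions(model, flank)
  w <- partition_window(part)
  if (aln$pos >= w[2] || aln_ref_span(aln) <= w[1])
    stop("alignment does not overlap gene window")
  ops <- parse_cigar(aln$cigar)
  rpos <- aln$pos
  qpos <- 1L
  new_ops <- character(0)
  new_seq <- character(0)
  new_pos <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    consumes_r <- op %in% c("M", "=", "X", "D", "N")
    consumes_q <- op %in% c("M", "=", "X", "I", "S")
    if (op %in% c("H", "P")) next
    if (op == "S") { qpos <- qpos + len; next }
    r0 <- rpos; r1 <- rpos + if (consumes_r) len else 0L
    ## overlap of [r0, r1) with window; insertions live at a point r0
    if (consumes_r) {
      lo <- max(r0, w[1]); hi <- min(r1, w[2])
      if (lo < hi) {
        if (is.na(new_pos)) new_pos <- lo
        keep <- hi - lo
        new_ops <- c(new_ops, paste0(keep, op))
        if (consumes_q) {
          off <- lo - r0
          new_seq <- c(new_seq,
                       substr(aln$seq, qpos + off, qpos + off + keep - 1L))
        }
      }
    } else if (op == "I") {
      if (r0 > w[1] && r0 < w[2]) {
        new_ops <- c(new_ops, paste0(len, op))
        new_seq <- c(new_seq, substr(aln$seq, qpos, qpos + len - 1L))
      }
    }
    if (consumes_r) rpos <- rpos + len
    if (consumes_q) qpos <- qpos + len
  }
  if (is.na(new_pos)) stop("alignment does not overlap gene window")
  contig_alignment(aln$qname, aln$contig, new_pos,
                   paste(new_ops, collapse = ""),
                   paste(new_seq, collapse = ""))
}

#' Left-align and parsimony-trim one variant against the reference
#'
#' Standard VCF normalization: shared trailing bases are removed (extending
#' left through the reference as needed), then shared leading bases beyond
#' the single anchor base are removed.
#'
#' @param variant one-row variant data frame.
#' @param reference reference sequence string for the variant's contig.
#' @return normalized one-row variant data frame.
#' @export
normalize_variant <- function(variant, reference) {
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  if (ref == alt) stop("ref == alt")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos == 0L) stop("cannot left-extend past contig start")
        b <- substr(reference, pos, pos)  # base at 0-based pos-1
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  variant$pos <- pos; variant$ref <- ref; variant$alt <- alt
  variant
}

#' Call variants from a contig alignment inside a window
#'
#' Walks the CIGAR, emitting every mismatch, insertion and deletion whose
#' edited bases fall inside \code{window}; indels are left-aligned and
#' parsimony-trimmed.  The alignment must span the window end-to-end
#' (incomplete assemblies are the caller's responsibility to exclude).
#'
#' @param aln a [contig_alignment()].
#' @param reference reference sequence string for the contig (position 1 of
#'   the string is reference coordinate 0).
#' @param window integer pair \code{c(start, end)}, 0-based half-open.
#' @return variant data frame (contig, pos, ref, alt, source_haplotype).
#' @export
call_variants_from_alignment <- function(aln, reference, window) {
  ops <- parse_cigar(aln$cigar)
  if (aln$pos > window[1] || aln_ref_span(aln) < window[2])
    stop("alignment does not span window end-to-end: ", aln$qname)
  vars <- list()
  emit <- function(pos, ref, alt) {
    v <- normalize_variant(new_variant(aln$contig, pos, ref, alt,
                                       aln$qname), reference)
    ed <- variant_edit(v[1, ])
    inside <- if (ed$re > ed$rs)
      ed$rs < window[2] && ed$re > window[1]
    else                                  # pure insertion point
      ed$rs >= window[1] && ed$rs <= window[2]
    if (inside) vars[[length(vars) + 1L]] <<- v
  }
  rpos <- aln$pos
  qpos <- 1L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("H", "P")) next
    if (op == "S") { qpos <- qpos + len; next }
    if (op %in% c("M", "=", "X")) {
      qseq <- substr(aln$seq, qpos, qpos + len - 1L)
      rseq <- substr(reference, rpos + 1L, rpos + len)
      if (qseq != rseq) {
        diff <- which(strsplit(qseq, "")[[1]] != strsplit(rseq, "")[[1]])
        for (d in diff) {
          p <- rpos + d - 1L
          if (p >= window[1] && p < window[2])
            emit(p, substr(rseq, d, d), substr(qseq, d, d))
        }
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      if (rpos > 0L) {
        anchor <- substr(reference, rpos, rpos)
        ins <- substr(aln$seq, qpos, qpos + len - 1L)
        emit(rpos - 1L, anchor, paste0(anchor, ins))
      }
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (rpos > 0L) {
        anchor <- substr(reference, rpos, rpos)
        del <- substr(reference, rpos + 1L, rpos + len)
        emit(rpos - 1L, paste0(anchor, del), anchor)
      }
      rpos <- rpos + len
    } else stop("unsupported CIGAR op: ", op)
  }
  if (!length(vars)) return(empty_variants())
  out <- do.call(rbind, vars)
  rownames(out) <- NULL
  out[order(out$pos), , drop = FALSE]
}

## ---- consequence classification -----------------------------------------

level_flags <- c("missense", "synonymous", "inframe_indel", "frameshift",
                 "start_loss", "stop_gain", "stop_loss", "splice_unmodeled")

## spliced CDS in transcript orientation with optional variants applied
spliced_cds <- function(model, reference, woff = 0L, vars = NULL) {
  region_sequence(model$cds, reference, woff, model$strand, vars)
}

cds_consequence <- function(ref_cds, alt_cds) {
  flags <- character(0)
  if ((nchar(ref_cds) - nchar(alt_cds)) %% 3L != 0L) {
    flags <- "frameshift"
  } else {
    if (substr(alt_cds, 1L, 3L) != "ATG") flags <- c(flags, "start_loss")
    pr <- aa_translate(ref_cds)
    pa <- aa_translate(alt_cds)
    stop_r <- regexpr("*", pr, fixed = TRUE)
    stop_a <- regexpr("*", pa, fixed = TRUE)
    if (stop_a == -1L) flags <- c(flags, "stop_loss")
    else if (stop_r != -1L && stop_a < stop_r) flags <- c(flags, "stop_gain")
    body_r <- if (stop_r == -1L) pr else substr(pr, 1L, stop_r - 1L)
    body_a <- if (stop_a == -1L) pa else substr(pa, 1L, stop_a - 1L)
    if (!length(flags)) {
      if (nchar(ref_cds) != nchar(alt_cds)) flags <- "inframe_indel"
      else if (body_r != body_a) flags <- "missense"
      else flags <- "synonymous"
    }
  }
  flags
}

#' Classify a variant into a haplotype level with consequence flags
#'
#' Membership in the region partition fixes the level: CDS variants are A
#' (protein-changing: missense, in-frame indel, frameshift, start-loss,
#' stop-gain, stop-loss) or C (synonymous); UTR variants are T; intronic
#' variants are G; flank variants are U (upstream) or D (downstream).  CDS
#' variants are decided by translating the variant-applied spliced CDS in
#' transcript frame.  A variant whose reference span straddles a
#' region boundary gets the \code{splice_unmodeled} flag and level A
#' (no splice-consequence modeling is attempted).
#'
#' @param variant one-row variant data frame.
#' @param partition a [partition_regions()] result.
#' @param model the [transcript_model()].
#' @param reference reference sequence string (coordinate 0 at string
#'   position 1).
#' @return the variant row with \code{level} and \code{flags} columns added
#'   (flags comma-joined, empty for non-coding levels).
#' @export
classify <- function(variant, partition, model, reference) {
  v <- variant[1, , drop = FALSE]
  ed <- variant_edit(v)
  ep <- if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) v$pos else v$pos + 1L
  reg <- region_of(partition, ep)
  span <- if (ed$re > ed$rs) seq.int(ed$rs, ed$re - 1L) else ep
  regs <- unique(vapply(span, function(p) region_of(partition, p),
                        character(1)))
  flags <- character(0)
  if (length(regs) > 1L) {
    flags <- "splice_unmodeled"
    level <- if ("cds" %in% regs) "A"
             else if ("intron" %in% regs) "G"
             else "T"
  } else if (reg == "cds") {
    ref_cds <- spliced_cds(model, reference)
    alt_cds <- spliced_cds(model, reference, 0L, v)
    flags <- cds_consequence(ref_cds, alt_cds)
    level <- if (identical(flags, "synonymous")) "C" else "A"
  } else {
    level <- region_to_level[[reg]]
  }
  v$level <- level
  v$flags <- paste(flags, collapse = ",")
  v
}

#' Classify a variant table
#' @inheritParams classify
#' @param variants variant data frame.
#' @return classified variant data frame (adds \code{level}, \code{flags}).
#' @export
classify_variants <- function(variants, partition, model, reference) {
  if (nrow(variants) == 0L) {
    variants$level <- character(0); variants$flags <- character(0)
    return(variants)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
    classify(variants[i, , drop = FALSE], partition, model, reference)))
  rownames(out) <- NULL
  out
}

## ---- homopolymer QV calibration and VQV ----------------------------------

#' Build a QV calibration table
#'
#' Maps (contig-or-sample id, base, homopolymer run length) to a
#' Phred-scaled quality value.  Row with \code{contig_id = "*"} acts as a
#' global fallback.  Lookups clamp the run length to the nearest tabulated
#' bin at or below it (and to the maximum bin above it).
#'
#' @param df data frame with columns \code{contig_id}, \code{base},
#'   \code{run_length}, \code{qv}.
#' @return object of class \code{QVCalibration}.
#' @export
qv_calibration <- function(df) {
  need <- c("contig_id", "base", "run_length", "qv")
  if (!all(need %in% names(df)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  if (any(df$qv < 0)) stop("negative QV in calibration table")
  df$run_length <- as.integer(df$run_length)
  structure(df[need], class = c("QVCalibration", "data.frame"))
}

#' Read / write calibration tables (TSV)
#' @param path TSV file with header contig_id, base, run_length, qv.
#' @return a [qv_calibration()] object.
#' @export
read_qv_calibration <- function(path) {
  qv_calibration(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_qv_calibration
#' @param calib a \code{QVCalibration}.
#' @export
write_qv_calibration <- function(calib, path) {
  write.table(as.data.frame(calib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

qv_lookup <- function(calib, contig_id, base, run_length) {
  rows <- calib[calib$contig_id == contig_id & calib$base == base, ]
  if (nrow(rows) == 0L)
    rows <- calib[calib$contig_id == "*" & calib$base == base, ]
  if (nrow(rows) == 0L)
    stop("no calibration rows for contig '", contig_id, "' base ", base,
         " and no '*' fallback")
  rows <- rows[order(rows$run_length), ]
  rl <- min(run_length, max(rows$run_length))  # clamp to max bin
  hit <- rows[rows$run_length <= rl, ]
  if (nrow(hit) == 0L) hit <- rows[1L, ]       # below smallest bin
  hit$qv[nrow(hit)]
}

#' Homopolymer context of a variant
#'
#' Run lengths are the maximal single-base runs containing the variant
#' locus, computed independently on the reference context and on the
#' variant-applied (alternate) context; non-homopolymer loci get run
#' length 1.
#'
#' @param variant one-row variant data frame.
#' @param reference reference sequence string.
#' @return list with \code{base_ref}, \code{run_length_ref},
#'   \code{base_alt}, \code{run_length_alt}.
#' @export
homopolymer_context <- function(variant, reference) {
  v <- variant[1, , drop = FALSE]
  pad <- 60L
  s <- max(0L, v$pos - pad)
  e <- min(nchar(reference), v$pos + nchar(v$ref) + pad)
  ctx <- win_substr(reference, 0L, s, e)
  off <- v$pos - s                       # 0-based offset of pos inside ctx
  alt_ctx <- apply_variants_interval(reference, 0L, s, e, v)
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
    list(base_ref = v$ref,
         run_length_ref = run_length_at(ctx, off + 1L),
         base_alt = v$alt,
         run_length_alt = run_length_at(alt_ctx, off + 1L))
  } else if (nchar(v$ref) > nchar(v$alt)) {     # deletion
    b <- substr(v$ref, 2L, 2L)
    list(base_ref = b,
         run_length_ref = run_length_at(ctx, off + 2L),
         base_alt = b,
         run_length_alt = max(1L, run_len_of_base(alt_ctx, off + 1L, b)))
  } else {                                       # insertion
    b <- substr(v$alt, 2L, 2L)
    list(base_ref = b,
         run_length_ref = max(1L, run_len_of_base(ctx, off + 1L, b)),
         base_alt = b,
         run_length_alt = run_length_at(alt_ctx, off + 2L))
  }
}

## longest run of base b touching 1-based position i or i+1
run_len_of_base <- function(seq, i, b) {
  best <- 0L
  for (j in c(i, i + 1L)) {
    if (j >= 1L && j <= nchar(seq) && substr(seq, j, j) == b)
      best <- max(best, run_length_at(seq, j))
  }
  best
}

#' Per-contig error probability of a variant context
#'
#' The lower of the reference- and alternate-context QVs is converted to a
#' probability: \code{p = 10^(-min(QV_ref, QV_alt)/10)}.
#'
#' @param calib a [qv_calibration()].
#' @param ctx a [homopolymer_context()].
#' @param contig_id contig/sample id used for table lookup.
#' @return error probability in (0, 1].
#' @export
contig_error_probability <- function(calib, ctx, contig_id) {
  qr <- qv_lookup(calib, contig_id, ctx$base_ref, ctx$run_length_ref)
  qa <- qv_lookup(calib, contig_id, ctx$base_alt, ctx$run_length_alt)
  10^(-min(qr, qa) / 10)
}

#' Binomial variant quality value (VQV)
#'
#' Under an error-only null where each of \code{covering} contigs
#' independently shows the allele with probability \code{p_err}, the
#' probability of observing at least \code{supporting} supporting contigs
#' is the upper binomial tail P = Pr[X >= supporting].  VQV is its Phred
#' transform \code{-10 log10 P}; VQV 100 corresponds to P = 1e-10 (the A/C
#' retention boundary) and VQV 50 to P = 1e-5 (T/G boundary).
#'
#' @param supporting number of contigs carrying the allele.
#' @param covering number of contigs covering the locus.
#' @param p_err per-contig error probability in (0, 1].
#' @return non-negative VQV (vectorized).
#' @export
vqv <- function(supporting, covering, p_err) {
  if (any(supporting < 0) || any(supporting > covering))
    stop("supporting must be in [0, covering]")
  if (any(p_err <= 0) || any(p_err > 1)) stop("p_err must be in (0, 1]")
  logp <- pbinom(supporting - 1, covering, p_err,
                 lower.tail = FALSE, log.p = TRUE)
  pmax(0, -10 * logp / log(10))
}

#' Apply per-level VQV retention thresholds
#'
#' Sets the \code{retained} flag: a variant is retained iff its VQV meets
#' the threshold for its level (\code{>=}, boundary inclusive).  With
#' \code{vqv_indels_only = TRUE} substitutions bypass the filter (always
#' retained), mirroring a frameshift-indel-focused filtering mode.
#'
#' @param variants classified variant data frame with \code{vqv} column.
#' @param thresholds named vector level -> minimum VQV.
#' @param drop if TRUE, return only retained rows.
#' @param vqv_indels_only filter indels only.
#' @return data frame with logical \code{retained}.
#' @export
filter_variants <- function(variants, thresholds = default_vqv_thresholds,
                            drop = FALSE, vqv_indels_only = FALSE) {
  if (nrow(variants) == 0L) {
    variants$retained <- logical(0)
    return(variants)
  }
  miss <- setdiff(unique(variants$level), names(thresholds))
  if (length(miss))
    stop("no VQV threshold for level(s): ", paste(miss, collapse = ", "))
  if (is.null(variants$vqv) || anyNA(variants$vqv))
    stop("vqv missing on some variants; annotate first")
  variants$retained <- variants$vqv >= thresholds[variants$level]
  if (vqv_indels_only) {
    is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
    variants$retained <- variants$retained | is_snv
  }
  if (drop) variants[variants$retained, , drop = FALSE] else variants
}

#' Pool per-haplotype variant calls across a panel and annotate VQV
#'
#' Identical variants observed on several haplotype contigs are pooled;
#' the supporting count is the number of carriers, the covering count the
#' panel size (configurable).  Each pooled variant gets its homopolymer
#' context, per-contig error probability (from the calibration of its
#' first carrier) and VQV.
#'
#' @param var_list list of per-haplotype variant data frames (as returned
#'   by [call_variants_from_alignment()]).
#' @param calib a [qv_calibration()].
#' @param reference reference sequence string.
#' @param covering covering count; defaults to the number of haplotypes in
#'   the panel.
#' @return variant data frame with \code{supporting}, \code{covering},
#'   \code{p_err}, \code{vqv} and a \code{carriers} list-column.
#' @export
pool_panel_variants <- function(var_list, calib, reference,
                                covering = length(var_list)) {
  all <- do.call(rbind, c(var_list, list(empty_variants())))
  if (nrow(all) == 0L) {
    out <- empty_variants()
    out$supporting <- integer(0); out$covering <- integer(0)
    out$p_err <- numeric(0); out$vqv <- numeric(0)
    out$carriers <- I(list())
    return(out)
  }
  key <- paste(all$contig, all$pos, all$ref, all$alt, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  rows <- lapply(groups, function(idx) {
    v <- all[idx[1], , drop = FALSE]
    v$source_haplotype <- NA_character_
    v$supporting <- length(unique(all$source_haplotype[idx]))
    v$covering <- covering
    ctx <- homopolymer_context(v, reference)
    v$p_err <- contig_error_probability(calib, ctx,
                                        all$source_haplotype[idx[1]])
    v$vqv <- vqv(v$supporting, v$covering, v$p_err)
    v$carriers <- I(list(sort(unique(all$source_haplotype[idx]))))
    v
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pos, out$ref, out$alt), , drop = FALSE]
}
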