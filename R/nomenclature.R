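## Per-level haplotype sequence derivation, catalog construction with
## global frequency-ranked identifiers, code assignment and cross-assembly
## rank comparison.

catalog_levels <- c("A", "C", "T", "G", "U", "D")

#' Derive the per-level sequences of one phased haplotype
#'
#' Applies a haplotype's retained variants to the reference and splits the
#' result into the level sequences: \code{a_seq} (protein), \code{c_seq}
#' (spliced CDS nucleotides), \code{t_seq} (exonic non-coding: 5'UTR
#' followed by 3'UTR in transcript order, or all exons of a non-coding
#' gene), \code{g_seq} (introns in transcript order), \code{u_seq} /
#' \code{d_seq} (upstream/downstream flanks).  All nucleotide sequences are
#' reported on the transcript strand.
#'
#' Translation disruption is detected relative to the reference model: a
#' CDS length change not divisible by 3 is a \code{frameshift}; loss of the
#' reference ATG start is \code{start_loss}; an in-frame stop strictly
#' before the haplotype's final codon is \code{stop_gain}; absence of a
#' terminal stop (when the reference has one) is \code{stop_loss}.  Any
#' disruption forces \code{a_seq} to be absent (\code{NA}) — such
#' haplotypes later render as \code{a0} — while \code{c_seq} is kept.
#'
#' @param variants retained variant data frame (possibly empty) to apply to
#'   the reference; a \code{retained} column, if present, must be all TRUE.
#' @param model a [transcript_model()].
#' @param partition the matching [partition_regions()] result.
#' @param reference reference sequence string (coordinate 0 at string
#'   position 1).
#' @param source haplotype identifier (sample+phase or assembly name).
#' @param cluster_truncated if TRUE, a stop-gain haplotype is clustered by
#'   its truncated protein instead of being forced to a0 (non-default).
#' @return object of class \code{LevelSequences}.
#' @export
derive_level_sequences <- function(variants, model, partition, reference,
                                   source = "hap", cluster_truncated = FALSE) {
  if (is.null(variants)) variants <- empty_variants()
  if (!is.null(variants$retained) && !all(variants$retained))
    stop("variant set contains non-retained variants; filter first")
  rs <- function(iv) region_sequence(iv, reference, 0L, model$strand,
                                     variants)
  t5 <- rs(partition$utr5)
  t3 <- rs(partition$utr3)
  t_seq <- if (is.na(t5) && is.na(t3)) NA_character_
           else paste0(if (is.na(t5)) "" else t5, if (is.na(t3)) "" else t3)
  g_seq <- rs(partition$introns)
  u_seq <- rs(partition$upstream)
  d_seq <- rs(partition$downstream)

  a_seq <- NA_character_
  c_seq <- NA_character_
  flags <- character(0)
  if (model$coding_flag) {
    ref_cds <- region_sequence(model$cds, reference, 0L, model$strand)
    c_seq <- rs(model$cds)
    if ((nchar(c_seq) - nchar(ref_cds)) %% 3L != 0L)
      flags <- c(flags, "frameshift")
    if (substr(ref_cds, 1L, 3L) == "ATG" && substr(c_seq, 1L, 3L) != "ATG")
      flags <- c(flags, "start_loss")
    aa <- aa_translate(c_seq)
    aa_ref <- aa_translate(ref_cds)
    stop_i <- regexpr("*", aa, fixed = TRUE)
    ref_has_stop <- grepl("*", aa_ref, fixed = TRUE)
    if (!length(flags)) {
      if (stop_i == -1L) {
        if (ref_has_stop) flags <- c(flags, "stop_loss")
      } else if (stop_i < nchar(aa)) {
        flags <- c(flags, "stop_gain")
      }
    }
    if (!length(flags)) {
      a_seq <- if (stop_i == -1L) aa else substr(aa, 1L, stop_i - 1L)
    } else if (cluster_truncated && identical(flags, "stop_gain")) {
      a_seq <- substr(aa, 1L, stop_i - 1L)
    }
  }
  structure(list(a_seq = a_seq, c_seq = c_seq, t_seq = t_seq,
                 g_seq = g_seq, u_seq = u_seq, d_seq = d_seq,
                 source = source, disruption_flags = flags,
                 gene = model$gene_symbol,
                 transcript = model$transcript_id),
            class = "LevelSequences")
}

#' @export
print.LevelSequences <- function(x, ...) {
  show <- function(s) if (is.na(s)) "<absent>" else
    if (nchar(s) > 40L) paste0(substr(s, 1, 37), "...") else s
  cat(sprintf("LevelSequences for %s (%s), source %s\n", x$gene,
              x$transcript, x$source))
  for (f in c("a_seq", "c_seq", "t_seq", "g_seq", "u_seq", "d_seq"))
    cat(sprintf("  %s: %s\n", f, show(x[[f]])))
  if (length(x$disruption_flags))
    cat("  disrupted:", paste(x$disruption_flags, collapse = ","), "\n")
  invisible(x)
}

ls_level_seq <- function(ls, level) {
  switch(level, A = ls$a_seq, C = ls$c_seq, T = ls$t_seq, G = ls$g_seq,
         U = ls$u_seq, D = ls$d_seq)
}

#' Build a frequency-ranked haplotype catalog for one gene
#'
#' Within each level, identical sequences across the panel are clustered
#' and numbered 1..K in descending global count; reference assemblies are
#' ordinary panel rows (one haplotype each), so their haplotypes sit inside
#' the same global ranking.  Count ties are broken by lexicographic order
#' of the sequence string, which makes the numbering independent of panel
#' input order.  Absent sequences map to id 0 and are excluded from
#' clustering.
#'
#' @param panel list of [derive_level_sequences()] results for one gene.
#' @param populations named character vector source -> population label
#'   (sources not named fall in population \code{"ALL"}).
#' @param assemblies character vector of panel sources that are reference
#'   assemblies.
#' @param version version tag stored as metadata.
#' @return object of class \code{HaplotypeCatalog}: per level a data frame
#'   with \code{id}, \code{sequence}, \code{count}, list-columns
#'   \code{members} and \code{in_assemblies}, and per-population count
#'   columns \code{n_<pop>}.
#' @export
build_catalog <- function(panel, populations = NULL,
                          assemblies = character(0), version = "1") {
  if (!length(panel)) stop("empty panel")
  genes <- unique(vapply(panel, `[[`, "", "transcript"))
  if (length(genes) != 1L)
    stop("panel mixes transcript models: ", paste(genes, collapse = ", "))
  sources <- vapply(panel, `[[`, "", "source")
  if (anyDuplicated(sources)) stop("duplicate haplotype sources in panel")
  pop_of <- setNames(rep("ALL", length(sources)), sources)
  if (!is.null(populations))
    pop_of[names(populations)] <- populations
  pops <- sort(unique(pop_of))

  levels <- lapply(catalog_levels, function(lv) {
    seqs <- vapply(panel, ls_level_seq, "", level = lv)
    names(seqs) <- sources
    seqs <- seqs[!is.na(seqs)]
    if (!length(seqs)) {
      df <- data.frame(id = integer(0), sequence = character(0),
                       count = integer(0))
      df$members <- I(list()); df$in_assemblies <- I(list())
      return(df)
    }
    tab <- table(seqs)
    ord <- order(-as.integer(tab), names(tab))
    uniq <- names(tab)[ord]
    members <- lapply(uniq, function(s) sort(names(seqs)[seqs == s]))
    df <- data.frame(id = seq_along(uniq), sequence = uniq,
                     count = as.integer(tab)[ord],
                     stringsAsFactors = FALSE)
    df$members <- I(members)
    df$in_assemblies <- I(lapply(members, intersect, x = assemblies))
    for (p in pops)
      df[[paste0("n_", p)]] <- vapply(members, function(m)
        sum(pop_of[m] == p), integer(1))
    df
  })
  names(levels) <- catalog_levels
  structure(list(gene = panel[[1]]$gene, transcript = panel[[1]]$transcript,
                 version = version, sources = sources,
                 populations = pop_of, assemblies = assemblies,
                 levels = levels),
            class = "HaplotypeCatalog")
}

#' @export
print.HaplotypeCatalog <- function(x, ...) {
  cat(sprintf("HaplotypeCatalog %s (%s) v%s: %d haplotypes\n", x$gene,
              x$transcript, x$version, length(x$sources)))
  for (lv in catalog_levels)
    cat(sprintf("  %s: %d cluster(s)\n", lv, nrow(x$levels[[lv]])))
  invisible(x)
}

catalog_id_of <- function(catalog, level, seq) {
  if (is.na(seq)) return(0L)
  df <- catalog$levels[[level]]
  hit <- match(seq, df$sequence)
  if (is.na(hit)) NA_integer_ else df$id[hit]
}

#' Assign the haplotype code of a sample against a catalog
#'
#' Per-level lookup of the sample's derived sequences.  Absent sequences
#' map to 0; a sequence not in the catalog is an error in strict mode, or
#' receives the provisional id K+1 otherwise.
#'
#' @param sample_ls a [derive_level_sequences()] result.
#' @param catalog a [build_catalog()] result.
#' @param strict error on novel sequences (default) instead of assigning
#'   provisional ids.
#' @param prefix code prefix; defaults to the catalog's gene symbol.
#' @return an [actg_code()] with a/c/t/g/u/d set and the catalog version.
#' @export
assign_code <- function(sample_ls, catalog, strict = TRUE,
                        prefix = catalog$gene) {
  ids <- lapply(catalog_levels, function(lv) {
    id <- catalog_id_of(catalog, lv, ls_level_seq(sample_ls, lv))
    if (is.na(id)) {
      if (strict)
        stop("novel sequence at level ", lv, " for source ",
             sample_ls$source)
      id <- nrow(catalog$levels[[lv]]) + 1L
    }
    id
  })
  names(ids) <- catalog_levels
  actg_code(prefix, a = ids$A, c = ids$C, t = ids$T, g = ids$G,
            u = ids$U, d = ids$D, version = catalog$version)
}

#' Compare global haplotype ranks carried by two reference assemblies
#'
#' For each gene catalog and each level where both assemblies resolved a
#' haplotype, reports the pair of globally assigned ids (ranks).  Because
#' ids are assigned once across the combined panel, a pair like (1, 5)
#' means the first assembly carries the globally most common haplotype
#' while the second carries the fifth.
#'
#' @param catalogs a [build_catalog()] result or list of them (one per
#'   gene).
#' @param assembly_1,assembly_2 assembly source names.
#' @return data frame (gene, level, rank_on_assembly_1, rank_on_assembly_2)
#'   with attribute \code{"marginals"}: per-assembly rank histograms
#'   (assembly, level, rank, n_genes).
#' @export
cross_assembly_ranks <- function(catalogs, assembly_1, assembly_2) {
  if (is(catalogs, "HaplotypeCatalog")) catalogs <- list(catalogs)
  rows <- list()
  marg <- list()
  for (cat in catalogs) {
    for (asm in c(assembly_1, assembly_2))
      if (!asm %in% cat$assemblies)
        stop("assembly '", asm, "' not registered in catalog for gene ",
             cat$gene)
    for (lv in c("A", "C", "T", "G")) {
      df <- cat$levels[[lv]]
      rank_of <- function(asm) {
        hit <- which(vapply(df$in_assemblies, function(x) asm %in% x,
                            logical(1)))
        if (length(hit)) df$id[hit[1]] else NA_integer_
      }
      r1 <- rank_of(assembly_1); r2 <- rank_of(assembly_2)
      if (!is.na(r1))
        marg[[length(marg) + 1L]] <- data.frame(
          assembly = assembly_1, level = lv, rank = r1)
      if (!is.na(r2))
        marg[[length(marg) + 1L]] <- data.frame(
          assembly = assembly_2, level = lv, rank = r2)
      if (!is.na(r1) && !is.na(r2))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = cat$gene, level = lv,
          rank_on_assembly_1 = r1, rank_on_assembly_2 = r2,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), level = character(0),
               rank_on_assembly_1 = integer(0),
               rank_on_assembly_2 = integer(0))
  mg <- if (length(marg)) do.call(rbind, marg) else
    data.frame(assembly = character(0), level = character(0),
               rank = integer(0))
  attr(out, "marginals") <- if (nrow(mg))
    stats::aggregate(list(n_genes = rep(1L, nrow(mg))),
                     mg[c("assembly", "level", "rank")], sum)
  else cbind(mg, n_genes = integer(0))
  out
}
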