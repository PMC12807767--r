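# Shared fixtures, built in code.

# The two-exon toy gene used across modules: exons 1-based [100,139] and
# [200,239], CDS [120,139]+[200,219], i.e. 0-based exons (99,139),(199,239)
# and CDS (119,139),(199,219).  CDS is 40 nt (not a codon multiple by
# design of the coordinates, so we build the reference so that the CDS is
# ATG + 11 codons + TAA = 39 nt padded with one extra base in the model;
# instead we use CDS (119,139)+(199,218) when translation must be clean.
toy_exons <- function() intervals(c(99L, 199L), c(139L, 239L))

toy_model <- function(strand = "+", clean_cds = TRUE) {
  cds <- if (clean_cds) intervals(c(119L, 199L), c(139L, 218L))
  else intervals(c(119L, 199L), c(139L, 219L))
  transcript_model("TOY", "NM_TOY", "chrT", strand, toy_exons(), cds)
}

# reference for chrT: 400 bp, deterministic, with the toy CDS spelled so
# that translation starts ATG and ends TAA on the + strand
toy_reference <- function() {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  cds1 <- paste0("ATG", strrep("CTG", 5), "GC")          # 20 nt
  cds2 <- paste0("T", strrep("GCT", 5), "TAA")           # 19 nt
  substr(base, 120, 139) <- cds1
  substr(base, 200, 218) <- cds2
  base
}

toy_gff_lines <- function() {
  c("##gff-version 3",
    "chrT\ttest\tgene\t100\t239\t.\t+\t.\tID=gene-TOY;Name=TOY",
    "chrT\ttest\tmRNA\t100\t239\t.\t+\t.\tID=NM_TOY;Parent=gene-TOY",
    "chrT\ttest\texon\t100\t139\t.\t+\t.\tID=e1;Parent=NM_TOY",
    "chrT\ttest\texon\t200\t239\t.\t+\t.\tID=e2;Parent=NM_TOY",
    "chrT\ttest\tCDS\t120\t139\t.\t+\t0\tID=c1;Parent=NM_TOY",
    "chrT\ttest\tCDS\t200\t219\t.\t+\t0\tID=c2;Parent=NM_TOY")
}

# small random coding gene + panel for property loops
random_panel <- function(seed, n_haploids = NULL, K = NULL) {
  set.seed(seed)
  n_exons <- sample(1:3, 1)
  strand <- sample(c("+", "-"), 1)
  if (is.null(K)) K <- sample(1:4, 1)
  cnts <- sort(sample(1:6, K, replace = TRUE), decreasing = TRUE)
  n_haploids <- sum(cnts)
  p <- cnts / n_haploids
  gene <- make_gene_model(n_exons = n_exons, cds_codons = 30L,
                          utr_lens = c(24L, 24L), intron_len = 40L,
                          flank = 60L, strand = strand, seed = seed)
  spec <- panel_spec(n_haploids = n_haploids, frequency_spectrum = p,
                     variants_per_level = c(A = 1L, C = 1L, T = 1L,
                                            G = if (n_exons > 1) 1L else 0L,
                                            U = 0L, D = 0L),
                     seed = seed + 1L)
  make_panel(gene, spec, flank = 60L)
}

panel_level_sequences <- function(panel) {
  lapply(names(panel$sequences), function(h)
    derive_level_sequences(panel$edits[[h]], panel$model,
                           panel$partition, panel$reference, source = h))
}

# reassemble the genomic window sequence of one haploid from its derived
# level sequences and the region partition (SNV-only panels: region
# widths match the reference)
reconstruct_window <- function(ls, panel) {
  part <- panel$partition
  strand <- panel$model$strand
  orient <- function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    if (strand == "-")
      intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", s))))
    else s
  }
  u5w <- sum(part$utr5$end - part$utr5$start)
  t5 <- if (is.na(ls$t_seq)) "" else substr(ls$t_seq, 1, u5w)
  t3 <- if (is.na(ls$t_seq)) "" else
    substr(ls$t_seq, u5w + 1, nchar(ls$t_seq))
  tx <- paste0(t5, if (is.na(ls$c_seq)) "" else ls$c_seq, t3)
  exonic_gen <- orient(tx)
  g_gen <- orient(ls$g_seq)
  ex_w <- panel$model$exons$end - panel$model$exons$start
  in_w <- if (nrow(part$introns)) part$introns$end - part$introns$start
          else integer(0)
  pieces <- character(0)
  eoff <- 0L; ioff <- 0L
  for (k in seq_along(ex_w)) {
    pieces <- c(pieces, substr(exonic_gen, eoff + 1L, eoff + ex_w[k]))
    eoff <- eoff + ex_w[k]
    if (k <= length(in_w)) {
      pieces <- c(pieces, substr(g_gen, ioff + 1L, ioff + in_w[k]))
      ioff <- ioff + in_w[k]
    }
  }
  up_gen <- orient(ls$u_seq); dn_gen <- orient(ls$d_seq)
  left <- if (strand == "+") up_gen else dn_gen
  right <- if (strand == "+") dn_gen else up_gen
  paste0(left, paste(pieces, collapse = ""), right)
}
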