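test_that("reference haplotype derives consistent level sequences", {
  ref <- toy_reference()
  m <- toy_model()
  p <- partition_regions(m, flank = 50L)
  ls <- derive_level_sequences(NULL, m, p, ref, source = "ref")
  expect_false(anyNA(c(ls$a_seq, ls$c_seq, ls$t_seq, ls$g_seq,
                       ls$u_seq, ls$d_seq)))
  # translate(c_seq) = a_seq + terminal stop
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(ls$c_seq))))
  expect_equal(aa, paste0(ls$a_seq, "*"))
  expect_equal(nchar(ls$t_seq), 20L + 21L)     # utr5 + utr3 widths
  expect_equal(nchar(ls$g_seq), 60L)
  expect_length(ls$disruption_flags, 0L)
})

test_that("start-loss haplotypes lose the protein but keep the CDS", {
  ref <- toy_reference()
  m <- toy_model()
  p <- partition_regions(m, flank = 50L)
  # ATG -> ATA at CDS start (third base, 0-based 121)
  v <- data.frame(contig = "chrT", pos = 121L, ref = "G", alt = "A",
                  source_haplotype = "h1")
  ls <- derive_level_sequences(v, m, p, ref, source = "h1")
  expect_true(is.na(ls$a_seq))
  expect_false(is.na(ls$c_seq))
  expect_true("start_loss" %in% ls$disruption_flags)

  # code renders a0 with c >= 1
  refls <- derive_level_sequences(NULL, m, p, ref, source = "ref")
  cat <- build_catalog(list(refls, ls))
  code <- format_code(assign_code(ls, cat))
  expect_match(code, ":a0c[12]")
})

test_that("stop-gain forces a0 unless truncated clustering is enabled", {
  ref <- toy_reference()
  m <- toy_model()
  p <- partition_regions(m, flank = 50L)
  # codon 2 CTG (122-124 0-based): C->T gives TTG? need a stop:
  # make TAG from CTG via C->T and T->A; single change C->T yields TTG
  # (Leu) so instead mutate codon 2 to TAG with an MNV-free pair of SNVs
  vs <- data.frame(contig = "chrT", pos = c(122L, 123L), ref = c("C", "T"),
                   alt = c("T", "A"), source_haplotype = "h1")
  ls <- derive_level_sequences(vs, m, p, ref, source = "h1")
  expect_true("stop_gain" %in% ls$disruption_flags)
  expect_true(is.na(ls$a_seq))
  ls2 <- derive_level_sequences(vs, m, p, ref, source = "h1",
                                cluster_truncated = TRUE)
  expect_equal(ls2$a_seq, "M")
})

test_that("non-coding and intronless genes zero the expected levels", {
  nc <- transcript_model("NC1", "NR_NC1", "chrT", "+",
                         intervals(c(99L, 199L), c(139L, 239L)))
  ref <- toy_reference()
  p <- partition_regions(nc, flank = 50L)
  ls <- derive_level_sequences(NULL, nc, p, ref, source = "ref")
  expect_true(is.na(ls$a_seq) && is.na(ls$c_seq))
  expect_false(is.na(ls$t_seq))
  expect_false(is.na(ls$g_seq))
  cat <- build_catalog(list(ls))
  code <- assign_code(ls, cat)
  expect_equal(format_code(code), "NC1:a0c0t1g1")
  expect_equal(format_code(code, "short"), "NC1:t1g1")

  # intronless coding gene -> g0
  one <- make_gene_model(n_exons = 1L, cds_codons = 10L,
                         utr_lens = c(10L, 10L), flank = 40L, seed = 3,
                         gene_symbol = "ONE", transcript_id = "NM_ONE")
  p1 <- partition_regions(one$model, flank = 40L)
  l1 <- derive_level_sequences(NULL, one$model, p1, one$reference,
                               source = "ref")
  expect_true(is.na(l1$g_seq))
  c1 <- build_catalog(list(l1))
  expect_equal(format_code(assign_code(l1, c1)), "ONE:a1c1t1g0")
})

test_that("catalog ids rank by count with lexicographic tie-break", {
  panel <- random_panel(11, K = 3)
  lss <- panel_level_sequences(panel)
  cat <- build_catalog(lss)
  for (lv in c("A", "C", "T", "G")) {
    df <- cat$levels[[lv]]
    expect_equal(df$id, seq_len(nrow(df)))
    expect_true(all(diff(df$count) <= 0))
  }
  expect_equal(cat$levels$A$count, sort(panel$counts, decreasing = TRUE))

  # tie-break: equal counts -> lexicographically smaller sequence first
  mk <- function(src, s) structure(
    list(a_seq = s, c_seq = NA_character_, t_seq = NA_character_,
         g_seq = NA_character_, u_seq = NA_character_,
         d_seq = NA_character_, source = src,
         disruption_flags = character(0),
         gene = "X", transcript = "NM_X"), class = "LevelSequences")
  cat2 <- build_catalog(list(mk("s1", "MKV"), mk("s2", "MAV"),
                             mk("s3", "MKV"), mk("s4", "MAV")))
  expect_equal(cat2$levels$A$sequence, c("MAV", "MKV"))
  expect_equal(cat2$levels$A$count, c(2L, 2L))
})

test_that("reference assemblies are embedded in the global ranking", {
  # nine clusters more frequent than a unique assembly haplotype:
  # the assembly lands at id 10
  cnts <- c(10:2, 1)
  panel <- local({
    set.seed(99)
    gene <- make_gene_model(n_exons = 2L, cds_codons = 40L,
                            utr_lens = c(40L, 40L), flank = 60L,
                            seed = 100)
    spec <- panel_spec(n_haploids = sum(cnts),
                       frequency_spectrum = cnts / sum(cnts),
                       variants_per_level = c(A = 1L, C = 0L, T = 0L,
                                              G = 0L, U = 0L, D = 0L),
                       seed = 101)
    make_panel(gene, spec, flank = 60L)
  })
  lss <- panel_level_sequences(panel)
  # the single haploid of the rarest cluster is the assembly
  rare <- names(panel$cluster_of)[panel$cluster_of == 10L]
  expect_length(rare, 1L)
  for (i in seq_along(lss))
    if (lss[[i]]$source == rare) lss[[i]]$source <- "ASM1"
  cat <- build_catalog(lss, assemblies = "ASM1")
  df <- cat$levels$A
  asm_id <- df$id[vapply(df$in_assemblies, function(x) "ASM1" %in% x,
                         logical(1))]
  expect_equal(asm_id, 10L)
  # independent count check: 9 clusters have strictly higher counts
  expect_equal(sum(df$count > df$count[df$id == asm_id]), 9L)
})

test_that("assign_code maps common haplotypes to all-1 codes and flags novels", {
  panel <- random_panel(21, K = 2)
  lss <- panel_level_sequences(panel)
  cat <- build_catalog(lss)
  common <- lss[[which(panel$cluster_of == 1L)[1]]]
  expect_equal(format_code(assign_code(common, cat)),
               paste0(panel$model$gene_symbol, ":a1c1t1g1"))

  novel <- common
  novel$g_seq <- paste0(novel$g_seq, "A")
  expect_error(assign_code(novel, cat), "level G")
  prov <- assign_code(novel, cat, strict = FALSE)
  expect_equal(prov$g, nrow(cat$levels$G) + 1L)
})

test_that("code formatting and parsing cover all documented forms", {
  expect_equal(format_code(actg_code("HBB", 1, 1, 1, 1)), "HBB:a1c1t1g1")
  expect_equal(format_code(actg_code("HBB", 1, 1, version = "1"),
                           "with_version"), "HBB:a1c1:v1")
  expect_equal(format_code(actg_code("NR_002819", 0, 0, 1, 0), "short"),
               "NR_002819:t1g0")
  expect_equal(format_code(actg_code("EH38E3212459", r = 1)),
               "EH38E3212459:r1")

  pc <- parse_code("NM_000518:a1c1")
  expect_equal(pc$prefix, "NM_000518")
  expect_equal(pc$a, 1L)
  expect_equal(pc$c, 1L)
  expect_true(is.na(pc$t) && is.na(pc$g))

  pr <- parse_code("EH38E3212459:r1")
  expect_equal(pr$r, 1L)

  pv <- parse_code("HBB:a1c1t1g1:v1")
  expect_equal(pv$version, "1")

  # malformed inputs report the first offending position
  expect_error(parse_code("HBB:a1x1"), "position 7")
  expect_error(parse_code("HBB:c1a1"), "position 7")   # out of order
  expect_error(parse_code("HBB:"), "position")
  expect_error(parse_code(":a1"), "position 1")
  expect_error(parse_code("HBB:a1:w1"), "position")

  # round-trip over randomized valid codes
  set.seed(31)
  for (i in 1:200) {
    depth <- sample(1:4, 1)
    lvs <- c("a", "c", "t", "g")[sort(sample(1:4, depth))]
    args <- as.list(setNames(sample(0:9, depth, replace = TRUE), lvs))
    args$prefix <- paste0("G", i)
    if (runif(1) < 0.3) args$version <- as.character(sample(1:5, 1))
    code <- do.call(actg_code, args)
    txt <- format_code(code, if (is.null(args$version)) "full"
                       else "with_version")
    back <- parse_code(txt)
    expect_equal(back[c("prefix", "a", "c", "t", "g", "r", "version")],
                 code[c("prefix", "a", "c", "t", "g", "r", "version")])
  }
})

test_that("cross-assembly rank pairs reproduce the bubble-grid rule", {
  panel <- local({
    gene <- make_gene_model(seed = 140, n_exons = 2L)
    spec <- panel_spec(n_haploids = 20L,
                       frequency_spectrum = c(6, 5, 4, 3, 2) / 20,
                       seed = 141L)
    make_panel(gene, spec)
  })
  lss <- panel_level_sequences(panel)
  # one haploid of cluster 1 becomes assembly 1; of cluster 5, assembly 2
  h1 <- names(panel$cluster_of)[panel$cluster_of == 1L][1]
  h5 <- names(panel$cluster_of)[panel$cluster_of == 5L][1]
  for (i in seq_along(lss)) {
    if (lss[[i]]$source == h1) lss[[i]]$source <- "GRCh38x"
    if (lss[[i]]$source == h5) lss[[i]]$source <- "CHM13x"
  }
  cat <- build_catalog(lss, assemblies = c("GRCh38x", "CHM13x"))
  pairs <- cross_assembly_ranks(cat, "GRCh38x", "CHM13x")
  a_pair <- pairs[pairs$level == "A", ]
  expect_equal(a_pair$rank_on_assembly_1, 1L)
  expect_equal(a_pair$rank_on_assembly_2, 5L)

  mg <- attr(pairs, "marginals")
  # marginal histogram counts per assembly sum to resolved gene-levels
  for (asm in c("GRCh38x", "CHM13x"))
    expect_equal(sum(mg$n_genes[mg$assembly == asm]), 4L)

  expect_error(cross_assembly_ranks(cat, "GRCh38x", "nope"),
               "not registered")

  # both assemblies on the top haplotype -> pair (1, 1)
  lss2 <- panel_level_sequences(panel)
  k1 <- names(panel$cluster_of)[panel$cluster_of == 1L]
  for (i in seq_along(lss2)) {
    if (lss2[[i]]$source == k1[1]) lss2[[i]]$source <- "A1"
    if (lss2[[i]]$source == k1[2]) lss2[[i]]$source <- "A2"
  }
  cat2 <- build_catalog(lss2, assemblies = c("A1", "A2"))
  p2 <- cross_assembly_ranks(cat2, "A1", "A2")
  expect_true(all(p2$rank_on_assembly_1 == 1L &
                    p2$rank_on_assembly_2 == 1L))
})

test_that("panel order never changes ids; C clusters refine A clusters", {
  for (seed in c(51, 52, 53)) {
    panel <- random_panel(seed)
    lss <- panel_level_sequences(panel)
    cat1 <- build_catalog(lss)
    set.seed(seed)
    cat2 <- build_catalog(sample(lss))
    for (lv in c("A", "C", "T", "G"))
      expect_equal(cat1$levels[[lv]][c("id", "sequence", "count")],
                   cat2$levels[[lv]][c("id", "sequence", "count")])

    # refinement: identical C sequence implies identical A sequence
    cseqs <- vapply(lss, `[[`, "", "c_seq")
    aseqs <- vapply(lss, `[[`, "", "a_seq")
    for (s in unique(cseqs[!is.na(cseqs)]))
      expect_length(unique(aseqs[!is.na(cseqs) & cseqs == s]), 1L)
  }
})

test_that("region decomposition reconstructs the full window sequence", {
  for (seed in c(61, 62, 63, 64)) {
    panel <- random_panel(seed)
    lss <- panel_level_sequences(panel)
    part <- panel$partition
    strand <- panel$model$strand
    for (i in seq_along(lss)) {
      ls <- lss[[i]]
      orient <- function(s) if (is.na(s)) "" else
        if (strand == "-") as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s))) else s
      # split t_seq back into utr5/utr3 parts by reference arithmetic:
      # planted variants are SNVs, so lengths match the reference widths
      u5w <- sum(part$utr5$end - part$utr5$start)
      t5 <- if (is.na(ls$t_seq)) "" else substr(ls$t_seq, 1, u5w)
      t3 <- if (is.na(ls$t_seq)) "" else
        substr(ls$t_seq, u5w + 1, nchar(ls$t_seq))
      # rebuild exonic sequence in transcript order, then genomic order
      tx <- paste0(t5, if (is.na(ls$c_seq)) "" else ls$c_seq, t3)
      stopifnot(nzchar(tx))
      exonic_gen <- orient(tx)
      # interleave exons and introns in genomic order
      g_gen <- orient(ls$g_seq)
      ex_w <- panel$model$exons$end - panel$model$exons$start
      in_w <- if (nrow(part$introns)) part$introns$end -
        part$introns$start else integer(0)
      pieces <- character(0)
      eoff <- 0L; ioff <- 0L
      # CDS may sit mid-exon; exonic_gen is already genomic-order exon bases
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
      full <- paste0(left, paste(pieces, collapse = ""), right)
      expect_equal(full, unname(panel$sequences[[lss[[i]]$source]]))
    }
  }
})
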