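ref0 <- function() toy_reference()

test_that("identity contigs yield no variants; mismatches are called", {
  ref <- ref0()
  w <- c(49L, 289L)
  aln <- contig_alignment("h1", "chrT", 49L, paste0(240, "M"),
                          substr(ref, 50, 289))
  expect_equal(nrow(call_variants_from_alignment(aln, ref, w)), 0L)

  # 10=1X10= style mismatch at window offset 10
  seq <- substr(ref, 50, 289)
  orig <- substr(seq, 11, 11)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(seq, 11, 11) <- alt
  v <- call_variants_from_alignment(
    contig_alignment("h2", "chrT", 49L, "10M1X229M", seq), ref, w)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 59L)
  expect_equal(v$ref, orig)
  expect_equal(v$alt, alt)
})

test_that("alignments not spanning the window end-to-end are rejected", {
  ref <- ref0()
  aln <- contig_alignment("h", "chrT", 60L, "100M", substr(ref, 61, 160))
  expect_error(call_variants_from_alignment(aln, ref, c(49L, 289L)),
               "end-to-end")
})

test_that("homopolymer indels are left-aligned, matching the brute-force oracle", {
  # reference with an internal A-run: ...GCG AAAA TCT...
  ref <- paste0("GGCGT", "GCG", "AAAA", "TCTGG", "ACGTACG")
  n <- nchar(ref)
  for (case in list(list(del = 2L), list(ins = "AA"), list(del = 1L),
                    list(ins = "A"))) {
    if (!is.null(case$del)) {
      # contig deletes bases from the *right* end of the run
      obs <- paste0(substr(ref, 1, 11 - case$del), substr(ref, 12, n))
      cig <- sprintf("%dM%dD%dM", 11L - case$del, case$del, n - 11L)
      seq <- obs
    } else {
      ins <- case$ins
      obs <- paste0(substr(ref, 1, 11), ins, substr(ref, 12, n))
      cig <- sprintf("11M%dI%dM", nchar(ins), n - 11L)
      seq <- obs
    }
    aln <- contig_alignment("h", "c", 0L, cig, seq)
    v <- call_variants_from_alignment(aln, ref, c(0L, n))
    expect_equal(nrow(v), 1L)
    o <- oracle_leftmost_indel(ref, obs)
    expect_equal(v$pos, o$pos)
    expect_equal(v$ref, o$ref)
    expect_equal(v$alt, o$alt)
  }
})

test_that("trimming clips to the window and commutes with calling", {
  ref <- ref0()
  m <- toy_model()
  w <- c(49L, 289L)
  full <- contig_alignment("h", "chrT", 0L, "400M", ref)
  tr <- trim_to_gene_window(full, m, flank = 50L)
  expect_equal(tr$pos, 49L)
  expect_equal(tr$cigar, "240M")
  expect_equal(tr$seq, substr(ref, 50, 289))

  exact <- contig_alignment("h", "chrT", 49L, "240M", substr(ref, 50, 289))
  tr2 <- trim_to_gene_window(exact, m, flank = 50L)
  expect_equal(tr2$pos, exact$pos)
  expect_equal(tr2$cigar, exact$cigar)
  expect_equal(tr2$seq, exact$seq)

  expect_error(trim_to_gene_window(
    contig_alignment("h", "chrT", 350L, "40M", substr(ref, 351, 390)),
    m, flank = 50L), "overlap")

  # commutation on random synthetic contigs: trim-then-call equals
  # call-then-window-filter for variants strictly inside the window
  for (seed in 1:8) {
    panel <- random_panel(seed)
    gw <- panel$window
    alns <- panel_alignments(panel)
    a <- alns[[length(alns)]]
    v1 <- call_variants_from_alignment(a, panel$reference, gw)
    tr <- trim_to_gene_window(a, panel$model, flank = 60L)
    v2 <- call_variants_from_alignment(tr, panel$reference, gw)
    expect_equal(v1[c("pos", "ref", "alt")], v2[c("pos", "ref", "alt")])
  }
})

test_that("classification follows region membership and translation", {
  ref <- ref0()
  m <- toy_model()
  p <- partition_regions(m, flank = 50L)

  # CDS codon 2 is CTG (pos 123-125 1-based): second base change -> missense
  mis <- data.frame(contig = "chrT", pos = 123L, ref = "T", alt = "A",
                    source_haplotype = "h")
  cv <- classify(mis, p, m, ref)
  expect_equal(cv$level, "A")
  expect_equal(cv$flags, "missense")

  # third base CTG -> CTA stays leucine -> synonymous, level C
  syn <- data.frame(contig = "chrT", pos = 124L, ref = "G", alt = "A",
                    source_haplotype = "h")
  cs <- classify(syn, p, m, ref)
  expect_equal(cs$level, "C")
  expect_equal(cs$flags, "synonymous")

  # start codon loss
  sl <- classify(data.frame(contig = "chrT", pos = 121L,
                            ref = substr(ref, 122, 122), alt = "C",
                            source_haplotype = "h"), p, m, ref)
  expect_equal(sl$level, "A")
  expect_match(sl$flags, "start_loss")

  # frameshift: single-base deletion inside CDS
  fs <- classify(data.frame(contig = "chrT", pos = 126L,
                            ref = substr(ref, 127, 128),
                            alt = substr(ref, 127, 127),
                            source_haplotype = "h"), p, m, ref)
  expect_equal(fs$level, "A")
  expect_match(fs$flags, "frameshift")

  # UTR -> T, intron -> G, upstream -> U
  regions <- list(list(pos = 105L, level = "T"),
                  list(pos = 160L, level = "G"),
                  list(pos = 60L, level = "U"),
                  list(pos = 250L, level = "D"))
  for (rg in regions) {
    b <- substr(ref, rg$pos + 1L, rg$pos + 1L)
    v <- classify(data.frame(contig = "chrT", pos = rg$pos, ref = b,
                             alt = setdiff(c("A", "C", "G", "T"), b)[1],
                             source_haplotype = "h"), p, m, ref)
    expect_equal(v$level, rg$level)
    expect_equal(v$flags, "")
  }

  # outside the window -> error
  expect_error(classify(data.frame(contig = "chrT", pos = 10L, ref = "A",
                                   alt = "C", source_haplotype = "h"),
                        p, m, ref), "outside")
})

test_that("every base of the gene window maps to exactly one level", {
  m <- toy_model()
  ref <- ref0()
  p <- partition_regions(m, flank = 50L)
  levels <- vapply(49:288, function(pos) {
    b <- substr(ref, pos + 1L, pos + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), b)[1]
    classify(data.frame(contig = "chrT", pos = pos, ref = b, alt = alt,
                        source_haplotype = "h"), p, m, ref)$level
  }, character(1))
  expect_true(all(levels %in% c("A", "C", "T", "G", "U", "D")))
  expect_equal(sum(levels %in% c("A", "C")), 39L)   # CDS width
  expect_equal(sum(levels == "G"), 60L)             # intron width
  expect_equal(sum(levels == "U"), 50L)
  expect_equal(sum(levels == "D"), 50L)
})

test_that("error probability follows the lower-QV Phred rule", {
  calib <- qv_calibration(data.frame(
    contig_id = "*", base = "A", run_length = c(1L, 4L, 8L),
    qv = c(30, 20, 10)))
  ctx <- list(base_ref = "A", run_length_ref = 1L,
              base_alt = "A", run_length_alt = 4L)
  expect_equal(contig_error_probability(calib, ctx, "h1"), 1e-2)

  # QV 0 on both sides -> probability 1
  c0 <- qv_calibration(data.frame(contig_id = "*", base = "A",
                                  run_length = 1L, qv = 0))
  ctx0 <- list(base_ref = "A", run_length_ref = 1L, base_alt = "A",
               run_length_alt = 1L)
  expect_equal(contig_error_probability(c0, ctx0, "h"), 1)

  # run length clamps to the maximum bin
  ctx_long <- list(base_ref = "A", run_length_ref = 25L, base_alt = "A",
                   run_length_alt = 25L)
  expect_equal(contig_error_probability(calib, ctx_long, "h"), 1e-1)

  # missing contig without fallback errors
  cnofb <- qv_calibration(data.frame(contig_id = "h1", base = "A",
                                     run_length = 1L, qv = 30))
  expect_error(contig_error_probability(cnofb, ctx0, "h2"), "fallback")

  # monotonicity: raising either QV never increases p
  set.seed(1)
  for (i in 1:20) {
    q1 <- runif(1, 0, 60); q2 <- runif(1, 0, 60); bump <- runif(1, 0, 20)
    mk <- function(qr, qa) {
      cal <- qv_calibration(data.frame(
        contig_id = "*", base = c("A", "C"), run_length = 1L,
        qv = c(qr, qa)))
      contig_error_probability(cal, list(base_ref = "A",
                                         run_length_ref = 1L,
                                         base_alt = "C",
                                         run_length_alt = 1L), "h")
    }
    expect_lte(mk(q1 + bump, q2), mk(q1, q2))
    expect_lte(mk(q1, q2 + bump), mk(q1, q2))
  }
})

test_that("homopolymer context measures runs on both sequence contexts", {
  ref <- paste0("GCGT", "AAAA", "TCGG")
  # deletion of one A: ref run 4, alt run 3
  ctx <- homopolymer_context(data.frame(contig = "c", pos = 3L,
                                        ref = "TA", alt = "T",
                                        source_haplotype = "h"), ref)
  expect_equal(ctx$base_ref, "A")
  expect_equal(ctx$run_length_ref, 4L)
  expect_equal(ctx$run_length_alt, 3L)
  # insertion of one A: ref run 4, alt run 5
  ctx2 <- homopolymer_context(data.frame(contig = "c", pos = 3L,
                                         ref = "T", alt = "TA",
                                         source_haplotype = "h"), ref)
  expect_equal(ctx2$run_length_ref, 4L)
  expect_equal(ctx2$run_length_alt, 5L)
  # SNV in non-homopolymer context: both runs 1
  ctx3 <- homopolymer_context(data.frame(contig = "c", pos = 1L,
                                         ref = "C", alt = "T",
                                         source_haplotype = "h"), ref)
  expect_equal(ctx3$run_length_ref, 1L)
  # T alt at position 2 joins the T at position 4? no: GTGT... stays 1
  expect_equal(ctx3$run_length_alt, 1L)
})

test_that("vqv matches the Phred transform of the exact binomial tail", {
  expect_equal(vqv(0, 10, 1e-3), 0)
  expect_equal(vqv(2, 2, 1e-3), 60, tolerance = 1e-9)
  expect_equal(vqv(1, 1, 1e-10), 100, tolerance = 1e-9)
  expect_equal(vqv(1, 1, 1e-5), 50, tolerance = 1e-9)
  expect_error(vqv(3, 2, 0.1), "supporting")
  expect_error(vqv(1, 2, 0), "p_err")

  # oracle equivalence for covering <= 12
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- 10^runif(1, -6, 0)
    expected <- if (k == 0) 0 else -10 * log10(oracle_binom_tail(k, n, p))
    expect_equal(vqv(k, n, p), expected, tolerance = 1e-9)
  }

  # monotonicity: non-increasing in p_err, non-decreasing in supporting
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    k <- sample(1:n, 1)
    p <- 10^runif(1, -6, -0.5)
    expect_gte(vqv(k, n, p / 2), vqv(k, n, p))
    if (k < n) expect_gte(vqv(k + 1, n, p), vqv(k, n, p))
  }
})

test_that("filtering applies inclusive per-level thresholds", {
  mk <- function(level, vqv) data.frame(
    contig = "c", pos = 1L, ref = "A", alt = "T",
    source_haplotype = "h", level = level, flags = "", vqv = vqv)
  vs <- rbind(mk("A", 99.9), mk("A", 100), mk("T", 50), mk("T", 49.9))
  out <- filter_variants(vs)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE, FALSE))
  kept <- filter_variants(vs, drop = TRUE)
  expect_equal(nrow(kept), 2L)

  expect_equal(nrow(filter_variants(mk("A", 5)[0, ])), 0L)
  expect_error(filter_variants(mk("Z", 10)), "threshold")

  # indel-only mode lets substitutions through
  out2 <- filter_variants(mk("A", 10), vqv_indels_only = TRUE)
  expect_true(out2$retained)
})

test_that("pooled panel VQV separates shared true variants from singletons", {
  panel <- random_panel(5, K = 3)
  inj <- inject_homopolymer_errors(panel, seed = 6)
  alns <- panel_alignments(panel, inj$edits)
  var_list <- lapply(alns, function(a)
    call_variants_from_alignment(a, panel$reference, panel$window))
  names(var_list) <- vapply(alns, function(a) a$qname, "")
  pooled <- pool_panel_variants(var_list, inj$calibration,
                                panel$reference)
  expect_true(all(pooled$covering == length(alns)))
  # every planted truth variant appears with supporting = cluster count
  tt <- panel$truth
  for (i in seq_len(nrow(tt))) {
    hit <- pooled[pooled$pos == tt$pos[i] & pooled$ref == tt$ref[i] &
                    pooled$alt == tt$alt[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$supporting,
                 sum(panel$cluster_of == tt$cluster[i]))
  }
})
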