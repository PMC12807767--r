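## Seeded generators for every input the pipeline consumes: toy gene
## models with homopolymer tracts, haplotype panels with controlled
## frequency spectra and level-tagged planted variants, homopolymer error
## injection with a matched QV calibration table, and diploid cohorts with
## planted expression effects.
##
## All generators take a mandatory seed and are bit-reproducible; RNG
## state is scoped locally (the caller's stream is untouched).

stop_free_codons <- c("CTG", "GCT", "AAG", "TTC", "GAC", "ATC")

#' Generate a toy transcript model and its reference sequence
#'
#' Builds one gene on a synthetic contig: \code{flank} bp of upstream
#' sequence, exons interleaved with introns, \code{flank} bp downstream.
#' For coding genes the CDS is \code{ATG} + \code{cds_codons - 2} body
#' codons (all \code{CTG}, i.e. leucine, so that third-base changes are
#' synonymous and second-base changes are missense) + \code{TAA}.
#' Homopolymer tracts of configurable length are written into the CDS
#' (codon-aligned lysine run) and into the first intron, providing
#' realistic indel-error substrate.
#'
#' @param n_exons number of exons (>= 1).
#' @param cds_codons total codons including start and stop (0 for a
#'   non-coding gene).
#' @param utr_lens integer pair: 5' and 3' UTR lengths (for non-coding
#'   genes the total exonic length is their sum plus \code{3*cds_codons}).
#' @param intron_len length of each intron.
#' @param flank flank length generated on both sides (use the same value
#'   when partitioning).
#' @param strand \code{"+"} or \code{"-"}.
#' @param hp_cds,hp_intron homopolymer tract lengths (0 disables; CDS
#'   tract is rounded down to a codon multiple).
#' @param seed mandatory integer seed.
#' @param gene_symbol,transcript_id,contig identifiers.
#' @return list with \code{model} (a [transcript_model()]) and
#'   \code{reference} (contig sequence string; coordinate 0 = string
#'   position 1).
#' @export
make_gene_model <- function(n_exons = 2L, cds_codons = 40L,
                            utr_lens = c(30L, 30L), intron_len = 60L,
                            flank = 200L, strand = "+",
                            hp_cds = 6L, hp_intron = 8L, seed,
                            gene_symbol = "TOY1",
                            transcript_id = "NM_TOY001",
                            contig = "chrS") {
  if (missing(seed)) stop("seed is mandatory")
  if (n_exons < 1L) stop("need >= 1 exon")
  coding <- cds_codons > 0L
  if (coding && cds_codons < 3L) stop("coding gene needs >= 3 codons")
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  rand_nt <- function(n) if (n <= 0L) "" else
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

  ## transcript-strand gene sequence, tracking exon/CDS spans in
  ## transcript coordinates (0-based within gene body)
  if (coding) {
    body_n <- cds_codons - 2L
    body <- rep("CTG", body_n)
    if (hp_cds >= 3L && body_n > 2L * (hp_cds %/% 3L)) {
      k <- hp_cds %/% 3L
      at <- max(2L, body_n %/% 2L)
      body[at:(at + k - 1L)] <- "AAA"
    }
    cds_seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
  } else cds_seq <- ""
  cds_len <- nchar(cds_seq)
  exonic_len <- utr_lens[1] + cds_len + utr_lens[2]
  ## split exonic sequence into n_exons chunks of roughly equal size
  cuts <- unique(round(seq(0L, exonic_len, length.out = n_exons + 1L)))
  if (length(cuts) != n_exons + 1L)
    stop("exonic span too short for ", n_exons, " exons")
  exonic_seq <- paste0(rand_nt(utr_lens[1]), cds_seq, rand_nt(utr_lens[2]))

  pieces <- character(0)
  exon_tx <- matrix(0L, nrow = n_exons, ncol = 2)  # tx coords
  gpos <- 0L
  exon_g <- matrix(0L, nrow = n_exons, ncol = 2)   # gene-body coords
  for (i in seq_len(n_exons)) {
    s <- cuts[i]; e <- cuts[i + 1L]
    exon_tx[i, ] <- c(s, e)
    ex_seq <- substr(exonic_seq, s + 1L, e)
    pieces <- c(pieces, ex_seq)
    exon_g[i, ] <- c(gpos, gpos + (e - s))
    gpos <- gpos + (e - s)
    if (i < n_exons) {
      intr <- rand_nt(intron_len)
      if (hp_intron >= 2L && i == 1L && intron_len > hp_intron + 4L) {
        at <- (intron_len - hp_intron) %/% 2L
        substr(intr, at + 1L, at + hp_intron) <-
          strrep("T", hp_intron)
      }
      ## keep run boundaries crisp so indel left-alignment stays inside
      pieces <- c(pieces, intr)
      gpos <- gpos + intron_len
    }
  }
  gene_tx_seq <- paste(pieces, collapse = "")
  gene_len <- nchar(gene_tx_seq)

  ## map transcript-strand gene sequence onto the genome
  gene_gen_seq <- if (strand == "+") gene_tx_seq else revcomp(gene_tx_seq)
  reference <- paste0(rand_nt(flank), gene_gen_seq, rand_nt(flank))
  gb_start <- flank

  tx2gen <- function(s, e) {
    if (strand == "+") c(gb_start + s, gb_start + e)
    else c(gb_start + gene_len - e, gb_start + gene_len - s)
  }
  ex_iv <- t(apply(exon_g, 1L, function(r) tx2gen(r[1], r[2])))
  exons <- intervals(ex_iv[, 1], ex_iv[, 2])
  cds <- intervals()
  if (coding) {
    cds_tx <- c(utr_lens[1], utr_lens[1] + cds_len)  # exonic coords
    ## intersect CDS exonic span with exons, mapped through introns
    cds_iv <- list()
    for (i in seq_len(n_exons)) {
      s <- max(exon_tx[i, 1], cds_tx[1]); e <- min(exon_tx[i, 2], cds_tx[2])
      if (s < e) {
        off <- exon_g[i, 1] - exon_tx[i, 1]   # exonic -> gene-body shift
        cds_iv[[length(cds_iv) + 1L]] <- tx2gen(s + off, e + off)
      }
    }
    m <- do.call(rbind, cds_iv)
    cds <- intervals(m[, 1], m[, 2])
  }
  model <- transcript_model(gene_symbol, transcript_id, contig, strand,
                            exons, cds)
  list(model = model, reference = toupper(reference))
}

#' Panel specification for the synthetic haplotype generator
#'
#' @param n_haploids panel size (haploid observations; default 30, a
#'   desk-scale stand-in for a few hundred genomes).
#' @param frequency_spectrum cluster proportions summing to 1 (default a
#'   decreasing 4-haplotype spectrum).
#' @param variants_per_level named map level -> number of distinguishing
#'   variants planted per non-reference haplotype.
#' @param seed mandatory integer seed.
#' @return list of class \code{PanelSpec}.
#' @export
panel_spec <- function(n_haploids = 30L,
                       frequency_spectrum = c(0.5, 0.25, 0.15, 0.10),
                       variants_per_level = c(A = 1L, C = 1L, T = 1L,
                                              G = 1L, U = 0L, D = 0L),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(frequency_spectrum) - 1) > 1e-9)
    stop("frequency_spectrum must sum to 1")
  if (any(frequency_spectrum <= 0)) stop("proportions must be in (0, 1]")
  structure(list(n_haploids = as.integer(n_haploids),
                 frequency_spectrum = frequency_spectrum,
                 variants_per_level = variants_per_level, seed = seed),
            class = "PanelSpec")
}

## largest-remainder apportionment of n among proportions p
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

## candidate SNV sites per level for a toy model; positions are genomic
## 0-based, each with ref and alt base chosen to realize the level
level_snv_sites <- function(model, part, reference) {
  sites <- list(A = list(), C = list(), T = list(), G = list(),
                U = list(), D = list())
  cds_ref <- region_sequence(model$cds, reference, 0L, model$strand)
  ## genomic position of the k-th CDS base (transcript order, 0-based)
  cds_pos <- cds_positions(model)
  n_codon <- nchar(cds_ref) %/% 3L
  if (n_codon > 2L) {
    for (i in 2:(n_codon - 1L)) {
      codon <- substr(cds_ref, 3L * i - 2L, 3L * i)
      if (codon != "CTG") next
      sites$A[[length(sites$A) + 1L]] <-
        list(tx = 3L * (i - 1L) + 1L, alt_tx = "A")  # CTG -> CAG (Gln)
      sites$C[[length(sites$C) + 1L]] <-
        list(tx = 3L * (i - 1L) + 2L, alt_tx = "A")  # CTG -> CTA (Leu)
    }
  }
  conv <- function(lst) lapply(lst, function(s) {
    gp <- cds_pos[s$tx + 1L]
    alt <- if (model$strand == "+") s$alt_tx else revcomp(s$alt_tx)
    list(pos = gp, ref = substr(reference, gp + 1L, gp + 1L), alt = alt)
  })
  sites$A <- conv(sites$A); sites$C <- conv(sites$C)

  plain_sites <- function(iv) {
    out <- list()
    if (is.null(dim(iv))) iv <- data.frame(start = iv[1], end = iv[2])
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] - 3L < iv$start[i] + 2L) next
      ps <- seq.int(iv$start[i] + 2L, iv$end[i] - 3L, by = 4L)
      for (p in ps) {
        b <- substr(reference, p + 1L, p + 1L)
        ## skip homopolymer interiors so SNVs stay unambiguous
        if (run_length_at(reference, p + 1L) > 2L) next
        alt <- setdiff(c("A", "C", "G", "T"), c(
          b, substr(reference, p, p), substr(reference, p + 2L, p + 2L)))[1]
        out[[length(out) + 1L]] <- list(pos = p, ref = b, alt = alt)
      }
    }
    out
  }
  sites$T <- c(plain_sites(part$utr5), plain_sites(part$utr3))
  sites$G <- plain_sites(part$introns)
  sites$U <- plain_sites(part$upstream)
  sites$D <- plain_sites(part$downstream)
  sites
}

## genomic 0-based positions of CDS bases in transcript order
cds_positions <- function(model) {
  pos <- integer(0)
  for (i in seq_len(nrow(model$cds)))
    pos <- c(pos, seq.int(model$cds$start[i], model$cds$end[i] - 1L))
  if (model$strand == "-") rev(pos) else pos
}

#' Generate a haplotype panel with a controlled frequency spectrum
#'
#' Haplotype cluster 1 is the reference sequence; each further cluster is
#' distinguished by its own planted SNVs — \code{variants_per_level[lv]}
#' variants at each level — so every cluster is distinct at every level
#' with a positive variant budget.  Cluster multiplicities follow the
#' frequency spectrum (largest-remainder apportionment of
#' \code{n_haploids}).
#'
#' @param gene a [make_gene_model()] result.
#' @param spec a [panel_spec()].
#' @param flank flank used for the region partition (must not exceed the
#'   flank the reference was generated with).
#' @return list with \code{sequences} (named haploid -> window sequence),
#'   \code{window} (genomic coords), \code{edits} (per-haploid planted
#'   variant tables), \code{truth} (planted variant table with intended
#'   levels), \code{cluster_of} (haploid -> cluster index),
#'   \code{counts} (per-cluster multiplicities), \code{model},
#'   \code{partition}, \code{reference}.
#' @export
make_panel <- function(gene, spec, flank = 200L) {
  model <- gene$model; reference <- gene$reference
  part <- partition_regions(model, flank)
  w <- partition_window(part)
  if (w[1] < 0L || w[2] > nchar(reference))
    stop("flank exceeds generated reference margins")
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  K <- length(spec$frequency_spectrum)
  sites <- level_snv_sites(model, part, reference)
  vpl <- spec$variants_per_level
  need <- (K - 1L) * vpl
  for (lv in names(vpl))
    if (vpl[[lv]] > 0L && length(sites[[lv]]) < need[[lv]])
      stop("not enough placeable ", lv, "-level sites: need ", need[[lv]],
           ", have ", length(sites[[lv]]))

  truth <- list()
  cluster_vars <- vector("list", K)
  cluster_vars[[1]] <- empty_variants()
  used <- setNames(rep(0L, length(vpl)), names(vpl))
  for (k in seq_len(K)[-1]) {
    vs <- list()
    for (lv in names(vpl)) {
      nv <- vpl[[lv]]
      if (nv == 0L) next
      take <- sites[[lv]][(used[[lv]] + 1L):(used[[lv]] + nv)]
      used[[lv]] <- used[[lv]] + nv
      for (s in take) {
        vs[[length(vs) + 1L]] <- new_variant(model$contig, s$pos, s$ref,
                                             s$alt, NA_character_)
        truth[[length(truth) + 1L]] <- cbind(
          new_variant(model$contig, s$pos, s$ref, s$alt, NA_character_),
          data.frame(cluster = k, level = lv, stringsAsFactors = FALSE))
      }
    }
    cluster_vars[[k]] <- if (length(vs)) do.call(rbind, vs)
                         else empty_variants()
  }

  counts <- apportion(spec$n_haploids, spec$frequency_spectrum)
  if (any(counts == 0L))
    stop("spectrum cell with zero haploids at n = ", spec$n_haploids)
  cluster_of <- rep.int(seq_len(K), counts)
  hap_ids <- sprintf("H%03d", seq_len(spec$n_haploids))
  names(cluster_of) <- hap_ids

  seqs <- vapply(cluster_of, function(k)
    apply_variants_interval(reference, 0L, w[1], w[2],
                            cluster_vars[[k]]), character(1))
  names(seqs) <- hap_ids
  edits <- lapply(cluster_of, function(k) {
    v <- cluster_vars[[k]]
    v[order(v$pos), , drop = FALSE]
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    cbind(empty_variants(), data.frame(cluster = integer(0),
                                       level = character(0)))
  list(sequences = seqs, window = w, edits = edits, truth = truth,
       cluster_of = cluster_of, counts = counts, model = model,
       partition = part, reference = reference)
}

#' Inject homopolymer indel errors and emit the matched QV calibration
#'
#' For every maximal homopolymer run of tabulated length in every
#' sequence, a single-base insertion or deletion (equal odds) is injected
#' with the per-run-length probability from \code{rate_map}.  The emitted
#' calibration satisfies \code{QV = -10 log10(rate)} at tabulated run
#' lengths; untabulated (shorter) contexts get \code{base_qv}, the
#' assembly consensus base quality.
#'
#' @param panel a [make_panel()] result.
#' @param rate_map named numeric vector: run length -> error probability
#'   in [0, 1).  Default emulates homopolymer-length-dependent consensus
#'   indel error of HiFi contigs.
#' @param seed mandatory integer seed.
#' @param base_qv QV for untabulated contexts (default 50).
#' @param min_run shortest run considered (derived from rate_map).
#' @return list with \code{sequences} (corrupted), \code{edits} (per
#'   haploid: planted + injected variant tables), \code{artifacts}
#'   (injected-variant truth table with haploid ids), \code{calibration}
#'   (a [qv_calibration()]).
#' @export
inject_homopolymer_errors <- function(panel,
                                      rate_map = c(`4` = 1e-3, `5` = 2e-3,
                                                   `6` = 5e-3, `7` = 1e-2,
                                                   `8` = 2e-2),
                                      seed, base_qv = 50) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(rate_map < 0 | rate_map >= 1)) stop("rates must be in [0, 1)")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lens <- as.integer(names(rate_map))
  min_run <- min(lens); max_run <- max(lens)
  w <- panel$window
  ref <- panel$reference

  artifacts <- list()
  edits <- panel$edits
  for (h in names(panel$sequences)) {
    ## runs are located on the *reference* so injected variants are
    ## expressed in reference coordinates like planted ones
    rl <- rle(strsplit(win_substr(ref, 0L, w[1], w[2]), "")[[1]])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hap_edits <- edits[[h]]
    occupied <- if (nrow(hap_edits)) hap_edits$pos else integer(0)
    for (i in seq_along(rl$lengths)) {
      L <- rl$lengths[i]
      if (L < min_run) next
      ## nearest tabulated bin at or below L (clamped to the max bin)
      bin <- max(lens[lens <= min(L, max_run)])
      rate <- rate_map[[as.character(bin)]]
      if (runif(1) >= rate) next
      run_start <- w[1] + starts[i] - 1L       # genomic 0-based
      if (run_start == 0L) next
      anchor_pos <- run_start - 1L
      if (any(abs(occupied - anchor_pos) < 3L)) next
      b <- rl$values[i]
      anchor <- substr(ref, anchor_pos + 1L, anchor_pos + 1L)
      if (runif(1) < 0.5) {                     # deletion of one base
        v <- new_variant(panel$model$contig, anchor_pos,
                         paste0(anchor, b), anchor, h)
      } else {                                  # insertion of one base
        v <- new_variant(panel$model$contig, anchor_pos, anchor,
                         paste0(anchor, b), h)
      }
      hap_edits <- rbind(hap_edits, v)
      occupied <- c(occupied, anchor_pos)
      artifacts[[length(artifacts) + 1L]] <- v
    }
    edits[[h]] <- hap_edits[order(hap_edits$pos), , drop = FALSE]
  }
  seqs <- vapply(names(panel$sequences), function(h)
    apply_variants_interval(ref, 0L, w[1], w[2], edits[[h]]),
    character(1))
  calib_rows <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(b) {
    data.frame(contig_id = "*", base = b,
               run_length = c(1L, lens),
               qv = c(base_qv, -10 * log10(pmax(rate_map,
                                                10^(-base_qv / 10)))),
               stringsAsFactors = FALSE)
  }))
  list(sequences = seqs, edits = edits,
       artifacts = if (length(artifacts)) do.call(rbind, artifacts) else
         empty_variants(),
       calibration = qv_calibration(calib_rows))
}

#' Turn panel sequences into contig alignments
#'
#' Builds the CIGAR of each haploid contig against the reference window
#' from its known edit list (planted variants plus injected errors), so
#' tests exercise the same alignment path as real SAM input.
#'
#' @param panel a [make_panel()] result.
#' @param edits per-haploid edit tables (default: the panel's planted
#'   edits; pass the \code{edits} of [inject_homopolymer_errors()] for
#'   corrupted contigs).
#' @return list of [contig_alignment()] objects.
#' @export
panel_alignments <- function(panel, edits = panel$edits) {
  lapply(names(panel$sequences), function(h)
    edits_to_alignment(edits[[h]], panel$window, panel$reference,
                       panel$model$contig, h))
}

## build a contig alignment spanning [w1, w2) from a sorted,
## non-overlapping edit table (SNVs ride inside M; indels emit I/D)
edits_to_alignment <- function(ed, w, reference, contig, qname) {
  cig <- list(); cur <- w[1]
  if (nrow(ed)) for (i in seq_len(nrow(ed))) {
    e <- variant_edit(ed[i, ])
    if (e$rs > cur) cig[[length(cig) + 1L]] <- c(e$rs - cur, "M")
    nins <- nchar(e$repl); ndel <- e$re - e$rs
    if (ndel == 1L && nins == 1L) cig[[length(cig) + 1L]] <- c(1L, "M")
    else {
      if (ndel > 0L) cig[[length(cig) + 1L]] <- c(ndel, "D")
      if (nins > 0L) cig[[length(cig) + 1L]] <- c(nins, "I")
    }
    cur <- e$re
  }
  if (w[2] > cur) cig[[length(cig) + 1L]] <- c(w[2] - cur, "M")
  lens <- as.integer(vapply(cig, `[`, "", 1L))
  ops <- vapply(cig, `[`, "", 2L)
  keep_l <- integer(0); keep_o <- character(0)
  for (i in seq_along(ops)) {
    if (length(keep_o) && keep_o[length(keep_o)] == ops[i])
      keep_l[length(keep_l)] <- keep_l[length(keep_l)] + lens[i]
    else { keep_l <- c(keep_l, lens[i]); keep_o <- c(keep_o, ops[i]) }
  }
  seq <- apply_variants_interval(reference, 0L, w[1], w[2], ed)
  contig_alignment(qname, contig, w[1],
                   paste0(keep_l, keep_o, collapse = ""), seq)
}

#' Effect specification for synthetic expression cohorts
#'
#' @param level target haplotype level.
#' @param target_id catalog haplotype id carrying the effect.
#' @param beta additive per-allele effect in noise-SD units.
#' @param noise_sd residual SD of normalized expression.
#' @param n_samples per-study diploid sample counts (default a three-panel
#'   design of unequal sizes, echoing typical LCL expression panels at
#'   desk scale).
#' @param baseline intercept of normalized expression.
#' @return list of class \code{EffectSpec}.
#' @export
effect_spec <- function(level = "T", target_id = 2L, beta = 1,
                        noise_sd = 1, n_samples = c(150L, 100L, 90L),
                        baseline = 10) {
  if (beta < 0) stop("effect size must be >= 0")
  if (!length(n_samples)) stop("need >= 1 study")
  structure(list(level = level, target_id = as.integer(target_id),
                 beta = beta, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), baseline = baseline),
            class = "EffectSpec")
}

#' Simulate diploid cohorts and expression with a planted haplotype effect
#'
#' Each study independently draws diploid samples by random pairing of
#' haplotypes from the catalog's level frequencies, then sets expression
#' to \code{baseline + beta * dosage(target haplotype) + N(0, noise_sd)}.
#' Per-study seeds are derived from the master seed so studies are
#' independent but jointly reproducible.
#'
#' @param catalog a [build_catalog()] result.
#' @param effect an [effect_spec()].
#' @param seed mandatory master seed.
#' @return list of studies; each has \code{study_id}, \code{expression}
#'   (named vector), \code{diplotypes} (sample, hap1, hap2) and
#'   \code{dosage}.
#' @export
make_cohort_and_expression <- function(catalog, effect, seed) {
  if (missing(seed)) stop("seed is mandatory")
  df <- catalog$levels[[effect$level]]
  if (nrow(df) < 2L) stop("catalog has < 2 haplotypes at level ",
                          effect$level)
  if (!effect$target_id %in% df$id)
    stop("target id ", effect$target_id, " absent at level ",
         effect$level)
  freq <- df$count / sum(df$count)
  lapply(seq_along(effect$n_samples), function(s) {
    old <- local_seed(as.integer((as.numeric(seed) * 131 + s) %%
                                   2147483647))
    on.exit(restore_seed(old))
    n <- effect$n_samples[s]
    h1 <- sample(df$id, n, replace = TRUE, prob = freq)
    h2 <- sample(df$id, n, replace = TRUE, prob = freq)
    ids <- sprintf("S%d_%04d", s, seq_len(n))
    dosage <- (h1 == effect$target_id) + (h2 == effect$target_id)
    expr <- effect$baseline + effect$beta * dosage +
      rnorm(n, 0, effect$noise_sd)
    names(expr) <- ids
    list(study_id = paste0("study", s), expression = expr,
         diplotypes = data.frame(sample = ids, hap1 = h1, hap2 = h2,
                                 stringsAsFactors = FALSE),
         dosage = dosage)
  })
}
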