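## Catalog-level diversity statistics: Good-Turing coverage, Chao1
## completeness, seeded subsampling, length-normalized z-scores and small
## regression summaries.

check_counts <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts)) stop("empty count vector")
  if (any(counts < 1L)) stop("cluster counts must be >= 1")
  counts
}

#' Good-Turing cover ratio of a haplotype catalog
#'
#' The probability that a newly sampled haplotype matches one already
#' registered: \code{1 - f1/N}, with \code{f1} the number of singleton
#' clusters and \code{N} the number of haploids observed.
#'
#' @param counts integer vector of cluster counts (one per distinct
#'   haplotype).
#' @return ratio in [0, 1].
#' @export
good_turing_cover <- function(counts) {
  counts <- check_counts(counts)
  1 - sum(counts == 1L) / sum(counts)
}

#' Chao1 richness and completeness of a haplotype catalog
#'
#' Richness is the classical Chao1 estimate
#' \code{S_obs + f1^2/(2 f2)} when doubletons exist, and the bias-corrected
#' \code{S_obs + f1 (f1 - 1) / (2 (f2 + 1))} when \code{f2 = 0}.
#' Completeness is \code{S_obs / richness}: the fraction of the predicted
#' total haplotype pool already catalogued.
#'
#' @inheritParams good_turing_cover
#' @param bias_corrected always use the bias-corrected form (default only
#'   when \code{f2 = 0}).
#' @return list with \code{richness} and \code{completeness}.
#' @export
chao1_completeness <- function(counts, bias_corrected = FALSE) {
  counts <- check_counts(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  richness <- if (f2 > 0L && !bias_corrected)
    s_obs + f1^2 / (2 * f2)
  else
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  list(richness = richness, completeness = s_obs / richness)
}

#' Median distinct-haplotype count under seeded subsampling
#'
#' Draws \code{n_haploids} haploid observations without replacement from
#' the catalog's count vector, \code{reps} times, and returns the median
#' number of distinct clusters hit.  This is the standard control for
#' unequal per-gene sample sizes (subsample to a common haploid depth).
#'
#' @inheritParams good_turing_cover
#' @param n_haploids subsample size (default 200).
#' @param reps number of replicates (default 100).
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return median distinct-cluster count over replicates.
#' @export
subsample_median_count <- function(counts, n_haploids = 200L, reps = 100L,
                                   seed) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (n < n_haploids)
    stop("panel has ", n, " haploids < subsample size ", n_haploids)
  if (missing(seed)) stop("seed is mandatory")
  pool <- rep.int(seq_along(counts), counts)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  vals <- vapply(seq_len(reps), function(i)
    length(unique(pool[sample.int(n, n_haploids)])), integer(1))
  median(vals)
}

## seed scoping helpers: set the RNG locally, restore global state after
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Length-normalized diversity z-scores
#'
#' For each gene, \code{x = log2(count / length)}; z-scores standardize x
#' across genes within one level (sample standard deviation).  Genes with
#' unusually low or high haplotype diversity for their length sit in the
#' tails.
#'
#' @param summaries data frame with columns \code{gene}, \code{count}
#'   (median subsampled haplotype count), \code{length} (level-specific
#'   sequence length, bp).
#' @param level level label attached to the output.
#' @return data frame (gene, level, median_subsampled_count, level_length,
#'   z).
#' @export
length_normalized_z <- function(summaries, level = "A") {
  if (nrow(summaries) < 2L) stop("need >= 2 genes")
  if (any(summaries$length <= 0)) stop("lengths must be > 0")
  if (any(summaries$count <= 0)) stop("counts must be > 0")
  x <- log2(summaries$count / summaries$length)
  s <- sd(x)
  if (s == 0) stop("zero variance across genes; z undefined")
  data.frame(gene = summaries$gene, level = level,
             median_subsampled_count = summaries$count,
             level_length = as.integer(summaries$length),
             z = (x - mean(x)) / s, stringsAsFactors = FALSE)
}

#' Reference level-specific sequence lengths of a gene model
#'
#' A = 3 x protein length (CDS minus stop), C = CDS nt, T = exonic
#' non-coding nt, G = intron nt, measured on the reference haplotype.
#'
#' @param model a [transcript_model()].
#' @param partition matching [partition_regions()].
#' @return named integer vector with elements A, C, T, G.
#' @export
level_lengths <- function(model, partition) {
  cds_len <- iv_width(model$cds)
  c(A = if (cds_len >= 3L) cds_len - 3L else 0L,
    C = cds_len,
    T = iv_width(partition$utr5) + iv_width(partition$utr3),
    G = iv_width(partition$introns))
}

#' Fraction of genes covered in at least a threshold number of samples
#'
#' @param per_gene_sample_counts named integer vector gene -> number of
#'   fully resolved samples.
#' @param thresholds integer thresholds.
#' @param chrom_class optional character vector (parallel to the counts)
#'   of chromosome classes, e.g. autosome/chrX/chrY; results are
#'   stratified by it.
#' @return data frame (chrom_class, threshold, n_genes, fraction).
#' @export
coverage_summary <- function(per_gene_sample_counts,
                             thresholds = c(1L, 50L, 100L, 200L),
                             chrom_class = NULL) {
  n <- length(per_gene_sample_counts)
  if (is.null(chrom_class)) chrom_class <- rep("all", n)
  out <- list()
  for (cls in unique(chrom_class)) {
    v <- per_gene_sample_counts[chrom_class == cls]
    for (th in thresholds)
      out[[length(out) + 1L]] <- data.frame(
        chrom_class = cls, threshold = th, n_genes = length(v),
        fraction = mean(v >= th), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Ordinary least squares slope and R-squared
#'
#' Small helper for the length-versus-coverage and length-versus-count
#' summaries.
#'
#' @param x,y numeric vectors (>= 3 points, non-degenerate x).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
length_count_regression <- function(x, y) {
  if (length(x) < 3L) stop("need >= 3 points")
  if (sd(x) == 0) stop("degenerate x")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Per-level diversity summary of a haplotype catalog
#'
#' Convenience wrapper: cover ratio, Chao1 richness/completeness and the
#' seeded subsampled median count per level of one catalog.
#'
#' @param catalog a [build_catalog()] result.
#' @param n_haploids,reps,seed passed to [subsample_median_count()]
#'   (skipped, with NA, when the panel is smaller than \code{n_haploids}).
#' @return data frame (gene, level, n_haploids, s_obs, cover_ratio,
#'   chao1_richness, completeness, median_subsampled_count).
#' @export
catalog_diversity <- function(catalog, n_haploids = 200L, reps = 100L,
                              seed = 1L) {
  rows <- lapply(c("A", "C", "T", "G"), function(lv) {
    df <- catalog$levels[[lv]]
    if (!nrow(df)) return(NULL)
    cnt <- df$count
    ch <- chao1_completeness(cnt)
    med <- if (sum(cnt) >= n_haploids)
      subsample_median_count(cnt, n_haploids, reps, seed = seed)
    else NA_real_
    data.frame(gene = catalog$gene, level = lv, n_haploids = sum(cnt),
               s_obs = length(cnt),
               cover_ratio = good_turing_cover(cnt),
               chao1_richness = ch$richness,
               completeness = ch$completeness,
               median_subsampled_count = med, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
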