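## Diplotype-based haplotype-expression association testing with
## cross-study effect-direction concordance, boxplot-style pairwise group
## contrasts.

#' Canonical key of an unordered diplotype
#'
#' @param hap1,hap2 positive haplotype ids.
#' @return string like \code{"1/2"} with the smaller id first.
#' @export
diplotype_key <- function(hap1, hap2) {
  if (any(hap1 < 1L) || any(hap2 < 1L)) stop("haplotype ids must be >= 1")
  paste(pmin(hap1, hap2), pmax(hap1, hap2), sep = "/")
}

#' Construct an expression study
#'
#' One study holds normalized expression for one gene and the
#' sample-to-diplotype map at one haplotype level.  Every tested sample
#' must have both an expression value and a diplotype.
#'
#' @param study_id study label.
#' @param expression named numeric vector sample -> normalized expression.
#' @param diplotypes data frame with columns \code{sample}, \code{hap1},
#'   \code{hap2}.
#' @param level haplotype level label (A, C, T, AC, ACT).
#' @return object of class \code{ExpressionStudy}.
#' @export
expression_study <- function(study_id, expression, diplotypes,
                             level = "T") {
  miss <- setdiff(diplotypes$sample, names(expression))
  if (length(miss))
    stop("samples without expression: ", paste(head(miss, 5),
                                               collapse = ", "))
  diplotypes$key <- diplotype_key(diplotypes$hap1, diplotypes$hap2)
  structure(list(study_id = study_id, expression = expression,
                 diplotypes = diplotypes, level = level),
            class = "ExpressionStudy")
}

#' Partition a study's samples by unordered diplotype
#'
#' @param study an [expression_study()].
#' @return named list diplotype key -> character vector of sample ids.
#' @export
group_samples <- function(study) {
  if (!nrow(study$diplotypes)) return(structure(list(), names = character(0)))
  split(study$diplotypes$sample, study$diplotypes$key)
}

#' Pairwise expression contrast between two diplotype groups
#'
#' Default test is the two-sided Wilcoxon rank-sum test (Welch t as
#' alternative); fold change is \code{mean(b)/mean(a)} on the normalized
#' scale (or the median ratio); direction is the sign of the group mean
#' (or median) difference.
#'
#' @param group_a_expr,group_b_expr numeric expression vectors.
#' @param test \code{"wilcoxon"} or \code{"welch"}.
#' @param fold_change \code{"mean"} or \code{"median"} ratio.
#' @return list with \code{fold_change}, \code{neg_log10_p},
#'   \code{direction} (one of \code{"a<b"}, \code{"a>b"}, \code{"tie"}).
#' @export
pairwise_test <- function(group_a_expr, group_b_expr,
                          test = c("wilcoxon", "welch"),
                          fold_change = c("mean", "median")) {
  test <- match.arg(test)
  fold_change <- match.arg(fold_change)
  ctr <- if (fold_change == "mean") mean else median
  ca <- ctr(group_a_expr); cb <- ctr(group_b_expr)
  p <- if (test == "wilcoxon")
    suppressWarnings(wilcox.test(group_a_expr, group_b_expr,
                                 alternative = "two.sided"))$p.value
  else t.test(group_a_expr, group_b_expr)$p.value
  if (is.na(p)) p <- 1
  list(fold_change = cb / ca,
       neg_log10_p = -log10(max(p, .Machine$double.xmin)),
       direction = if (ca < cb) "a<b" else if (ca > cb) "a>b" else "tie")
}

#' All pairwise diplotype contrasts of one study
#'
#' Tests every pair of diplotype groups meeting the minimum group size;
#' undersized contrasts are skipped and listed in the
#' \code{"skipped"} attribute with a reason.
#'
#' @param study an [expression_study()].
#' @param gene gene label carried into the output.
#' @param min_n minimum per-group sample count (default 3).
#' @inheritParams pairwise_test
#' @return data frame (gene, level, study, group_a, group_b, n_a, n_b,
#'   fold_change, neg_log10_p, direction).
#' @export
study_associations <- function(study, gene = "gene", min_n = 3L,
                               test = "wilcoxon", fold_change = "mean") {
  groups <- group_samples(study)
  keys <- sort(names(groups))
  rows <- list(); skipped <- list()
  if (length(keys) >= 2L) {
    for (pair in asplit(combn(keys, 2L), 2L)) {
      ka <- pair[1]; kb <- pair[2]
      na <- length(groups[[ka]]); nb <- length(groups[[kb]])
      if (na < min_n || nb < min_n) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          group_a = ka, group_b = kb,
          reason = sprintf("group size %d vs %d below min %d", na, nb,
                           min_n))
        next
      }
      pt <- pairwise_test(study$expression[groups[[ka]]],
                          study$expression[groups[[kb]]],
                          test = test, fold_change = fold_change)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, level = study$level, study = study$study_id,
        group_a = ka, group_b = kb, n_a = na, n_b = nb,
        fold_change = pt$fold_change, neg_log10_p = pt$neg_log10_p,
        direction = pt$direction, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), level = character(0),
               study = character(0), group_a = character(0),
               group_b = character(0), n_a = integer(0), n_b = integer(0),
               fold_change = numeric(0), neg_log10_p = numeric(0),
               direction = character(0))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

#' Cross-study concordance of pairwise associations
#'
#' Associations are keyed by (gene, level, group pair); keys present in
#' fewer than two studies are excluded (and reported in the
#' \code{"excluded"} attribute).  The concordance ratio is the fraction of
#' studies sharing the majority direction; \code{concordant_all} is TRUE
#' iff all non-tie directions agree.
#'
#' @param associations data frame of per-study rows as returned by
#'   [study_associations()] (rbind several studies).
#' @return data frame (gene, level, group_a, group_b, n_studies,
#'   directions, concordance_ratio, concordant_all, min_neg_log10_p,
#'   mean_fold_change).
#' @export
concordance <- function(associations) {
  key <- paste(associations$gene, associations$level, associations$group_a,
               associations$group_b, sep = "\r")
  groups <- split(seq_len(nrow(associations)), key)
  rows <- list(); excluded <- character(0)
  for (idx in groups) {
    sub <- associations[idx, , drop = FALSE]
    if (length(unique(sub$study)) < 2L) {
      excluded <- c(excluded, sprintf("%s %s %s-%s: single study",
                                      sub$gene[1], sub$level[1],
                                      sub$group_a[1], sub$group_b[1]))
      next
    }
    dirs <- sub$direction
    tab <- table(dirs)
    ratio <- max(tab) / length(dirs)
    nontie <- dirs[dirs != "tie"]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = sub$gene[1], level = sub$level[1], group_a = sub$group_a[1],
      group_b = sub$group_b[1], n_studies = length(dirs),
      directions = paste(dirs, collapse = ","),
      concordance_ratio = ratio,
      concordant_all = length(unique(nontie)) <= 1L,
      min_neg_log10_p = min(sub$neg_log10_p),
      mean_fold_change = mean(sub$fold_change), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), level = character(0),
               group_a = character(0), group_b = character(0),
               n_studies = integer(0), directions = character(0),
               concordance_ratio = numeric(0),
               concordant_all = logical(0), min_neg_log10_p = numeric(0),
               mean_fold_change = numeric(0))
  attr(out, "excluded") <- excluded
  out
}

#' Counts of concordant associations at increasing significance cutoffs
#'
#' For each level and each -log10(p) cutoff, counts associations whose
#' direction is concordant across all studies and whose weakest per-study
#' p-value still meets the cutoff.  Counts are non-increasing in the
#' cutoff.
#'
#' @param concordant a [concordance()] result.
#' @param thresholds numeric -log10(p) cutoffs (default 2..10).
#' @return data frame (level, threshold, n_associations).
#' @export
significance_table <- function(concordant, thresholds = 2:10) {
  keep <- concordant[concordant$concordant_all, , drop = FALSE]
  out <- list()
  for (lv in unique(concordant$level))
    for (th in thresholds)
      out[[length(out) + 1L]] <- data.frame(
        level = lv, threshold = th,
        n_associations = sum(keep$level == lv &
                               keep$min_neg_log10_p >= th))
  if (!length(out)) return(data.frame(level = character(0),
                                      threshold = numeric(0),
                                      n_associations = integer(0)))
  do.call(rbind, out)
}
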