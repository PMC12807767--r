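#' Published summary counts of the 258-genome haplotype release
#'
#' The nomenclature implemented here was introduced alongside a long-read
#' haplotype catalog built from 258 globally sampled genomes plus the
#' GRCh38 and CHM13v2 reference assemblies.  These printed release-summary
#' tables are carried as data so that consistency arithmetic (per-level
#' haplotype totals, chromosome-class gene totals, superpopulation genome
#' totals) can be recomputed and checked without access to the raw
#' sequencing data.
#'
#' @format a list with elements
#' \describe{
#'   \item{haplotypes_per_level}{named integer vector: distinct haplotypes
#'     catalogued at the A, C, T and G levels.}
#'   \item{haplotypes_total}{printed grand total of catalogued
#'     haplotypes.}
#'   \item{genes_by_chrom_class}{named integer vector: retained genes on
#'     autosomes, chrX and chrY.}
#'   \item{genes_total}{printed total of retained genes.}
#'   \item{genomes_by_superpopulation}{named integer vector: panel
#'     genomes per continental superpopulation (EAS, AFR, AMR, SAS,
#'     EUR).}
#'   \item{genomes_total}{printed panel size.}
#' }
#' @export
release_summary_counts <- list(
  haplotypes_per_level = c(A = 174376L, C = 300610L, T = 486288L,
                           G = 3695204L),
  haplotypes_total = 4656478L,
  genes_by_chrom_class = c(autosomal = 18319L, chrX = 831L, chrY = 44L),
  genes_total = 19194L,
  genomes_by_superpopulation = c(EAS = 130L, AFR = 50L, AMR = 44L,
                                 SAS = 25L, EUR = 9L),
  genomes_total = 258L
)
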