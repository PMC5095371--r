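#' Published peach pedigree reference counts
#'
#' Small plain-text tables bundled with the package: per-F2 de novo mutation
#' counts for the three peach pedigree groups (I and II intraspecific, III
#' interspecific), the strand-collapsed base-substitution spectra, and the
#' coding/non-coding selection tallies.  They serve as regression inputs for
#' the summary, spectrum and selection stages.
#'
#' @return `peach_mutation_counts()`: data.frame (sample, group, cross, snv,
#'   indel), one row per F2.
#' @export
peach_mutation_counts <- function() {
  utils::read.table(system.file("extdata", "peach_f2_mutation_counts.tsv",
                                package = "pedimut"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname peach_mutation_counts
#' @return `peach_spectrum_counts()`: data.frame (class, intraspecific,
#'   interspecific) over the six substitution classes.
#' @export
peach_spectrum_counts <- function() {
  utils::read.table(system.file("extdata", "peach_spectrum_counts.tsv",
                                package = "pedimut"),
                    header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname peach_mutation_counts
#' @return `peach_selection_counts()`: data.frame of region/effect tallies
#'   per cross and mutation type.
#' @export
peach_selection_counts <- function() {
  utils::read.table(system.file("extdata", "peach_selection_counts.tsv",
                                package = "pedimut"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname peach_mutation_counts
#' @return `peach_constants()`: reference constants for rate work — the
#'   effective genome length (back-solved from the published group-I rate and
#'   its confidence interval), per-group callable-coverage fractions, the
#'   genome G:C fraction, per-haplotype unique-coverage fractions and the
#'   per-group F1 haplotype diversities.
#' @export
peach_constants <- function() {
  list(genome_length = 2.2571e8,
       coverage = c(I = 0.843, II = 0.649, III = 0.769),
       gc_fraction = 0.375,
       unique_coverage = c(persica = 0.935, davidiana = 0.795),
       f1_diversity = c(I = 0.0029, II = 0.0027, III = 0.0124))
}
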