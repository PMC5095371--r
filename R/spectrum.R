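SUB_CLASSES <- c("A:T>G:C", "G:C>A:T", "A:T>T:A", "A:T>C:G",
                 "G:C>T:A", "G:C>C:G")

#' Strand-collapsed substitution class and transition flag
#'
#' The six classes pair each substitution with its reverse complement
#' (A>G and T>C are both `A:T>G:C`, etc.).  Transitions are purine<->purine
#' or pyrimidine<->pyrimidine changes.
#'
#' @param ref,alt single-base character vectors, ref != alt.
#' @return data.frame with `class` (factor over the six classes) and
#'   `transition` (logical).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # collapse onto the A/G representative strand
  flip <- ref %in% c("T", "C")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  key <- paste0(r, ">", a)
  map <- c("A>G" = "A:T>G:C", "G>A" = "G:C>A:T", "A>T" = "A:T>T:A",
           "A>C" = "A:T>C:G", "G>T" = "G:C>T:A", "G>C" = "G:C>C:G")
  cls <- map[key]
  data.frame(class = factor(cls, levels = SUB_CLASSES),
             transition = cls %in% c("A:T>G:C", "G:C>A:T"))
}

#' Tabulate the mutation spectrum
#'
#' @param x either a data.frame of base mutations with `ref`/`alt` columns
#'   (indel rows are ignored), or a named count vector over the six
#'   strand-collapsed classes.
#' @return a `spectrum_table`: counts and fractions per class plus
#'   transition/transversion event totals.
#' @export
spectrum_table <- function(x) {
  if (is.data.frame(x)) {
    snv <- x[nchar(x$ref) == 1 & nchar(x$alt) == 1, , drop = FALSE]
    cls <- classify_substitution(snv$ref, snv$alt)$class
    counts <- table(cls)
  } else {
    if (is.null(names(x)) || !all(names(x) %in% SUB_CLASSES))
      stop("count vector must be named by the six substitution classes")
    counts <- stats::setNames(rep(0, 6), SUB_CLASSES)
    counts[names(x)] <- x
  }
  counts <- as.numeric(counts[SUB_CLASSES])
  names(counts) <- SUB_CLASSES
  total <- sum(counts)
  ti <- sum(counts[c("A:T>G:C", "G:C>A:T")])
  structure(list(counts = counts,
                 fractions = if (total > 0) counts / total else counts,
                 ti_events = ti, tv_events = total - ti, total = total),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  d <- data.frame(class = names(x$counts), count = x$counts,
                  fraction = round(x$fractions, 3), row.names = NULL)
  print(d)
  cat(sprintf("transitions %d (%.3f), transversions %d (%.3f); Ti/Tv rate ratio %.2f\n",
              x$ti_events, x$ti_events / max(x$total, 1), x$tv_events,
              x$tv_events / max(x$total, 1),
              if (x$tv_events > 0) titv_rate_ratio(x) else NA))
  invisible(x)
}

#' Transition/transversion rate ratio
#'
#' Transitions arise from one substitution type against two transversion
#' types per site, so the *rate* ratio is twice the event ratio:
#' `2 * Ti events / Tv events`.
#'
#' @param spectrum a [spectrum_table()].
#' @export
titv_rate_ratio <- function(spectrum) {
  if (spectrum$tv_events == 0) stop("zero transversion events")
  2 * spectrum$ti_events / spectrum$tv_events
}

#' Composition-corrected AT-bias fold
#'
#' Rate of G:C>A:T changes per G:C site over the rate of A:T>G:C changes per
#' A:T site: `(n_GC>AT / gc) / (n_AT>GC / (1 - gc))`.
#'
#' @param spectrum a [spectrum_table()].
#' @param gc_fraction genomic G+C fraction in (0, 1).
#' @return the fold; `Inf` with a warning if there are no A:T>G:C events.
#' @export
at_bias_fold <- function(spectrum, gc_fraction) {
  stopifnot(gc_fraction > 0, gc_fraction < 1)
  gc_at <- spectrum$counts["G:C>A:T"]; at_gc <- spectrum$counts["A:T>G:C"]
  if (at_gc == 0) {
    warning("no A:T>G:C events: fold is infinite")
    return(Inf)
  }
  unname((gc_at / gc_fraction) / (at_gc / (1 - gc_fraction)))
}

#' Chi-square goodness-of-fit statistic with Yates continuity correction
#'
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` on one degree of freedom; the clamp at
#' zero keeps the statistic at 0 when all |O - E| <= 0.5.
#'
#' @param observed,expected numeric vectors of two (or more) category counts.
#' @return list with `statistic` and `p.value` (`chi^2_1` upper tail).
#' @export
yates_chisq <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ")
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum(pmax(abs(observed - expected) - 0.5, 0)^2 / expected)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Trinucleotide-context mutation rates in three registers
#'
#' Each point mutation is counted in the three triplets containing it (at
#' the start, centre and end position); backgrounds count every overlapping
#' genomic triplet.  Per-triplet rates give expected mutation counts per
#' compartment (divided by 3 so the expectations sum to the observed count
#' when the compartments partition the genome).  The CpG-context rate (a
#' mutated C with 3' G, or G with 5' C) is reported separately.
#'
#' @param mutations data.frame of base mutations (chrom, pos, ref, alt);
#'   sites without full flanking context are excluded and counted.
#' @param genome a [make_genome()] with sequence.
#' @param compartments optional named list of region data.frames
#'   (chrom, start, end) for expected counts.
#' @return a `triplet_rate_table`.
#' @export
triplet_analysis <- function(mutations, genome, compartments = NULL) {
  snv <- mutations[nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1, ,
                   drop = FALSE]
  ctx <- mutation_triplets(genome, snv$chrom, snv$pos)
  full <- !apply(is.na(ctx), 1, any)
  n_excluded <- sum(!full)
  trips <- as.vector(ctx[full, , drop = FALSE])
  all64 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3)
  mut_counts <- table(factor(trips, levels = all64))
  bg <- triplet_content(genome)[all64]
  rate <- ifelse(bg > 0, as.numeric(mut_counts) / as.numeric(bg), 0)
  names(rate) <- all64
  expected <- NULL
  if (!is.null(compartments)) {
    expected <- vapply(compartments, function(reg) {
      cbg <- triplet_content(genome, reg)[all64]
      sum(rate * as.numeric(cbg)) / 3
    }, numeric(1))
  }
  # CpG: mutated C followed by G, or mutated G preceded by C
  cen <- ctx[full, "centre"]
  is_cpg <- (snv$ref[full] == "C" & substr(cen, 3, 3) == "G") |
    (snv$ref[full] == "G" & substr(cen, 1, 1) == "C")
  dinuc <- colSums(Biostrings::dinucleotideFrequency(genome$seq))
  cpg_sites <- 2 * dinuc[["CG"]]          # C and G positions of each CpG
  structure(list(
    table = data.frame(triplet = all64, mut_count = as.numeric(mut_counts),
                       background = as.numeric(bg), rate = rate,
                       row.names = NULL),
    expected = expected, n_mutations = sum(full), n_excluded = n_excluded,
    cpg = list(count = sum(is_cpg), sites = cpg_sites,
               rate = if (cpg_sites > 0) sum(is_cpg) / cpg_sites else NA)),
    class = "triplet_rate_table")
}

#' @export
print.triplet_rate_table <- function(x, ...) {
  cat("Triplet mutation-rate table:", x$n_mutations, "mutations",
      sprintf("(%d excluded at contig edges)\n", x$n_excluded))
  top <- x$table[order(-x$table$rate), ][1:5, ]
  print(top, row.names = FALSE)
  cat(sprintf("CpG-context: %d mutations over %d CpG-involved sites (rate %.3g)\n",
              x$cpg$count, x$cpg$sites, x$cpg$rate))
  if (!is.null(x$expected)) {
    cat("expected counts per compartment:\n"); print(round(x$expected, 2))
  }
  invisible(x)
}

#' Selection checks from pre-tallied counts
#'
#' (a) coding vs non-coding mutation counts against the genomic coding
#' fraction (Yates chi-square), (b) non-synonymous : synonymous against the
#' 3:1 mutational null (Yates chi-square), (c) one-tailed Fisher test for an
#' excess of multiple-of-three indels inside coding sequence.
#'
#' @param n_coding,n_noncoding observed mutation counts by region.
#' @param coding_fraction genomic fraction that is coding.
#' @param n_nonsyn,n_syn observed coding SNV effect counts.
#' @param frameshift_table 2x2 matrix: rows coding/non-coding, columns
#'   multiple-of-three / not.
#' @return a `selection_report` of the three tests.
#' @export
selection_report <- function(n_coding, n_noncoding, coding_fraction,
                             n_nonsyn, n_syn, frameshift_table = NULL) {
  total <- n_coding + n_noncoding
  coding_test <- yates_chisq(c(n_coding, n_noncoding),
                             total * c(coding_fraction, 1 - coding_fraction))
  ns_total <- n_nonsyn + n_syn
  syn_test <- if (ns_total > 0)
    yates_chisq(c(n_nonsyn, n_syn), ns_total * c(3, 1) / 4) else NULL
  fs_test <- NULL
  if (!is.null(frameshift_table)) {
    ft <- stats::fisher.test(frameshift_table, alternative = "greater")
    fs_test <- list(p.value = ft$p.value, estimate = unname(ft$estimate),
                    table = frameshift_table)
  }
  structure(list(coding = list(observed = c(coding = n_coding,
                                            noncoding = n_noncoding),
                               coding_fraction = coding_fraction,
                               test = coding_test),
                 nonsyn = list(observed = c(nonsyn = n_nonsyn, syn = n_syn),
                               null = "3:1", test = syn_test),
                 frameshift = fs_test),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection checks on the de novo mutation profile\n")
  cat(sprintf("  coding %d vs non-coding %d (coding fraction %.3f): chi2 = %.3f, p = %.3g\n",
              x$coding$observed["coding"], x$coding$observed["noncoding"],
              x$coding$coding_fraction, x$coding$test$statistic,
              x$coding$test$p.value))
  if (!is.null(x$nonsyn$test))
    cat(sprintf("  non-syn %d : syn %d vs 3:1: chi2 = %.3f, p = %.3g\n",
                x$nonsyn$observed["nonsyn"], x$nonsyn$observed["syn"],
                x$nonsyn$test$statistic, x$nonsyn$test$p.value))
  if (!is.null(x$frameshift))
    cat(sprintf("  multiple-of-3 indels in coding: one-tailed Fisher p = %.2f\n",
                x$frameshift$p.value))
  invisible(x)
}

#' Selection checks from a mutation list and coding annotation
#'
#' Classifies each mutation by region using the coding intervals, each coding
#' SNV as synonymous/non-synonymous on the annotated frame (standard nuclear
#' code), and each indel by length modulo 3, then runs [selection_report()].
#'
#' @param mutations data.frame (chrom, pos, ref, alt).
#' @param genome a [make_genome()] with sequence and coding intervals (or
#'   supply `coding`).
#' @param coding optional coding-interval data.frame overriding the genome's.
#' @export
selection_tests <- function(mutations, genome, coding = NULL) {
  coding <- coding %||% genome$coding
  if (is.null(coding) || !nrow(coding)) stop("no coding annotation supplied")
  cfrac <- sum(coding$end - coding$start + 1) / genome_length(genome)
  hit <- coding_interval_of(mutations$chrom, mutations$pos, coding)
  is_snv <- nchar(mutations$ref) == 1 & nchar(mutations$alt) == 1
  in_cds <- !is.na(hit)
  n_syn <- n_nonsyn <- 0
  for (i in which(is_snv & in_cds)) {
    eff <- codon_effect(genome, coding[hit[i], ], mutations$pos[i],
                        mutations$alt[i])
    if (identical(eff, "synonymous")) n_syn <- n_syn + 1
    else if (identical(eff, "nonsynonymous")) n_nonsyn <- n_nonsyn + 1
  }
  indel <- mutations[!is_snv, , drop = FALSE]
  ih <- hit[!is_snv]
  mult3 <- abs(nchar(indel$ref) - nchar(indel$alt)) %% 3 == 0
  fs <- NULL
  if (nrow(indel))
    fs <- matrix(c(sum(!is.na(ih) & mult3), sum(!is.na(ih) & !mult3),
                   sum(is.na(ih) & mult3), sum(is.na(ih) & !mult3)),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("coding", "noncoding"),
                                 c("mult3", "not_mult3")))
  selection_report(sum(in_cds), sum(!in_cds), cfrac, n_nonsyn, n_syn, fs)
}

coding_interval_of <- function(chrom, pos, coding) {
  vapply(seq_along(pos), function(i) {
    j <- which(coding$chrom == chrom[i] & coding$start <= pos[i] &
                 coding$end >= pos[i])
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
}

## synonymous/nonsynonymous call for a coding SNV on a plus-strand CDS
codon_effect <- function(genome, cds, pos, alt) {
  off <- (pos - cds$start - cds$frame) %% 3          # position within codon
  cstart <- pos - off
  if (cstart < cds$start || cstart + 2 > cds$end) return(NA_character_)
  codon <- genome_base(genome, cds$chrom, cstart, 3)
  mut <- codon
  substr(mut, off + 1, off + 1) <- alt
  aa1 <- Biostrings::GENETIC_CODE[[codon]]
  aa2 <- Biostrings::GENETIC_CODE[[mut]]
  if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
}
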