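#' Build a synthetic genome model
#'
#' Generates a random genome with a prescribed G:C composition together with a
#' set of non-overlapping coding intervals (frame 0, plus strand, lengths a
#' multiple of 3).  The peach genome motivating the defaults has A:T and G:C
#' compositions of 62.5% and 37.5%, hence `gc_fraction = 0.375`.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param gc_fraction genome G+C fraction in (0, 1).
#' @param coding_fraction approximate fraction of the genome covered by coding
#'   intervals; set to 0 for no annotation.
#' @param mean_cds_length mean coding-interval length in bp (rounded to a
#'   multiple of 3, minimum 30).
#' @param sequence if `FALSE`, no base sequence is materialised (positions and
#'   alleles are still simulable); saves memory for large genomes.
#' @param seed optional integer seed.
#' @return an object of class `genome_model`: chromosome table, optional
#'   `Biostrings::DNAStringSet` sequence, coding-interval table.
#' @export
make_genome <- function(chrom_lengths, gc_fraction = 0.375,
                        coding_fraction = 0, mean_cds_length = 900,
                        sequence = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(chrom_lengths > 0), gc_fraction > 0, gc_fraction < 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  chrom <- data.frame(name = names(chrom_lengths),
                      length = as.numeric(chrom_lengths),
                      stringsAsFactors = FALSE)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- NULL
  if (sequence) {
    seqs <- Biostrings::DNAStringSet(vapply(chrom$length, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1)))
    names(seqs) <- chrom$name
  }
  coding <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0),
                       frame = integer(0))
  if (coding_fraction > 0) {
    len0 <- max(30, 3 * round(mean_cds_length / 3))
    cd <- lapply(seq_len(nrow(chrom)), function(i) {
      L <- chrom$length[i]
      n <- max(1, round(coding_fraction * L / len0))
      # lay genes on a grid with random jitter so they never overlap
      pitch <- floor(L / n)
      if (pitch <= len0 + 2) n <- max(1, floor(L / (len0 + 10)))
      pitch <- floor(L / n)
      start <- (seq_len(n) - 1) * pitch +
        sample.int(max(1, pitch - len0 - 1), n, replace = TRUE)
      start <- pmin(start, L - len0)
      start <- start[start >= 1]
      data.frame(chrom = chrom$name[i], start = start,
                 end = start + len0 - 1, strand = "+", frame = 0L)
    })
    coding <- do.call(rbind, cd)
  }
  structure(list(chrom = chrom, seq = seqs, coding = coding,
                 gc_fraction = gc_fraction),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Synthetic genome:", nrow(x$chrom), "chromosome(s),",
      format(sum(x$chrom$length), big.mark = ","), "bp, GC",
      x$gc_fraction, "\n")
  if (nrow(x$coding))
    cat("  coding intervals:", nrow(x$coding), "(",
        round(sum(x$coding$end - x$coding$start + 1) /
                sum(x$chrom$length), 3), "of genome )\n")
  invisible(x)
}

genome_length <- function(genome) sum(genome$chrom$length)

## global <-> per-chromosome coordinate maps (1-based everywhere internally)
chrom_offsets <- function(genome) {
  c(0, cumsum(genome$chrom$length))[seq_len(nrow(genome$chrom))]
}

global_to_local <- function(genome, gpos) {
  off <- chrom_offsets(genome)
  idx <- findInterval(gpos - 1, c(off, sum(genome$chrom$length)))
  data.frame(chrom = genome$chrom$name[idx], pos = gpos - off[idx])
}

#' Base(s) of the genome sequence at given positions
#' @keywords internal
genome_base <- function(genome, chrom, pos, width = 1) {
  if (is.null(genome$seq)) return(NULL)
  vapply(seq_along(pos), function(i) {
    as.character(Biostrings::subseq(genome$seq[[chrom[i]]],
                                    start = pos[i],
                                    width = width))
  }, character(1))
}

#' Trinucleotide content of a genome or of genomic intervals
#'
#' Counts every overlapping trinucleotide (i.e. triplets starting at the
#' first, second and third nucleotide of each sequence, and onwards), the
#' background register convention used by the triplet mutation-rate analysis.
#'
#' @param genome a `genome_model` with sequence.
#' @param regions optional data.frame (chrom, start, end) restricting counting.
#' @return named integer vector over the 64 trinucleotides.
#' @export
triplet_content <- function(genome, regions = NULL) {
  stopifnot(!is.null(genome$seq))
  if (is.null(regions)) {
    counts <- colSums(Biostrings::trinucleotideFrequency(genome$seq))
  } else {
    parts <- lapply(seq_len(nrow(regions)), function(i) {
      s <- max(1, regions$start[i])
      e <- min(genome$chrom$length[genome$chrom$name == regions$chrom[i]],
               regions$end[i])
      if (e - s + 1 < 3) return(NULL)
      Biostrings::trinucleotideFrequency(
        Biostrings::subseq(genome$seq[[regions$chrom[i]]], start = s, end = e))
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) {
      counts <- structure(integer(64),
                          names = Biostrings::mkAllStrings(c("A","C","G","T"), 3))
    } else counts <- colSums(do.call(rbind, parts))
  }
  counts
}

#' Trinucleotide context of a mutation, in three registers
#'
#' Returns the triplets having the mutated base at the start, centre and end
#' position.  `NA` rows mark sites too close to a contig edge.
#' @keywords internal
mutation_triplets <- function(genome, chrom, pos) {
  L <- stats::setNames(genome$chrom$length, genome$chrom$name)
  t(vapply(seq_along(pos), function(i) {
    p <- pos[i]; cl <- L[[chrom[i]]]
    ctx <- c(start = NA_character_, centre = NA_character_, end = NA_character_)
    if (p + 2 <= cl) ctx["start"] <- genome_base(genome, chrom[i], p, 3)
    if (p - 1 >= 1 && p + 1 <= cl) ctx["centre"] <- genome_base(genome, chrom[i], p - 1, 3)
    if (p - 2 >= 1) ctx["end"] <- genome_base(genome, chrom[i], p - 2, 3)
    ctx
  }, character(3)))
}
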