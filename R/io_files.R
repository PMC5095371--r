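#' Write a simulated group to the pipeline's on-disk formats
#'
#' Emits: `genome.fa` (FASTA), `coding.gff3`, `sv_mask.bed` (possibly empty),
#' one multi-sample VCF 4.2 per emulated caller (`calls_<name>.vcf`),
#' `counts.tsv` (stranded allele read counts), `truth.json` and `group.yaml`.
#' All files are plain text; a rerun with the same seed is byte-identical.
#'
#' @param sim a [simulate_group()] result.
#' @param dir output directory (created if needed).
#' @param sv_mask optional `GRanges` written as the mask.
#' @return named character vector of paths, invisibly.
#' @export
write_group <- function(sim, dir, sv_mask = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(sim$genome$seq)) {
    paths["fasta"] <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome$seq, paths["fasta"])
  }
  paths["gff"] <- file.path(dir, "coding.gff3")
  write_coding_gff(sim$genome, paths["gff"])
  paths["bed"] <- file.path(dir, "sv_mask.bed")
  if (is.null(sv_mask) || !length(sv_mask)) {
    file.create(paths["bed"])
  } else rtracklayer::export(sv_mask, paths["bed"], format = "BED")
  for (cn in names(sim$config$caller_profiles)) {
    p <- file.path(dir, paste0("calls_", cn, ".vcf"))
    write_sim_vcf(sim, cn, p)
    paths[paste0("vcf_", cn)] <- p
  }
  paths["counts"] <- file.path(dir, "counts.tsv")
  data.table::fwrite(sim$counts, paths["counts"], sep = "\t")
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(markers = sim$truth$markers,
         f2_genotypes = as.data.frame(sim$truth$f2_genotypes),
         injected_mutations = sim$truth$injected_mutations,
         shared_mutations = sim$truth$shared_mutations,
         artifacts = sim$truth$artifacts),
    paths["truth"], digits = NA)
  paths["group"] <- file.path(dir, "group.yaml")
  write_group_yaml(sim$group, paths["group"])
  invisible(paths)
}

write_coding_gff <- function(genome, path) {
  if (!nrow(genome$coding)) { writeLines("##gff-version 3", path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(
    genome$coding$chrom,
    IRanges::IRanges(genome$coding$start, genome$coding$end),
    strand = genome$coding$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "pedimut"
  S4Vectors::mcols(gr)$phase <- as.integer(genome$coding$frame)
  S4Vectors::mcols(gr)$ID <- sprintf("cds%05d", seq_along(gr))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read coding intervals from a GFF3 file
#' @param path GFF3 file; `CDS` features are used.
#' @return data.frame (chrom, start, end, strand, frame).
#' @export
read_coding_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  ph <- S4Vectors::mcols(gr)$phase
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             frame = if (is.null(ph)) 0L else as.integer(ph),
             stringsAsFactors = FALSE)
}

GT_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
             ambiguous = "./.", missing = "./.")

write_sim_vcf <- function(sim, caller, path) {
  keep <- which(sim$caller_keep[[caller]])
  samples <- colnames(sim$geno)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", sim$genome$chrom$name,
                   as.integer(sim$genome$chrom$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- GT_CODE[classify_genotype(sim$ad$ref[keep, , drop = FALSE],
                                  sim$ad$alt[keep, , drop = FALSE])]
  dim(gt) <- c(length(keep), length(samples))
  cell <- matrix(paste0(gt, ":", sim$ad$ref[keep, ], ",", sim$ad$alt[keep, ],
                        ":", sim$ad$dp[keep, ]),
                 nrow = length(keep))
  body <- paste(sim$sites$chrom[keep], as.integer(sim$sites$pos[keep]), ".",
                sim$sites$ref[keep], sim$sites$alt[keep], 999, "PASS", ".",
                "GT:AD:DP", apply(cell, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the stranded allele-counts table
#'
#' Dialect: tab-separated with columns chrom, pos, sample, allele, fwd_reads,
#' rev_reads.
#' @param path TSV file.
#' @export
read_counts_table <- function(path) {
  ct <- data.table::fread(path, colClasses = list(
    character = c("chrom", "sample", "allele")))
  data.table::setkeyv(ct, c("chrom", "pos"))
  ct[]
}

#' @rdname read_counts_table
#' @param counts counts `data.table`.
#' @export
write_counts_table <- function(counts, path) {
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' Read / write a marker table
#' @param markers marker data.frame from [build_marker_set()].
#' @param path TSV file.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character"),
                    stringsAsFactors = FALSE)
}
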