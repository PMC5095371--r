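GENO_CLASSES <- c("hom_ref", "het", "hom_alt", "ambiguous", "missing")
INFORMATIVE <- c("hom_ref", "het", "hom_alt")

#' Classify a genotype from reference/alternate read counts
#'
#' The reference-allelic ratio (ref reads over ref+alt reads) calls a
#' homozygote at 95-100% (hom_ref) or 0-5% (hom_alt) and a heterozygote at
#' 30-70%; sites with depth below 10 or above 80 are `missing`, and ratios in
#' none of the bands are `ambiguous`.  All band and depth bounds are
#' inclusive, and depth is the sum of the two allele depths.
#'
#' @param ref_reads,alt_reads non-negative integer vectors (or matrices of
#'   identical shape).
#' @param min_depth,max_depth inclusive callable-depth window.
#' @param hom_tol homozygote band half-width (ratio <= `hom_tol` or
#'   >= 1 - `hom_tol`).
#' @param het_band inclusive heterozygote ratio band, length 2.
#' @return character vector (or matrix) over
#'   `c("hom_ref","het","hom_alt","ambiguous","missing")`.
#' @export
classify_genotype <- function(ref_reads, alt_reads, min_depth = 10,
                              max_depth = 80, hom_tol = 0.05,
                              het_band = c(0.30, 0.70)) {
  if (any(ref_reads < 0, na.rm = TRUE) || any(alt_reads < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  d <- dim(ref_reads)
  r <- as.numeric(ref_reads); a <- as.numeric(alt_reads)
  depth <- r + a
  ratio <- ifelse(depth > 0, r / depth, NA_real_)
  out <- rep("ambiguous", length(r))
  out[ratio >= 1 - hom_tol] <- "hom_ref"
  out[ratio <= hom_tol] <- "hom_alt"
  out[ratio >= het_band[1] & ratio <= het_band[2]] <- "het"
  out[is.na(ratio) | depth < min_depth | depth > max_depth] <- "missing"
  if (!is.null(d)) dim(out) <- d
  if (!is.null(colnames(ref_reads))) colnames(out) <- colnames(ref_reads)
  out
}

#' Construct a site-call set
#'
#' Container for a stream of VCF loci: per-site fields plus per-sample
#' ref/alt allele depths.  Usually built by [read_site_calls()] or
#' [sim_site_calls()].
#'
#' @param chrom,pos,ref,alt,qual per-site vectors (`pos` 1-based).
#' @param ref_ad,alt_ad numeric matrices, sites x samples, with sample names
#'   as column names.  `NA` depths mark uncalled multi-allelic records.
#' @export
site_calls <- function(chrom, pos, ref, alt, qual, ref_ad, alt_ad) {
  stopifnot(all(pos >= 1), nrow(ref_ad) == length(pos),
            identical(dim(ref_ad), dim(alt_ad)),
            !is.null(colnames(ref_ad)))
  info <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                     ref = as.character(ref), alt = as.character(alt),
                     qual = as.numeric(qual), stringsAsFactors = FALSE)
  info$biallelic <- !grepl(",", info$alt) & info$alt != "."
  structure(list(info = info, ref_ad = ref_ad, alt_ad = alt_ad,
                 samples = colnames(ref_ad), geno = NULL),
            class = "site_calls")
}

#' @export
print.site_calls <- function(x, ...) {
  cat("Site calls:", nrow(x$info), "loci x", length(x$samples), "samples\n")
  invisible(x)
}

#' Read a multi-sample VCF into a site-call set
#'
#' Uses `vcfR` for parsing; allele depths come from the per-sample `AD`
#' field, and genotype classes are recomputed from those depths (not from the
#' written `GT`), matching the read-count-based classification rules.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples optional character vector restricting/ordering samples.
#' @return a [site_calls()] object.
#' @export
read_site_calls <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(ad))
    if (length(miss))
      stop("samples absent from VCF: ", paste(miss, collapse = ", "))
    ad <- ad[, samples, drop = FALSE]
  }
  sp <- strsplit(ifelse(is.na(ad), "NA,NA", ad), ",", fixed = TRUE)
  ref_ad <- matrix(suppressWarnings(
    as.numeric(vapply(sp, `[`, character(1), 1))), nrow = nrow(ad))
  alt_ad <- matrix(suppressWarnings(
    as.numeric(vapply(sp, function(x) if (length(x) >= 2) x[2] else "0",
                      character(1)))), nrow = nrow(ad))
  colnames(ref_ad) <- colnames(alt_ad) <- colnames(ad)
  site_calls(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
             ref_ad = ref_ad, alt_ad = alt_ad)
}

genotype_classes <- function(sc, ...) {
  if (!is.null(sc$geno)) return(sc$geno)
  classify_genotype(sc$ref_ad, sc$alt_ad, ...)
}

#' Retain only high-confidence variant sites
#'
#' Applies the confident-site rules: bi-allelic records with quality >= 50,
#' per-sample genotype classification under the callable-depth window, and a
#' strict majority (> 0.5) of group samples with informative calls
#' (classified hom/het, neither missing nor ambiguous).
#'
#' @param sc a [site_calls()] object.
#' @param group optional [pedigree_group()]; restricts the informative-call
#'   fraction to the group's samples.  All group samples must be present.
#' @param min_qual minimum record quality.
#' @param min_informative strict lower bound on the informative fraction.
#' @param ... passed to [classify_genotype()].
#' @return filtered `site_calls` with the class matrix cached in `$geno` and
#'   a per-reason drop log in `attr(, "drop_log")`.
#' @export
filter_confident_sites <- function(sc, group = NULL, min_qual = 50,
                                   min_informative = 0.5, ...) {
  use <- if (is.null(group)) sc$samples else group_samples(group)
  miss <- setdiff(use, sc$samples)
  if (length(miss))
    stop("group samples missing from calls: ", paste(miss, collapse = ", "))
  geno <- genotype_classes(sc, ...)
  inf_frac <- rowMeans(matrix(geno[, use] %in% INFORMATIVE,
                              nrow = nrow(geno)))
  ok_bi <- sc$info$biallelic
  ok_q <- !is.na(sc$info$qual) & sc$info$qual >= min_qual
  ok_inf <- inf_frac > min_informative
  keep <- ok_bi & ok_q & ok_inf
  log <- c(not_biallelic = sum(!ok_bi),
           low_qual = sum(ok_bi & !ok_q),
           uninformative = sum(ok_bi & ok_q & !ok_inf),
           kept = sum(keep))
  out <- structure(list(info = sc$info[keep, , drop = FALSE],
                        ref_ad = sc$ref_ad[keep, , drop = FALSE],
                        alt_ad = sc$alt_ad[keep, , drop = FALSE],
                        samples = sc$samples,
                        geno = geno[keep, , drop = FALSE]),
                   class = "site_calls")
  attr(out, "drop_log") <- log
  out
}

#' Which loci fall inside a structural-variant mask?
#'
#' @param chrom,pos 1-based locus vectors.
#' @param mask a `GRanges` (e.g. from [read_sv_mask()]) or `NULL`.
#' @keywords internal
in_sv_mask <- function(chrom, pos, mask) {
  if (is.null(mask) || length(mask) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, mask) > 0
}

#' Read a BED mask of structural-variant regions
#'
#' BED intervals are 0-based half-open on disk; the returned `GRanges` is
#' 1-based inclusive, the package-internal convention.
#' @param path BED file.
#' @export
read_sv_mask <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "BED")
}

#' Build the confident marker set of an F1 parent
#'
#' Markers are filtered sites where the F1 is a confident heterozygote,
#' excluding loci inside the structural-variant mask.
#'
#' @param sc filtered [site_calls()] (from [filter_confident_sites()]).
#' @param f1 F1 sample name.
#' @param sv_mask optional `GRanges` mask.
#' @param origins optional data.frame (chrom, pos, origin_ref, origin_alt)
#'   with grandparent-resolved haplotype labels to attach.
#' @return data.frame of markers (chrom, pos, ref, alt, origin_ref,
#'   origin_alt).
#' @export
build_marker_set <- function(sc, f1, sv_mask = NULL, origins = NULL) {
  geno <- genotype_classes(sc)
  if (!f1 %in% sc$samples) stop("F1 sample not in calls: ", f1)
  if (!is.null(sv_mask) && length(sv_mask) &&
      !all(as.character(GenomicRanges::seqnames(sv_mask)) %in% sc$info$chrom) &&
      nrow(sc$info))
    warning("SV mask names chromosomes absent from the call set")
  het <- geno[, f1] == "het" & !in_sv_mask(sc$info$chrom, sc$info$pos, sv_mask)
  mk <- sc$info[het, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  mk$origin_ref <- NA_character_; mk$origin_alt <- NA_character_
  if (!is.null(origins)) {
    i <- match(paste(mk$chrom, mk$pos), paste(origins$chrom, origins$pos))
    mk$origin_ref <- origins$origin_ref[i]
    mk$origin_alt <- origins$origin_alt[i]
  }
  rownames(mk) <- NULL
  mk
}

#' Genome heterozygosity from a genotyped site stream
#'
#' heterozygosity = het sites / (het + hom sites); ambiguous and missing
#' classes drop out of both numerator and denominator.  The stream must
#' include confidently genotyped non-variant (homozygous) sites.
#'
#' @param classes character vector/matrix of genotype classes for one sample.
#' @return proportion in [0, 1].
#' @export
estimate_heterozygosity <- function(classes) {
  n_het <- sum(classes == "het")
  n_hom <- sum(classes %in% c("hom_ref", "hom_alt"))
  if (n_het + n_hom == 0) stop("no confidently genotyped sites in stream")
  n_het / (n_het + n_hom)
}
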