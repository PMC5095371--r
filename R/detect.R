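MASK_REASONS <- c("low_support", "no_strand_pair", "parental_background_missing",
                  "excess_missing", "allele_elsewhere", "cluster", "sv_mask")

#' Find rare-variant candidate mutations
#'
#' Screens filtered sites for alleles carried by fewer than `max_freq`
#' samples of the group (carrier samples, not allele copies); every F2
#' carrier of such an allele becomes a focal candidate.  Alleles also present
#' in the F1 still enter the list here — they are masked later by the
#' read-level `allele_elsewhere` rule, never silently dropped.
#'
#' @param sc filtered [site_calls()] with cached genotype classes.
#' @param group a [pedigree_group()].
#' @param max_freq strict carrier-count bound (default 3: "fewer than three").
#' @return data.frame of candidates (chrom, pos, ref, alt, allele, sample,
#'   type), one row per focal F2 x derived allele.
#' @export
find_rare_candidates <- function(sc, group, max_freq = 3) {
  geno <- genotype_classes(sc)
  gs <- group_samples(group)
  out <- list()
  for (which_allele in c("alt", "ref")) {
    carr <- if (which_allele == "alt") geno %in% c("het", "hom_alt")
            else geno %in% c("het", "hom_ref")
    dim(carr) <- dim(geno); colnames(carr) <- colnames(geno)
    n_car <- rowSums(carr[, gs, drop = FALSE])
    f2c <- carr[, group$f2, drop = FALSE]
    cand_site <- which(n_car >= 1 & n_car < max_freq &
                         rowSums(f2c) >= 1)
    for (i in cand_site) {
      focal <- group$f2[f2c[i, ]]
      out[[length(out) + 1]] <- data.frame(
        chrom = sc$info$chrom[i], pos = sc$info$pos[i],
        ref = sc$info$ref[i], alt = sc$info$alt[i],
        allele = sc$info[[which_allele]][i], sample = focal,
        type = ifelse(nchar(sc$info$ref[i]) == nchar(sc$info$alt[i]),
                      "snv", "indel"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_candidates())
  res <- do.call(rbind, out)
  res[order(match(res$chrom, unique(sc$info$chrom)), res$pos, res$sample), ,
      drop = FALSE]
}

empty_candidates <- function() {
  data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), allele = character(0), sample = character(0),
             type = character(0), stringsAsFactors = FALSE)
}

#' Evaluate candidates against strand-aware read support, with soft-masking
#'
#' A candidate PASSes iff (i) the focal sample shows at least `min_reads`
#' reads of the derived allele with at least `min_strand_reads` on each
#' strand, (ii) the parent is informative and at most `max_missing` other F2s
#' are missing, and (iii) not a single read supports the derived allele in
#' the parent or any other F2.  Failures are soft-masked with all applicable
#' reason codes.
#'
#' @param cands candidates from [find_rare_candidates()].
#' @param counts stranded counts `data.table` (see [read_counts_table()]).
#' @param sc the filtered [site_calls()] the candidates came from.
#' @param group a [pedigree_group()].
#' @param min_reads minimum derived-allele reads in the focal sample.
#' @param min_strand_reads minimum derived-allele reads per strand (the
#'   default 1 reads the support rule as ">= 5 total with both strands
#'   represented"; set 5 for the stricter ">= 5 per strand" reading).
#' @param max_missing maximum missing genotype calls among the other F2s.
#' @param sv_mask optional `GRanges`; candidates inside it get `sv_mask`.
#' @return the candidates with `status` (PASS/masked), `reasons`
#'   (semicolon-joined codes) and focal support columns appended.
#' @export
evaluate_candidates <- function(cands, counts, sc, group, min_reads = 5,
                                min_strand_reads = 1, max_missing = 5,
                                sv_mask = NULL) {
  n <- nrow(cands)
  if (!n) {
    cands$status <- character(0); cands$reasons <- character(0)
    cands$fwd <- integer(0); cands$rev <- integer(0)
    return(cands)
  }
  geno <- genotype_classes(sc)
  key <- paste(sc$info$chrom, sc$info$pos)
  row_of <- match(paste(cands$chrom, cands$pos), key)
  if (anyNA(row_of)) stop("candidate locus absent from the site calls")
  cdt <- data.table::as.data.table(
    cands[, c("chrom", "pos", "allele", "sample")])
  cdt$cand_id <- seq_len(n)
  cc <- counts[cdt, on = c("chrom", "pos"), allow.cartesian = TRUE]
  if (anyNA(cc$allele)) stop("candidate locus absent from the counts table")
  hit <- cc$allele == cc$i.allele
  focal <- cc$sample == cc$i.sample
  fwd <- vapply(split(cc$fwd_reads * (hit & focal), cc$cand_id), sum, 0)
  rev <- vapply(split(cc$rev_reads * (hit & focal), cc$cand_id), sum, 0)
  elsewhere <- vapply(split((cc$fwd_reads + cc$rev_reads) * (hit & !focal) *
                              (cc$sample %in% group_samples(group)),
                            cc$cand_id), sum, 0)
  ord <- as.integer(names(fwd))
  fwd <- fwd[order(ord)]; rev <- rev[order(ord)]
  elsewhere <- elsewhere[order(ord)]
  f1_class <- geno[row_of, group$f1]
  n_missing_other <- vapply(seq_len(n), function(i) {
    others <- setdiff(group$f2, cands$sample[i])
    sum(geno[row_of[i], others] == "missing")
  }, 0)
  reasons <- lapply(seq_len(n), function(i) {
    r <- character(0)
    if (fwd[i] + rev[i] < min_reads) r <- c(r, "low_support")
    if (fwd[i] < min_strand_reads || rev[i] < min_strand_reads)
      r <- c(r, "no_strand_pair")
    if (!f1_class[i] %in% INFORMATIVE) r <- c(r, "parental_background_missing")
    if (n_missing_other[i] > max_missing) r <- c(r, "excess_missing")
    if (elsewhere[i] > 0) r <- c(r, "allele_elsewhere")
    r
  })
  sv <- in_sv_mask(cands$chrom, cands$pos, sv_mask)
  reasons <- lapply(seq_len(n), function(i)
    if (sv[i]) c(reasons[[i]], "sv_mask") else reasons[[i]])
  cands$status <- ifelse(lengths(reasons) == 0, "PASS", "masked")
  cands$reasons <- vapply(reasons, paste, character(1), collapse = ";")
  cands$fwd <- fwd; cands$rev <- rev
  cands
}

#' Mask clustered candidates (likely contamination)
#'
#' Any candidate participating, within one focal sample, in a window of at
#' most `snv_window` bp holding more than `snv_max` base substitutions (>= 4
#' by default) or a window of at most `indel_window` bp holding more than
#' `indel_max` indels (>= 3) is masked with reason `cluster`.  Windows slide:
#' any span qualifies.
#'
#' @param cands evaluated candidates.
#' @param snv_window,snv_max,indel_window,indel_max cluster rule parameters;
#'   `*_max` are the largest non-clustered counts ("more than three", "more
#'   than two").
#' @param pool optional data.frame (chrom, pos, sample, type) of additional
#'   candidate loci contributing cluster evidence (e.g. the pooled candidates
#'   of all callers); windows are counted over `cands` plus `pool`.
#' @export
apply_cluster_mask <- function(cands, snv_window = 10, snv_max = 3,
                               indel_window = 20, indel_max = 2,
                               pool = NULL) {
  if (!nrow(cands)) return(cands)
  ev_cols <- c("chrom", "pos", "sample", "type")
  ev <- cands[, ev_cols]
  if (!is.null(pool)) ev <- unique(rbind(ev, pool[, ev_cols]))
  mask <- rep(FALSE, nrow(cands))
  for (s in unique(cands$sample)) {
    for (ty in c("snv", "indel")) {
      idx <- which(cands$sample == s & cands$type == ty)
      if (!length(idx)) next
      w <- if (ty == "snv") snv_window else indel_window
      mx <- if (ty == "snv") snv_max else indel_max
      for (ch in unique(cands$chrom[idx])) {
        ii <- idx[cands$chrom[idx] == ch]
        po <- sort(unique(ev$pos[ev$sample == s & ev$type == ty &
                                   ev$chrom == ch]))
        for (j in seq_along(po)) {
          inw <- po >= po[j] & po <= po[j] + w - 1
          if (sum(inw) > mx)
            mask[ii[cands$pos[ii] %in% po[inw]]] <- TRUE
        }
      }
    }
  }
  if (any(mask)) {
    cands$status[mask] <- "masked"
    cands$reasons[mask] <- ifelse(cands$reasons[mask] == "", "cluster",
                                  paste0(cands$reasons[mask], ";cluster"))
  }
  cands
}

#' Left-align and trim an indel representation
#' @keywords internal
normalize_variant <- function(pos, ref, alt) {
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1
    }
    ref[i] <- r; alt[i] <- a
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Combine PASS sets from two variant callers
#'
#' Locus representations are normalized before comparison; the union carries
#' provenance flags and per-type consistency counts.  Same locus+sample with
#' conflicting derived alleles is flagged for review, not auto-merged.
#'
#' @param passed_a,passed_b data.frames of PASS candidates (chrom, pos, ref,
#'   alt, sample, type) from each caller.
#' @param names_ab caller display names.
#' @return a `caller_set_report`: union data.frame with `callers` column,
#'   per-type counts (`n_both`, `n_only_a`, `n_only_b`), conflicts.
#' @export
merge_caller_sets <- function(passed_a, passed_b, names_ab = c("A", "B")) {
  keyed <- function(d) {
    if (!nrow(d)) return(cbind(d, key = character(0), kg = character(0)))
    nv <- normalize_variant(d$pos, d$ref, d$alt)
    d$key <- paste(d$chrom, nv$pos, nv$ref, nv$alt, d$sample, sep = ":")
    d$kg <- paste(d$chrom, nv$pos, d$sample, sep = ":")
    d
  }
  a <- keyed(passed_a); b <- keyed(passed_b)
  conflicts <- intersect(a$kg[!a$key %in% b$key], b$kg[!b$key %in% a$key])
  u <- rbind(cbind(a, caller = names_ab[1]), cbind(b, caller = names_ab[2]))
  u <- u[!u$kg %in% conflicts, , drop = FALSE]
  agg <- split(u$caller, u$key)
  first <- u[!duplicated(u$key), , drop = FALSE]
  first$callers <- vapply(agg[first$key], function(x)
    paste(sort(unique(x)), collapse = "+"), character(1))
  per_type <- function(ty) {
    f <- first[first$type == ty, , drop = FALSE]
    both <- sum(grepl("\\+", f$callers))
    c(n_both = both,
      n_only_a = sum(f$callers == names_ab[1]),
      n_only_b = sum(f$callers == names_ab[2]),
      union = nrow(f))
  }
  counts <- rbind(snv = per_type("snv"), indel = per_type("indel"))
  union_df <- first[, c("chrom", "pos", "ref", "alt", "sample", "type",
                        "callers")]
  rownames(union_df) <- NULL
  structure(list(union = union_df, counts = counts,
                 consistency = counts[, "n_both"] /
                   pmax(counts[, "union"], 1),
                 conflicts = conflicts, callers = names_ab),
            class = "caller_set_report")
}

#' @export
print.caller_set_report <- function(x, ...) {
  cat("Caller-set union (", paste(x$callers, collapse = " + "), ")\n", sep = "")
  for (ty in rownames(x$counts)) {
    k <- x$counts[ty, ]
    cat(sprintf("  %-6s union %d: both %d, only %s %d, only %s %d (consistency %.1f%%)\n",
                ty, k["union"], k["n_both"], x$callers[1], k["n_only_a"],
                x$callers[2], k["n_only_b"], 100 * x$consistency[ty]))
  }
  if (length(x$conflicts))
    cat("  flagged for review (conflicting alleles):",
        length(x$conflicts), "\n")
  invisible(x)
}

#' Scan for shared (putatively parental-somatic) mutations
#'
#' Point mutations whose derived allele is present in `min_carriers` to
#' `max_carriers` F2s, absent (zero supporting reads) from the F1, with every
#' carrier individually meeting the strand-aware read-support rule.
#'
#' @inheritParams evaluate_candidates
#' @param min_carriers,max_carriers inclusive F2 carrier range (default 2-5).
#' @return data.frame of loci with comma-joined carrier lists.
#' @export
scan_shared_mutations <- function(sc, counts, group, min_carriers = 2,
                                  max_carriers = 5, min_reads = 5,
                                  min_strand_reads = 1) {
  geno <- genotype_classes(sc)
  carr <- geno %in% c("het", "hom_alt"); dim(carr) <- dim(geno)
  colnames(carr) <- colnames(geno)
  nf2 <- rowSums(carr[, group$f2, drop = FALSE])
  snv <- nchar(sc$info$ref) == nchar(sc$info$alt)
  f1_ok <- geno[, group$f1] %in% INFORMATIVE & !carr[, group$f1]
  idx <- which(snv & f1_ok & nf2 >= min_carriers & nf2 <= max_carriers)
  out <- list()
  for (i in idx) {
    carriers <- group$f2[carr[i, group$f2]]
    cc <- counts[data.table::data.table(chrom = sc$info$chrom[i],
                                        pos = sc$info$pos[i]),
                 on = c("chrom", "pos")]
    al <- sc$info$alt[i]
    f1r <- sum(cc$fwd_reads[cc$allele == al & cc$sample == group$f1],
               cc$rev_reads[cc$allele == al & cc$sample == group$f1],
               na.rm = TRUE)
    if (f1r > 0) next
    ok <- vapply(carriers, function(s) {
      f <- sum(cc$fwd_reads[cc$allele == al & cc$sample == s], na.rm = TRUE)
      r <- sum(cc$rev_reads[cc$allele == al & cc$sample == s], na.rm = TRUE)
      f + r >= min_reads && f >= min_strand_reads && r >= min_strand_reads
    }, logical(1))
    if (!all(ok)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = sc$info$chrom[i], pos = sc$info$pos[i], ref = sc$info$ref[i],
      alt = al, carriers = paste(carriers, collapse = ","),
      n_carriers = length(carriers), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      carriers = character(0), n_carriers = integer(0)))
  do.call(rbind, out)
}

#' Run the full candidate-identification chain for one or two caller sets
#'
#' rare-variant screen -> read-support evaluation with soft-masking ->
#' cluster mask -> (if two callers) union with consistency bookkeeping.
#'
#' @param caller_sites named list of filtered [site_calls()] (one per caller).
#' @param counts stranded counts `data.table`.
#' @param group a [pedigree_group()].
#' @param sv_mask optional `GRanges`.
#' @param ... passed to [evaluate_candidates()].
#' @return a `mutation_calls` object: per-caller candidate tables (PASS and
#'   masked, with reasons), the merged PASS set, and the caller report.
#' @export
detect_mutations <- function(caller_sites, counts, group, sv_mask = NULL,
                             ...) {
  if (inherits(caller_sites, "site_calls"))
    caller_sites <- list(calls = caller_sites)
  cand <- lapply(caller_sites, function(sc) {
    x <- find_rare_candidates(sc, group)
    evaluate_candidates(x, counts, sc, group, sv_mask = sv_mask, ...)
  })
  ## cluster evidence is pooled over the callers, so that a record one caller
  ## missed still counts towards the other's cluster windows
  pool <- unique(do.call(rbind, lapply(cand, function(x)
    x[, c("chrom", "pos", "sample", "type"), drop = FALSE])))
  cand <- lapply(cand, apply_cluster_mask, pool = pool)
  pass <- lapply(cand, function(x) x[x$status == "PASS", , drop = FALSE])
  if (length(cand) >= 2) {
    report <- merge_caller_sets(pass[[1]], pass[[2]],
                                names_ab = names(cand)[1:2])
    final <- report$union
  } else {
    report <- NULL
    final <- pass[[1]][, c("chrom", "pos", "ref", "alt", "sample", "type")]
    if (nrow(final)) final$callers <- names(cand)[1]
    else final$callers <- character(0)
  }
  structure(list(candidates = cand, mutations = final, report = report,
                 group = group), class = "mutation_calls")
}

#' @export
print.mutation_calls <- function(x, ...) {
  cat("De novo mutation calls for group", x$group$id, "\n")
  cat("  PASS:", nrow(x$mutations),
      sprintf("(%d snv, %d indel)\n", sum(x$mutations$type == "snv"),
              sum(x$mutations$type == "indel")))
  for (cn in names(x$candidates)) {
    cc <- x$candidates[[cn]]
    cat(sprintf("  %s: %d candidates, %d masked\n", cn, nrow(cc),
                sum(cc$status == "masked")))
  }
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
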