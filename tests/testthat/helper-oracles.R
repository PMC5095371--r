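# Independent oracles and fixture builders.  These re-state the rules from
# scratch (plain loops, no package internals) so the vectorised
# implementations are checked against a literal reading.

# -- literal genotype banding ------------------------------------------------
oracle_classify <- function(ref, alt) {
  depth <- ref + alt
  if (depth < 10 || depth > 80) return("missing")
  ratio <- ref / depth
  if (ratio >= 0.95) return("hom_ref")
  if (ratio <= 0.05) return("hom_alt")
  if (ratio >= 0.30 && ratio <= 0.70) return("het")
  "ambiguous"
}

# -- literal site-by-site, sample-by-sample mutation scan --------------------
# Enumerates every locus x F2, applies the rare-allele screen, the
# strand-aware support rule, the background rules and the cluster rule
# exactly as stated, and returns the PASS keys "chrom:pos:sample:allele".
oracle_detect <- function(sc, counts, group) {
  cts <- as.data.frame(counts)
  samples <- c(group$f1, group$f2)
  n <- nrow(sc$info)
  cls <- matrix("", n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) for (s in samples)
    cls[i, s] <- oracle_classify(sc$ref_ad[i, s], sc$alt_ad[i, s])
  reads_of <- function(i, s, al, strand) {
    sel <- cts$chrom == sc$info$chrom[i] & cts$pos == sc$info$pos[i] &
      cts$sample == s & cts$allele == al
    sum(cts[[strand]][sel])
  }
  pass <- character(0)
  pass_meta <- list()
  for (i in seq_len(n)) {
    for (al_which in c("alt", "ref")) {
      al <- sc$info[[al_which]][i]
      has <- if (al_which == "alt") c("het", "hom_alt") else c("het", "hom_ref")
      carriers <- samples[cls[i, ] %in% has]
      if (length(carriers) >= 3) next
      for (s in intersect(carriers, group$f2)) {
        f <- reads_of(i, s, al, "fwd_reads")
        r <- reads_of(i, s, al, "rev_reads")
        if (f + r < 5 || f < 1 || r < 1) next
        if (!cls[i, group$f1] %in% c("hom_ref", "het", "hom_alt")) next
        others <- setdiff(group$f2, s)
        if (sum(cls[i, others] == "missing") > 5) next
        elsewhere <- 0
        for (o in setdiff(samples, s))
          elsewhere <- elsewhere + reads_of(i, o, al, "fwd_reads") +
            reads_of(i, o, al, "rev_reads")
        if (elsewhere > 0) next
        pass_meta[[length(pass_meta) + 1]] <-
          list(chrom = sc$info$chrom[i], pos = sc$info$pos[i], sample = s,
               allele = al,
               type = if (nchar(sc$info$ref[i]) == nchar(sc$info$alt[i]))
                 "snv" else "indel")
      }
    }
  }
  # cluster rule over candidate loci that got this far is deliberately NOT
  # applied here: the oracle applies it over ALL rare candidates, as the rule
  # reads, via the caller below
  all_cand <- oracle_rare_loci(sc, cls, group)
  keep <- vapply(pass_meta, function(m) {
    same <- all_cand$sample == m$sample & all_cand$type == m$type &
      all_cand$chrom == m$chrom
    po <- sort(unique(all_cand$pos[same]))
    w <- if (m$type == "snv") 10 else 20
    mx <- if (m$type == "snv") 3 else 2
    clustered <- FALSE
    for (p0 in po) {
      inw <- po[po >= p0 & po <= p0 + w - 1]
      if (length(inw) > mx && m$pos %in% inw) clustered <- TRUE
    }
    !clustered
  }, logical(1))
  pass_meta <- pass_meta[keep]
  vapply(pass_meta, function(m)
    paste(m$chrom, m$pos, m$sample, m$allele, sep = ":"), character(1))
}

oracle_rare_loci <- function(sc, cls, group) {
  samples <- c(group$f1, group$f2)
  out <- data.frame(chrom = character(0), pos = numeric(0),
                    sample = character(0), type = character(0))
  for (i in seq_len(nrow(sc$info))) {
    for (al_which in c("alt", "ref")) {
      has <- if (al_which == "alt") c("het", "hom_alt") else c("het", "hom_ref")
      carriers <- samples[cls[i, ] %in% has]
      if (length(carriers) >= 3) next
      for (s in intersect(carriers, group$f2))
        out <- rbind(out, data.frame(
          chrom = sc$info$chrom[i], pos = sc$info$pos[i], sample = s,
          type = if (nchar(sc$info$ref[i]) == nchar(sc$info$alt[i]))
            "snv" else "indel"))
    }
  }
  out
}

# -- studentised permutation oracle for the Brunner-Munzel p value -----------
perm_bm_p <- function(x, y, n_perm = 2000) {
  stat <- function(x, y) {
    m <- length(x); n <- length(y)
    r <- rank(c(x, y)); r1 <- r[seq_len(m)]; r2 <- r[m + seq_len(n)]
    v1 <- sum((r1 - rank(x) - mean(r1) + (m + 1) / 2)^2) / (m - 1)
    v2 <- sum((r2 - rank(y) - mean(r2) + (n + 1) / 2)^2) / (n - 1)
    vs <- m * v1 + n * v2
    if (vs <= 0) return(0)
    m * n * (mean(r2) - mean(r1)) / ((m + n) * sqrt(vs))
  }
  obs <- abs(stat(x, y))
  pool <- c(x, y); m <- length(x)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), m)
    if (abs(stat(pool[idx], pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# -- fixture builders --------------------------------------------------------
# A site-call set + counts table built directly from a per-sample spec list:
# each site is list(chrom, pos, ref, alt, qual, ad = list(sample = c(ref, alt)),
# reads = list(sample = list(allele = c(fwd, rev)))).
build_fixture <- function(sites, samples) {
  n <- length(sites)
  ref_ad <- alt_ad <- matrix(0, n, length(samples),
                             dimnames = list(NULL, samples))
  rows <- list()
  for (i in seq_len(n)) {
    st <- sites[[i]]
    for (s in samples) {
      ad <- st$ad[[s]]
      if (!is.null(ad)) { ref_ad[i, s] <- ad[1]; alt_ad[i, s] <- ad[2] }
      for (al in names(st$reads[[s]])) {
        fr <- st$reads[[s]][[al]]
        rows[[length(rows) + 1]] <- data.frame(
          chrom = st$chrom, pos = st$pos, sample = s, allele = al,
          fwd_reads = fr[1], rev_reads = fr[2])
      }
    }
  }
  counts <- data.table::as.data.table(do.call(rbind, rows))
  data.table::setkeyv(counts, c("chrom", "pos"))
  sc <- site_calls(chrom = vapply(sites, `[[`, "", "chrom"),
                   pos = vapply(sites, function(s) s$pos, 1),
                   ref = vapply(sites, `[[`, "", "ref"),
                   alt = vapply(sites, `[[`, "", "alt"),
                   qual = vapply(sites, function(s) s$qual %||% 999, 1),
                   ref_ad = ref_ad, alt_ad = alt_ad)
  list(sc = sc, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a standard well-supported site: all samples hom-ref 20/0 except overrides
std_site <- function(chrom = "chr1", pos, ref = "A", alt = "T", samples,
                     override = list(), qual = 999) {
  ad <- reads <- list()
  for (s in samples) {
    ad[[s]] <- c(20, 0)
    reads[[s]] <- list()
    reads[[s]][[ref]] <- c(10, 10)
  }
  for (s in names(override)) {
    ad[[s]] <- override[[s]]$ad
    reads[[s]] <- override[[s]]$reads
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
       ad = ad, reads = reads)
}

# small simulated group used across detection tests
sim20kb <- function(seed, error_rate = 1e-3, rate = 2e-5, n_f2 = 6, ...) {
  g <- make_genome(c(chr1 = 2e4), sequence = FALSE, seed = seed + 1000)
  cfg <- sim_config(cross_type = "interspecific", n_f2 = n_f2,
                    true_mutation_rate = rate, error_rate = error_rate,
                    caller_profiles = c(A = 0, B = 0), seed = seed, ...)
  simulate_group(g, cfg)
}
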