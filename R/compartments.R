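#' Assign het/hom compartments per F2 from marker genotypes
#'
#' Runs of consecutive same-state confident markers become intervals;
#' boundaries between discordant flanking markers are placed at their
#' midpoint, so interior sequence is fully tiled and only chromosome ends
#' beyond the outermost markers (and chromosomes without markers) are
#' `unassigned`.  Homozygous runs inherit the parental haplotype-of-origin
#' label of their allele when the marker table carries origin tags.
#'
#' @param markers marker data.frame (chrom, pos, optionally origin_ref /
#'   origin_alt), ordered or not.
#' @param f2_classes matrix markers x F2 samples of genotype classes
#'   (`"hom_ref"/"het"/"hom_alt"`, others skipped) or alt-allele copies
#'   (0/1/2).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return a `compartment_map`: per sample, a data.frame (chrom, start, end,
#'   state in het/hom/unassigned, origin).
#' @export
assign_compartments <- function(markers, f2_classes, chrom_lengths) {
  if (is.numeric(f2_classes)) {
    cls <- c("hom_ref", "het", "hom_alt")[f2_classes + 1]
    dim(cls) <- dim(f2_classes); colnames(cls) <- colnames(f2_classes)
    f2_classes <- cls
  }
  ord <- order(match(markers$chrom, names(chrom_lengths)), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  f2_classes <- f2_classes[ord, , drop = FALSE]
  maps <- lapply(colnames(f2_classes), function(s) {
    per_chr <- lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      on_c <- which(markers$chrom == ch)
      st <- f2_classes[on_c, s]
      ok <- st %in% c("hom_ref", "het", "hom_alt")
      on_c <- on_c[ok]; st <- st[ok]
      if (!length(on_c))
        return(data.frame(chrom = ch, start = 1, end = L,
                          state = "unassigned", origin = NA_character_))
      pos <- markers$pos[on_c]
      state <- ifelse(st == "het", "het", "hom")
      origin <- rep(NA_character_, length(st))
      if ("origin_ref" %in% names(markers)) {
        origin[st == "hom_ref"] <- markers$origin_ref[on_c][st == "hom_ref"]
        origin[st == "hom_alt"] <- markers$origin_alt[on_c][st == "hom_alt"]
      }
      run_key <- paste(state, ifelse(state == "hom", origin, ""))
      runs <- rle(run_key)
      ends_i <- cumsum(runs$lengths); starts_i <- ends_i - runs$lengths + 1
      n <- length(runs$lengths)
      bnd <- floor((pos[ends_i[-n]] + pos[starts_i[-1]]) / 2)
      start <- c(pos[1], bnd + 1)
      end <- c(bnd, pos[length(pos)])
      out <- data.frame(chrom = ch, start = start, end = end,
                        state = state[starts_i],
                        origin = origin[starts_i], stringsAsFactors = FALSE)
      pre <- post <- NULL
      if (pos[1] > 1)
        pre <- data.frame(chrom = ch, start = 1, end = pos[1] - 1,
                          state = "unassigned", origin = NA_character_)
      if (pos[length(pos)] < L)
        post <- data.frame(chrom = ch, start = pos[length(pos)] + 1, end = L,
                           state = "unassigned", origin = NA_character_)
      rbind(pre, out, post)
    })
    do.call(rbind, per_chr)
  })
  names(maps) <- colnames(f2_classes)
  structure(list(maps = maps, chrom_lengths = chrom_lengths),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  hf <- compartment_het_fraction(x)
  cat("Compartment maps for", length(x$maps), "F2s; mean het fraction",
      round(mean(hf), 3), "\n")
  invisible(x)
}

#' Fraction of the assigned genome in heterozygous compartments, per sample
#' @param cmap a [assign_compartments()] result.
#' @export
compartment_het_fraction <- function(cmap) {
  vapply(cmap$maps, function(m) {
    len <- m$end - m$start + 1
    sum(len[m$state == "het"]) / sum(len[m$state != "unassigned"])
  }, numeric(1))
}

#' Locate mutations in their focal sample's compartments
#'
#' @param mutations data.frame (chrom, pos, sample).
#' @param cmap a [assign_compartments()] result.
#' @return the mutations with `state` and `origin` columns; samples without
#'   a map get `unassigned`.
#' @export
map_mutations_to_compartments <- function(mutations, cmap) {
  mutations$state <- "unassigned"; mutations$origin <- NA_character_
  for (i in seq_len(nrow(mutations))) {
    m <- cmap$maps[[mutations$sample[i]]]
    if (is.null(m)) next
    j <- which(m$chrom == mutations$chrom[i] & m$start <= mutations$pos[i] &
                 m$end >= mutations$pos[i])
    if (length(j)) {
      mutations$state[i] <- m$state[j[1]]
      mutations$origin[i] <- m$origin[j[1]]
    }
  }
  mutations
}

#' Observed vs expected mutation counts per compartment state
#'
#' Expectations are proportional to the summed compartment lengths across
#' the focal samples' maps (optionally re-weighted, e.g. by triplet-content
#' expected rates), scaled to the number of assigned mutations, and compared
#' with a Yates chi-square.
#'
#' @param mutations data.frame (chrom, pos, sample).
#' @param cmap a [assign_compartments()] result.
#' @param weights optional named numeric (`het`, `hom`) multiplying the bp
#'   shares (composition correction).
#' @return list: observed, expected, test ([yates_chisq()] or NULL if a
#'   class is empty), and the annotated mutations.
#' @export
compartment_counts <- function(mutations, cmap, weights = NULL) {
  ann <- map_mutations_to_compartments(mutations, cmap)
  obs <- c(het = sum(ann$state == "het"), hom = sum(ann$state == "hom"))
  n <- sum(obs)
  if (n == 0) stop("all mutations are unassigned")
  bp <- vapply(c("het", "hom"), function(st) {
    sum(vapply(cmap$maps, function(m)
      sum((m$end - m$start + 1)[m$state == st]), numeric(1)))
  }, numeric(1))
  if (!is.null(weights)) bp <- bp * weights[names(bp)]
  if (any(bp == 0)) {
    warning("empty compartment class; test skipped")
    return(list(observed = obs, expected = NULL, test = NULL,
                mutations = ann))
  }
  expected <- n * bp / sum(bp)
  list(observed = obs, expected = expected,
       test = yates_chisq(obs, expected), mutations = ann)
}

#' Heterozygosity-versus-distance window profile around mutations
#'
#' For each mutation and window index `i` (0..`n_windows`-1), pools the two
#' `window_bp` flanks at distance `i * window_bp` (window 0 is the
#' 2 x 100 bp sequence surrounding the site) and computes the F1 SNP
#' heterozygosity as het sites / informative sites.  Mutation-windows with
#' fewer than `min_informative` informative bp are discarded; means and
#' standard errors are taken across mutations per window.
#'
#' @param mutations data.frame (chrom, pos).
#' @param het_sites data.frame (chrom, pos) of F1 heterozygous sites.
#' @param chrom_lengths named chromosome lengths.
#' @param informative optional data.frame (chrom, pos) of *uninformative*
#'   positions to exclude; by default every bp in bounds is informative.
#' @param n_windows,window_bp,min_informative profile geometry.
#' @param genome_average reference line (e.g. the F1 genomic heterozygosity);
#'   stored on the result.
#' @return a `window_profile` data.frame (window, distance_bp, mean, se, n).
#' @export
window_het_profile <- function(mutations, het_sites, chrom_lengths,
                               informative = NULL, n_windows = 20,
                               window_bp = 100, min_informative = 80,
                               genome_average = NA_real_) {
  het_by_chr <- split(het_sites$pos, het_sites$chrom)
  het_by_chr <- lapply(het_by_chr, sort)
  unin_by_chr <- if (is.null(informative)) list()
    else lapply(split(informative$pos, informative$chrom), sort)
  count_in <- function(sorted, lo, hi) {
    if (is.null(sorted) || hi < lo) return(0L)
    findInterval(hi, sorted) - findInterval(lo - 1e-9, sorted)
  }
  res <- array(NA_real_, dim = c(nrow(mutations), n_windows))
  for (i in seq_len(nrow(mutations))) {
    ch <- mutations$chrom[i]; p <- mutations$pos[i]
    L <- chrom_lengths[[ch]]
    hs <- het_by_chr[[ch]]; un <- unin_by_chr[[ch]]
    for (w in seq_len(n_windows)) {
      d <- (w - 1) * window_bp
      lo1 <- max(1, p - d - window_bp); hi1 <- p - d - 1
      lo2 <- p + d + 1; hi2 <- min(L, p + d + window_bp)
      bp <- max(0, hi1 - lo1 + 1) + max(0, min(hi2, L) - lo2 + 1)
      n_un <- count_in(un, lo1, hi1) + count_in(un, lo2, hi2)
      inf_bp <- bp - n_un
      if (inf_bp < min_informative) next
      n_het <- count_in(hs, lo1, hi1) + count_in(hs, lo2, hi2)
      res[i, w] <- n_het / inf_bp
    }
  }
  prof <- data.frame(
    window = seq_len(n_windows) - 1,
    distance_bp = (seq_len(n_windows) - 1) * window_bp,
    mean = colMeans(res, na.rm = TRUE),
    se = apply(res, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    n = colSums(!is.na(res)))
  attr(prof, "genome_average") <- genome_average
  class(prof) <- c("window_profile", "data.frame")
  prof
}

#' @export
print.window_profile <- function(x, ...) {
  cat("Heterozygosity-vs-distance profile (genome average",
      format(attr(x, "genome_average")), ")\n")
  print.data.frame(round(as.data.frame(x), 5))
  invisible(x)
}

#' Brunner-Munzel rank test of stochastic equality
#'
#' Two-sample nonparametric test robust to unequal variances, with mid-ranks
#' for ties, the t approximation on Satterthwaite degrees of freedom, and a
#' two-sided p value.  The estimate is the relative effect
#' P(X < Y) + 0.5 P(X = Y).  When the rank variance degenerates (e.g. all
#' values tied), the p value falls back to a permutation test with a warning.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param n_perm permutations for the degenerate fallback.
#' @return an object of class `htest`.
#' @export
brunner_munzel <- function(x, y, n_perm = 10000) {
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) stop("both samples must have size >= 2")
  r <- rank(c(x, y)); r1 <- r[seq_len(m)]; r2 <- r[m + seq_len(n)]
  m1 <- mean(r1); m2 <- mean(r2)
  p_hat <- (m2 - (n + 1) / 2) / m
  v1 <- sum((r1 - rank(x) - m1 + (m + 1) / 2)^2) / (m - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n + 1) / 2)^2) / (n - 1)
  vs <- m * v1 + n * v2
  if (vs <= 0) {
    warning("degenerate rank variance; using permutation p value")
    obs <- abs(p_hat - 0.5)
    pool <- c(x, y)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(m + n, m)
      rr <- rank(pool); abs((mean(rr[-idx]) - (n + 1) / 2) / m - 0.5)
    }, numeric(1))
    stat <- 0; df <- NA_real_
    pv <- mean(perm >= obs - 1e-12)
  } else {
    stat <- m * n * (m2 - m1) / ((m + n) * sqrt(vs))
    df <- vs^2 / ((m * v1)^2 / (m - 1) + (n * v2)^2 / (n - 1))
    pv <- 2 * stats::pt(-abs(stat), df)
  }
  structure(list(statistic = c(BM = stat), parameter = c(df = df),
                 p.value = pv,
                 estimate = c("P(X<Y) + .5 P(X=Y)" = p_hat),
                 method = "Brunner-Munzel test",
                 data.name = paste(deparse(substitute(x)), "vs",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Average pairwise per-site diversity
#'
#' Mean per-site difference over all unordered pairs of aligned haplotypes.
#'
#' @param x character/numeric matrix, haplotypes in rows, sites in columns
#'   (>= 2 rows).
#' @export
pairwise_diversity <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2) stop("need >= 2 aligned haplotypes")
  n <- nrow(x)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(x[i, ] != x[j, ]); np <- np + 1
  }
  tot / np
}
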