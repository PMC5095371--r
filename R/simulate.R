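#' Simulation settings for a synthetic pedigree group
#'
#' The defaults emulate the sequencing design the package targets: an F1 tree
#' heterozygous at a density set by its cross type (about 0.29% of sites for
#' an intraspecific cross, 1.24% for an interspecific one), selfed F2s whose
#' markers segregate 1:2:1, de novo mutations arising at ~1e-8 per site per
#' generation over the diploid genome, and stranded read counts at ~40x mean
#' depth with a per-base sequencing-error rate.
#'
#' @param cross_type `"interspecific"` (default) or `"intraspecific"`;
#'   sets the default marker density.
#' @param marker_density F1 heterozygous sites per bp; default 0.0124
#'   (interspecific) or 0.0029 (intraspecific).
#' @param n_f2 number of selfed F2 samples (>= 1).
#' @param true_mutation_rate per site per generation; mutations per F2 are
#'   Poisson with mean `2 * genome length * rate` (diploid genome).
#' @param depth_mean mean sequencing depth (Poisson depth model).
#' @param error_rate per-base sequencing error rate; an errored read is
#'   reassigned to a uniformly chosen different base.
#' @param indel_fraction fraction of injected mutations that are indels
#'   (default 46/286, the observed indel share); indel lengths uniform 1-10.
#' @param cluster_artifact_rate expected number of injected contamination
#'   clusters per genome (exercises the cluster mask).
#' @param n_shared number of shared (parental-somatic-like) mutations present
#'   in 2-5 F2s each and absent from the F1.
#' @param caller_profiles named numeric vector of per-candidate miss
#'   probabilities for the two emulated variant callers; defaults follow the
#'   observed consistency bookkeeping (HC lost ~4.6%, UG ~6.7% of SNVs).
#' @param segregation `"independent"` (each marker segregates independently,
#'   the default) or `"chromosome"` (whole-chromosome gametes; a crude block
#'   mode).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @export
sim_config <- function(cross_type = c("interspecific", "intraspecific"),
                       marker_density = NULL, n_f2 = 10,
                       true_mutation_rate = 1e-8, depth_mean = 40,
                       error_rate = 1e-3, indel_fraction = 46 / 286,
                       cluster_artifact_rate = 0, n_shared = 0,
                       caller_profiles = c(HC = 0.046, UG = 0.067),
                       segregation = c("independent", "chromosome"),
                       seed = 1L) {
  cross_type <- match.arg(cross_type)
  segregation <- match.arg(segregation)
  if (is.null(marker_density))
    marker_density <- if (cross_type == "interspecific") 0.0124 else 0.0029
  rates <- c(marker_density, true_mutation_rate, error_rate, indel_fraction,
             caller_profiles)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_f2 < 1) stop("n_f2 must be >= 1")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (length(caller_profiles) != 2 || is.null(names(caller_profiles)))
    stop("caller_profiles must be two named miss probabilities")
  structure(list(cross_type = cross_type, marker_density = marker_density,
                 n_f2 = n_f2, true_mutation_rate = true_mutation_rate,
                 depth_mean = depth_mean, error_rate = error_rate,
                 indel_fraction = indel_fraction,
                 cluster_artifact_rate = cluster_artifact_rate,
                 n_shared = n_shared, caller_profiles = caller_profiles,
                 segregation = segregation, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

rand_other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

## Stranded read counts for a site x sample grid.
## g: copies of the alt allele (0/1/2); is_indel flags rows whose alt allele
## cannot be created by a base-substitution error.  Returns a long
## data.table(row, allele_slot, n, fwd) with slots ref/alt/o1/o2/o3.
simulate_read_counts <- function(g, is_indel, depth_mean, error_rate) {
  n <- length(g)
  depth <- stats::rpois(n, depth_mean)
  n_alt <- ifelse(g == 1L, stats::rbinom(n, depth, 0.5),
                  ifelse(g == 2L, depth, 0L))
  n_ref <- depth - n_alt
  # errors leaving the ref allele
  e_ref <- stats::rbinom(n, n_ref, error_rate)
  ref_to_alt <- ifelse(is_indel, 0L, stats::rbinom(n, e_ref, 1 / 3))
  rest <- e_ref - ref_to_alt
  # distribute remaining errored ref reads over the non-ref, non-alt bases
  # (2 such bases at SNV sites, 3 at indel sites)
  o1 <- ifelse(is_indel, stats::rbinom(n, rest, 1 / 3),
               stats::rbinom(n, rest, 1 / 2))
  rest2 <- rest - o1
  o2 <- ifelse(is_indel, stats::rbinom(n, rest2, 1 / 2), rest2)
  o3 <- ifelse(is_indel, rest2 - o2, 0L)
  # errors leaving the alt allele (substitution alleles only)
  e_alt <- ifelse(is_indel, 0L, stats::rbinom(n, n_alt, error_rate))
  alt_to_ref <- stats::rbinom(n, e_alt, 1 / 3)
  alt_rest <- e_alt - alt_to_ref
  a1 <- stats::rbinom(n, alt_rest, 1 / 2)
  a2 <- alt_rest - a1
  cnt <- cbind(ref = n_ref - e_ref + alt_to_ref,
               alt = n_alt - e_alt + ref_to_alt,
               o1 = o1 + a1, o2 = o2 + a2, o3 = o3)
  fwd <- matrix(stats::rbinom(length(cnt), as.vector(cnt), 0.5), nrow = n)
  colnames(fwd) <- colnames(cnt)
  list(counts = cnt, fwd = fwd, depth = depth)
}

#' Simulate a pedigree group with known ground truth
#'
#' Builds the F1 marker set, draws F2 genotypes under 1:2:1 selfing
#' segregation, injects de novo mutations (and optional shared mutations and
#' contamination clusters), simulates stranded read counts for every variant
#' site and sample, and emulates two variant callers that each independently
#' miss candidate records with their profile's probability.
#'
#' @param genome a [make_genome()] object.
#' @param config a [sim_config()].
#' @return an object of class `sim_group` holding the truth set, the site
#'   table, per-sample genotypes, the stranded counts table and per-caller
#'   call masks; see [write_group()] to emit files.
#' @export
simulate_group <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- genome_length(genome)
  if (config$marker_density * L < 1)
    stop("marker_density x genome length < 1: no markers to segregate")
  group <- pedigree_group(
    id = "sim", cross_type = config$cross_type, f1 = "F1",
    f2 = sprintf("F2_%02d", seq_len(config$n_f2)),
    genome_length = L, gc_fraction = genome$gc_fraction)
  samples <- group_samples(group)
  ns <- length(samples)

  ## --- markers -------------------------------------------------------------
  n_mark <- stats::rbinom(1, L, config$marker_density)
  gpos <- sort(sample.int(L, n_mark))
  loc <- global_to_local(genome, gpos)
  ref <- genome_base_or_random(genome, loc$chrom, loc$pos)
  alt <- rand_other_base(ref)
  markers <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref,
                        alt = alt, origin_ref = "hapA", origin_alt = "hapB",
                        stringsAsFactors = FALSE)
  ## F2 genotypes at markers: copies of the alt (hapB) allele
  if (config$segregation == "independent") {
    f2_geno <- matrix(sample(0:2, n_mark * config$n_f2, replace = TRUE,
                             prob = c(0.25, 0.5, 0.25)),
                      nrow = n_mark, ncol = config$n_f2)
  } else {
    f2_geno <- matrix(0L, n_mark, config$n_f2)
    for (ci in genome$chrom$name) {
      on_c <- which(markers$chrom == ci)
      if (!length(on_c)) next
      gam <- matrix(sample(0:1, 2 * config$n_f2, replace = TRUE),
                    nrow = 2)
      f2_geno[on_c, ] <- matrix(rep(colSums(gam), each = length(on_c)),
                                nrow = length(on_c))
    }
  }
  colnames(f2_geno) <- group$f2

  ## --- de novo mutations ---------------------------------------------------
  n_mut_per_f2 <- stats::rpois(config$n_f2, 2 * L * config$true_mutation_rate)
  used <- gpos
  mut_list <- list()
  for (j in seq_len(config$n_f2)) {
    if (n_mut_per_f2[j] == 0) next
    mp <- draw_free_positions(L, n_mut_per_f2[j], used)
    used <- c(used, mp)
    mut_list[[j]] <- build_mutations(genome, mp, group$f2[j], config)
  }
  mutations <- do.call(rbind, mut_list)
  if (is.null(mutations)) mutations <- empty_mutations()

  ## --- shared (parental somatic) mutations --------------------------------
  shared <- empty_mutations()
  shared$carriers <- character(0)
  if (config$n_shared > 0) {
    sp <- draw_free_positions(L, config$n_shared, used)
    used <- c(used, sp)
    shared <- build_mutations(genome, sp, NA_character_, config,
                              snv_only = TRUE)
    shared$carriers <- vapply(seq_len(nrow(shared)), function(i) {
      paste(sample(group$f2, sample(2:5, 1)), collapse = ",")
    }, character(1))
  }

  ## --- contamination clusters ----------------------------------------------
  artifacts <- empty_mutations()
  n_art <- stats::rpois(1, config$cluster_artifact_rate)
  if (n_art > 0) {
    starts <- draw_free_positions(L, n_art, used, margin = 12)
    art_l <- lapply(starts, function(s) {
      ap <- s + sort(c(0, sample(1:9, 3)))       # 4 substitutions within 10 bp
      a <- build_mutations(genome, ap, sample(group$f2, 1), config,
                           snv_only = TRUE)
      a$kind <- "artifact"
      a
    })
    artifacts <- do.call(rbind, art_l)
    used <- c(used, artifacts$gpos)
  }

  ## --- site table and genotype matrix -------------------------------------
  sites <- rbind(
    data.frame(chrom = markers$chrom, pos = markers$pos, gpos = gpos,
               ref = markers$ref, alt = markers$alt, kind = "marker",
               type = "snv", focal = NA_character_, stringsAsFactors = FALSE),
    sites_from_mut(mutations), sites_from_mut(shared), sites_from_mut(artifacts))
  geno <- matrix(0L, nrow(sites), ns, dimnames = list(NULL, samples))
  geno[seq_len(n_mark), group$f1] <- 1L
  geno[seq_len(n_mark), group$f2] <- f2_geno
  extra <- which(sites$kind != "marker")
  for (i in extra) {
    if (sites$kind[i] == "shared") {
      k <- which(sites$gpos[i] == shared$gpos)
      geno[i, strsplit(shared$carriers[k], ",")[[1]]] <- 1L
    } else {
      geno[i, sites$focal[i]] <- 1L
    }
  }
  ord <- order(match(sites$chrom, genome$chrom$name), sites$pos)
  sites <- sites[ord, ]; geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL

  ## --- read counts ---------------------------------------------------------
  nsite <- nrow(sites)
  grid_g <- as.vector(geno)                       # site-major within sample
  grid_indel <- rep(sites$type == "indel", ns)
  rc <- simulate_read_counts(grid_g, grid_indel, config$depth_mean,
                             config$error_rate)
  counts <- counts_long(sites, samples, rc)
  ad <- list(ref = matrix(rc$counts[, "ref"], nsite, ns,
                          dimnames = list(NULL, samples)),
             alt = matrix(rc$counts[, "alt"], nsite, ns,
                          dimnames = list(NULL, samples)),
             dp = matrix(rc$depth, nsite, ns, dimnames = list(NULL, samples)))

  ## --- caller emulation ----------------------------------------------------
  candidate <- sites$kind != "marker"
  caller_keep <- lapply(config$caller_profiles, function(miss) {
    keep <- rep(TRUE, nsite)
    keep[candidate] <- stats::runif(sum(candidate)) >= miss
    keep
  })

  structure(list(genome = genome, config = config, group = group,
                 truth = list(markers = markers, f2_genotypes = f2_geno,
                              injected_mutations = mutations,
                              shared_mutations = shared,
                              artifacts = artifacts),
                 sites = sites, geno = geno, counts = counts,
                 ad = ad, caller_keep = caller_keep),
            class = "sim_group")
}

#' @export
print.sim_group <- function(x, ...) {
  cat("Simulated pedigree group:", length(x$group$f2), "F2s,",
      nrow(x$truth$markers), "markers,",
      nrow(x$truth$injected_mutations), "injected mutations\n")
  invisible(x)
}

genome_base_or_random <- function(genome, chrom, pos) {
  if (is.null(genome$seq))
    sample(BASES, length(pos), replace = TRUE)
  else genome_base(genome, chrom, pos)
}

draw_free_positions <- function(L, n, used, margin = 0) {
  p <- numeric(0)
  while (length(p) < n) {
    cand <- sample.int(L - margin, n - length(p))
    cand <- setdiff(cand, c(used, p))
    p <- c(p, cand)
  }
  sort(p)
}

build_mutations <- function(genome, gpos, focal, config, snv_only = FALSE) {
  loc <- global_to_local(genome, gpos)
  n <- length(gpos)
  is_indel <- if (snv_only) rep(FALSE, n)
              else stats::runif(n) < config$indel_fraction
  ref <- genome_base_or_random(genome, loc$chrom, loc$pos)
  alt <- rand_other_base(ref)
  len <- integer(n)
  for (i in which(is_indel)) {
    l <- sample(1:10, 1)
    if (stats::runif(1) < 0.5) {                 # insertion
      alt[i] <- paste0(ref[i], paste(sample(BASES, l, replace = TRUE),
                                     collapse = ""))
      len[i] <- l
    } else {                                     # deletion
      cl <- genome$chrom$length[genome$chrom$name == loc$chrom[i]]
      l <- min(l, cl - loc$pos[i])
      if (l < 1) { is_indel[i] <- FALSE; next }
      del <- genome_base_or_random(genome, rep(loc$chrom[i], l),
                                   loc$pos[i] + seq_len(l))
      if (!is.null(genome$seq))
        del <- strsplit(genome_base(genome, loc$chrom[i], loc$pos[i] + 1, l),
                        "")[[1]]
      alt[i] <- ref[i]
      ref[i] <- paste0(ref[i], paste(del, collapse = ""))
      len[i] <- l
    }
  }
  data.frame(chrom = loc$chrom, pos = loc$pos, gpos = gpos, ref = ref,
             alt = alt, sample = focal,
             type = ifelse(is_indel, "indel", "snv"),
             len = len, mult3 = is_indel & len %% 3 == 0,
             kind = if (is.null(focal) || all(is.na(focal))) "shared" else "mutation",
             stringsAsFactors = FALSE)
}

empty_mutations <- function() {
  data.frame(chrom = character(0), pos = numeric(0), gpos = numeric(0),
             ref = character(0), alt = character(0), sample = character(0),
             type = character(0), len = integer(0), mult3 = logical(0),
             kind = character(0), stringsAsFactors = FALSE)
}

sites_from_mut <- function(m) {
  if (!nrow(m)) return(NULL)
  data.frame(chrom = m$chrom, pos = m$pos, gpos = m$gpos, ref = m$ref,
             alt = m$alt, kind = m$kind, type = m$type, focal = m$sample,
             stringsAsFactors = FALSE)
}

## long stranded counts table from the grid results
counts_long <- function(sites, samples, rc) {
  nsite <- nrow(sites); ns <- length(samples)
  slot_allele <- function(slot) {
    if (slot == "ref") return(rep(sites$ref, ns))
    if (slot == "alt") return(rep(sites$alt, ns))
    # deterministic other-base alleles per site: bases not equal to the ref
    # first base nor to a single-base alt
    oth <- t(vapply(seq_len(nsite), function(i) {
      r1 <- substr(sites$ref[i], 1, 1)
      excl <- if (nchar(sites$ref[i]) == 1 && nchar(sites$alt[i]) == 1)
        c(r1, sites$alt[i]) else r1
      ob <- setdiff(BASES, excl)
      length(ob) <- 3
      ob
    }, character(3)))
    rep(oth[, match(slot, c("o1", "o2", "o3"))], ns)
  }
  parts <- lapply(colnames(rc$counts), function(slot) {
    n <- rc$counts[, slot]
    keep <- n > 0
    if (!any(keep)) return(NULL)
    data.table::data.table(
      chrom = rep(sites$chrom, ns)[keep], pos = rep(sites$pos, ns)[keep],
      sample = rep(samples, each = nsite)[keep],
      allele = slot_allele(slot)[keep],
      fwd_reads = rc$fwd[keep, slot], rev_reads = n[keep] - rc$fwd[keep, slot])
  })
  out <- data.table::rbindlist(parts)
  out <- out[!is.na(out$allele)]
  data.table::setkeyv(out[order(chrom, pos, sample)], c("chrom", "pos"))[]
}

#' Genotype classes at simulated non-variant sites
#'
#' Draws read counts for `n` reference-homozygous sites under a group's depth
#' and error model and classifies them, giving the homozygous-callable stream
#' needed for heterozygosity estimation (het sites / (het + hom sites)).
#'
#' @param config a [sim_config()].
#' @param n number of non-variant sites.
#' @return character vector of genotype classes.
#' @export
simulate_nonvariant_classes <- function(config, n) {
  depth <- stats::rpois(n, config$depth_mean)
  err <- stats::rbinom(n, depth, config$error_rate)
  classify_genotype(depth - err, err)
}

#' In-memory per-caller site calls from a simulated group
#'
#' @param sim a `sim_group`.
#' @param caller caller name or index in the config's `caller_profiles`.
#' @return a `site_calls` object (as from [read_site_calls()]).
#' @export
sim_site_calls <- function(sim, caller = 1) {
  keep <- sim$caller_keep[[caller]]
  site_calls(chrom = sim$sites$chrom[keep], pos = sim$sites$pos[keep],
             ref = sim$sites$ref[keep], alt = sim$sites$alt[keep],
             qual = rep(999, sum(keep)),
             ref_ad = sim$ad$ref[keep, , drop = FALSE],
             alt_ad = sim$ad$alt[keep, , drop = FALSE])
}

#' Inject a contamination-like cluster of substitutions
#'
#' Adds `n_subs` correlated non-parental substitution alleles within `span` bp
#' in one sample, re-drawing read counts for the new sites, so that the
#' downstream cluster mask can be exercised.  Operates on a `sim_group`
#' before [write_group()].
#'
#' @param sim a `sim_group`.
#' @param chrom,pos locus of the first substitution.
#' @param sample focal sample name.
#' @param n_subs number of substitutions (>= 1).
#' @param span window in bp containing all substitutions (>= 1).
#' @export
inject_cluster_artifact <- function(sim, chrom, pos, sample,
                                    n_subs = 4, span = 10) {
  stopifnot(inherits(sim, "sim_group"))
  if (span < 1) stop("span must be >= 1")
  cl <- sim$genome$chrom$length[sim$genome$chrom$name == chrom]
  if (!length(cl) || pos < 1 || pos + span - 1 > cl)
    stop("locus outside chromosome bounds")
  offs <- if (n_subs > 1) sort(c(0, sample(seq_len(span - 1), n_subs - 1)))
          else 0
  p <- pos + offs
  off0 <- chrom_offsets(sim$genome)[match(chrom, sim$genome$chrom$name)]
  a <- build_mutations(sim$genome, off0 + p, sample, sim$config,
                       snv_only = TRUE)
  a$kind <- "artifact"
  new_sites <- sites_from_mut(a)
  samples <- colnames(sim$geno)
  geno <- matrix(0L, nrow(new_sites), length(samples),
                 dimnames = list(NULL, samples))
  geno[, sample] <- 1L
  rc <- simulate_read_counts(as.vector(geno),
                             rep(FALSE, length(geno)),
                             sim$config$depth_mean, sim$config$error_rate)
  add <- counts_long(new_sites, samples, rc)
  sim$sites <- rbind(sim$sites, new_sites)
  sim$geno <- rbind(sim$geno, geno)
  sim$ad$ref <- rbind(sim$ad$ref, matrix(rc$counts[, "ref"], nrow(new_sites)))
  sim$ad$alt <- rbind(sim$ad$alt, matrix(rc$counts[, "alt"], nrow(new_sites)))
  sim$ad$dp <- rbind(sim$ad$dp, matrix(rc$depth, nrow(new_sites)))
  sim$counts <- data.table::setkeyv(
    rbind(sim$counts, add)[order(chrom, pos, sample)], c("chrom", "pos"))
  sim$truth$artifacts <- rbind(sim$truth$artifacts[
    , setdiff(names(sim$truth$artifacts), "carriers"), drop = FALSE], a)
  for (k in seq_along(sim$caller_keep))
    sim$caller_keep[[k]] <- c(sim$caller_keep[[k]], rep(TRUE, nrow(new_sites)))
  sim
}
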