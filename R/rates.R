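#' Exact (Garwood) Poisson confidence interval
#'
#' Chi-square-quantile construction: for an observed count `k`, the two-sided
#' interval is `[qchisq(a/2, 2k)/2, qchisq(1-a/2, 2k+2)/2]`, with lower bound
#' 0 at `k = 0` (one-sided upper interval).
#'
#' @param k non-negative integer count(s).
#' @param conf confidence level.
#' @return matrix with columns `lower`, `upper`.
#' @export
poisson_ci <- function(k, conf = 0.95) {
  a <- 1 - conf
  lower <- ifelse(k == 0, 0, stats::qchisq(a / 2, 2 * k) / 2)
  upper <- stats::qchisq(1 - a / 2, 2 * (k + 1)) / 2
  cbind(lower = lower, upper = upper)
}

#' Estimate the callable fraction of the genome by mutation injection
#'
#' Injects synthetic derived alleles (allele fraction ~0.5 at the local
#' depth) at uniformly sampled genomic sites of one F2 in a simulated group,
#' pushes each through the full confident-site + candidate-evaluation chain,
#' and reports the fraction recovered as PASS.  Sites colliding with existing
#' variant loci (the injected allele would be a third allele) and sites in
#' the structural-variant mask count as uncallable.
#'
#' @param sim a [simulate_group()] result.
#' @param n_injected number of injected sites (>= 1).
#' @param focal F2 receiving the injections (default: first F2).
#' @param sv_mask optional `GRanges` mask.
#' @param seed integer seed for the injection draws.
#' @param depth_fun optional function(n) returning per-site per-sample depths,
#'   overriding the group's Poisson depth model (for constructed profiles).
#' @param min_depth,max_depth callable-depth window used for genotype
#'   classification (see [classify_genotype()]).
#' @param ... detection parameters passed to [evaluate_candidates()].
#' @return a `callable_estimate`: fraction, n_injected, n_recovered.
#' @export
estimate_callable_fraction <- function(sim, n_injected = 1000, focal = NULL,
                                       sv_mask = NULL, seed = 1,
                                       depth_fun = NULL, min_depth = 10,
                                       max_depth = 80, ...) {
  stopifnot(inherits(sim, "sim_group"))
  if (n_injected < 1) stop("n_injected must be >= 1")
  set.seed(seed)
  group <- sim$group
  if (is.null(focal)) focal <- group$f2[1]
  L <- genome_length(sim$genome)
  gpos <- sample.int(L, n_injected, replace = TRUE)
  collide <- gpos %in% sim$sites$gpos
  loc <- global_to_local(sim$genome, gpos)
  ref <- genome_base_or_random(sim$genome, loc$chrom, loc$pos)
  alt <- rand_other_base(ref)
  samples <- colnames(sim$geno)
  nsite <- n_injected
  geno <- matrix(0L, nsite, length(samples), dimnames = list(NULL, samples))
  geno[, focal] <- 1L
  cfg <- sim$config
  grid_g <- as.vector(geno)
  if (is.null(depth_fun)) {
    rc <- simulate_read_counts(grid_g, rep(FALSE, length(grid_g)),
                               cfg$depth_mean, cfg$error_rate)
  } else {
    depth <- depth_fun(length(grid_g))
    n_alt <- ifelse(grid_g == 1L, stats::rbinom(length(grid_g), depth, 0.5), 0L)
    rc <- list(counts = cbind(ref = depth - n_alt, alt = n_alt,
                              o1 = 0L, o2 = 0L, o3 = 0L),
               fwd = NULL, depth = depth)
    rc$fwd <- matrix(stats::rbinom(length(rc$counts),
                                   as.vector(rc$counts), 0.5),
                     nrow = length(grid_g),
                     dimnames = list(NULL, colnames(rc$counts)))
  }
  # unique synthetic positions so the mini call set has one row per injection
  inj_sites <- data.frame(chrom = "injected", pos = seq_len(nsite),
                          gpos = gpos, ref = ref, alt = alt,
                          kind = "injection", type = "snv", focal = focal,
                          stringsAsFactors = FALSE)
  counts <- counts_long(inj_sites, samples, rc)
  sc <- site_calls(chrom = inj_sites$chrom, pos = inj_sites$pos, ref = ref,
                   alt = alt, qual = rep(999, nsite),
                   ref_ad = matrix(rc$counts[, "ref"], nsite,
                                   dimnames = list(NULL, samples)),
                   alt_ad = matrix(rc$counts[, "alt"], nsite,
                                   dimnames = list(NULL, samples)))
  scf <- filter_confident_sites(sc, group, min_depth = min_depth,
                                max_depth = max_depth)
  cand <- find_rare_candidates(scf, group)
  cand <- cand[cand$sample == focal & cand$allele == cand$alt, , drop = FALSE]
  if (nrow(cand)) cand <- evaluate_candidates(cand, counts, scf, group, ...)
  passed_pos <- cand$pos[cand$status == "PASS"]
  recovered <- seq_len(nsite) %in% passed_pos & !collide &
    !in_sv_mask(loc$chrom, loc$pos, sv_mask)
  structure(list(group = group$id, callable_fraction = mean(recovered),
                 n_injected = n_injected, n_recovered = sum(recovered)),
            class = "callable_estimate")
}

#' @export
print.callable_estimate <- function(x, ...) {
  cat(sprintf("Callable fraction (group %s): %.3f (%d of %d injected recovered)\n",
              x$group, x$callable_fraction, x$n_recovered, x$n_injected))
  invisible(x)
}

#' Per-sample mutation counts and group summary statistics
#'
#' @param mutations data.frame with `sample` and `type` columns (one row per
#'   mutation), e.g. the `$mutations` slot of [detect_mutations()].
#' @param group a [pedigree_group()]; zero-count F2s are included.
#' @return a `group_summary`: per-sample SNV/indel counts, means and standard
#'   errors (sample sd / sqrt(n)).
#' @export
summarize_group <- function(mutations, group) {
  bad <- setdiff(unique(mutations$sample), group_samples(group))
  if (length(bad))
    stop("mutation sample(s) not in group roster: ", paste(bad, collapse = ", "))
  tab <- data.frame(sample = group$f2, stringsAsFactors = FALSE)
  tab$snv <- vapply(group$f2, function(s)
    sum(mutations$sample == s & mutations$type == "snv"), 0)
  tab$indel <- vapply(group$f2, function(s)
    sum(mutations$sample == s & mutations$type == "indel"), 0)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  structure(list(group = group$id, table = tab, n_f2 = length(group$f2),
                 mean = c(snv = mean(tab$snv), indel = mean(tab$indel)),
                 se = c(snv = se(tab$snv), indel = se(tab$indel)),
                 total = c(snv = sum(tab$snv), indel = sum(tab$indel))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group %s (%d F2s): %d SNVs, %d indels\n", x$group, x$n_f2,
              x$total["snv"], x$total["indel"]))
  cat(sprintf("  mean (+/- s.e.): %.2f +/- %.2f SNV, %.2f +/- %.2f indel\n",
              x$mean["snv"], x$se["snv"], x$mean["indel"], x$se["indel"]))
  invisible(x)
}

#' Per-site per-generation mutation rate with exact Poisson 95% CI
#'
#' mu = mean mutations per F2 / (2 x callable fraction x genome length); the
#' confidence interval scales the exact Poisson interval on the total count:
#' `mu * [L(k), U(k)] / k` (one-sided upper interval when k = 0).
#'
#' @param summary a [summarize_group()] result, or a list with `total` and
#'   `n_f2` (total mutation count and number of F2s).
#' @param callable a [estimate_callable_fraction()] result or a bare fraction.
#' @param genome_length haploid reference genome length in bp.
#' @param type `"snv"` or `"indel"` (which count of the summary to use).
#' @param conf confidence level.
#' @return a `rate_estimate` with `mu`, `ci_low`, `ci_high`, `total_count`,
#'   `haploid_sites`.
#' @export
estimate_rate <- function(summary, callable, genome_length, type = "snv",
                          conf = 0.95) {
  cf <- if (inherits(callable, "callable_estimate"))
    callable$callable_fraction else as.numeric(callable)
  if (cf <= 0) stop("callable fraction must be > 0")
  k <- if (is.null(names(summary$total))) summary$total[1]
       else summary$total[[type]]
  n <- summary$n_f2
  haploid <- cf * genome_length
  mu <- (k / n) / (2 * haploid)
  ci <- poisson_ci(k, conf)
  structure(list(mu = mu,
                 ci_low = unname(ci[1, "lower"]) / n / (2 * haploid),
                 ci_high = unname(ci[1, "upper"]) / n / (2 * haploid),
                 total_count = k, n_f2 = n, callable_fraction = cf,
                 haploid_sites = haploid, type = type, conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s mutation rate: %.3g per site per generation (%.0f%% CI %.3g - %.3g)\n",
              x$type, x$mu, 100 * x$conf, x$ci_low, x$ci_high))
  cat(sprintf("  %d mutations / %d F2s over 2 x %.4g callable haploid bp\n",
              x$total_count, x$n_f2, x$haploid_sites))
  invisible(x)
}

#' Fold difference between two rate estimates
#' @param a,b `rate_estimate` objects (numerator, denominator).
#' @export
rate_ratio <- function(a, b) {
  if (b$mu == 0) stop("denominator rate is zero")
  a$mu / b$mu
}
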