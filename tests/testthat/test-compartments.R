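tile_ok <- function(map, chrom_lengths) {
  for (ch in names(chrom_lengths)) {
    m <- map[map$chrom == ch, ]
    m <- m[order(m$start), ]
    if (!nrow(m)) return(FALSE)
    if (m$start[1] != 1 || m$end[nrow(m)] != chrom_lengths[[ch]]) return(FALSE)
    if (nrow(m) > 1 && any(m$start[-1] != m$end[-nrow(m)] + 1)) return(FALSE)
  }
  TRUE
}

test_that("compartment intervals plus unassigned gaps tile each chromosome", {
  mk <- data.frame(chrom = rep(c("c1", "c2"), c(5, 3)),
                   pos = c(100, 200, 300, 400, 500, 50, 150, 900),
                   origin_ref = "hapA", origin_alt = "hapB")
  cls <- matrix(c("het", "het", "hom_ref", "hom_ref", "het",
                  "hom_alt", "hom_alt", "ambiguous"), ncol = 1,
                dimnames = list(NULL, "F2_01"))
  cl <- c(c1 = 1000, c2 = 1000)
  cm <- assign_compartments(mk, cls, cl)
  m <- cm$maps$F2_01
  expect_true(tile_ok(m, cl))
  # run structure on c1: het (100-250), hom (251-450), het (451-500)
  c1 <- m[m$chrom == "c1" & m$state != "unassigned", ]
  expect_equal(c1$state, c("het", "hom", "het"))
  expect_equal(c1$start, c(100, 251, 451))
  expect_equal(c1$end, c(250, 450, 500))
  expect_equal(c1$origin[2], "hapA")       # hom_ref run carries hapA
  # c2: ambiguous marker ignored; single hom_alt run labelled hapB
  c2 <- m[m$chrom == "c2" & m$state != "unassigned", ]
  expect_equal(c2$state, "hom")
  expect_equal(c2$origin, "hapB")
  expect_equal(c2$end, 150)
})

test_that("an all-het F2 yields one het interval per chromosome and empty chromosomes stay unassigned", {
  mk <- data.frame(chrom = "c1", pos = c(10, 500, 990))
  cls <- matrix("het", 3, 1, dimnames = list(NULL, "s"))
  cm <- assign_compartments(mk, cls, c(c1 = 1000, c2 = 500))
  m <- cm$maps$s
  expect_equal(sum(m$state == "het"), 1)
  expect_equal(m$state[m$chrom == "c2"], "unassigned")
})

test_that("compartments recover simulated truth states at high marker density", {
  sim <- sim20kb(seed = 91, error_rate = 0, rate = 0, marker_density = 0.01)
  scf <- filter_confident_sites(sim_site_calls(sim, 1), sim$group)
  mk <- build_marker_set(scf, "F1", origins = sim$truth$markers)
  idx <- match(paste(mk$chrom, mk$pos),
               paste(scf$info$chrom, scf$info$pos))
  cl <- stats::setNames(sim$genome$chrom$length, sim$genome$chrom$name)
  cm <- assign_compartments(mk, pedimut:::genotype_classes(scf)[
    idx, sim$group$f2, drop = FALSE], cl)
  for (m in cm$maps) expect_true(tile_ok(m, cl))
  # truth state at every true marker vs the interval covering it
  tm <- sim$truth$markers
  acc <- vapply(sim$group$f2, function(s) {
    truth_state <- ifelse(sim$truth$f2_genotypes[, s] == 1, "het", "hom")
    got <- map_mutations_to_compartments(
      data.frame(chrom = tm$chrom, pos = tm$pos, sample = s), cm)$state
    mean(got == truth_state)
  }, numeric(1))
  expect_gt(mean(acc), 0.99)
  expect_lt(abs(mean(compartment_het_fraction(cm)) - 0.5), 0.1)
})

test_that("observed versus expected compartment counts behave under the null", {
  # constructed map: 60% het, 40% hom; mutations uniform
  cmap <- structure(list(maps = list(
    s1 = data.frame(chrom = "c1", start = c(1, 601), end = c(600, 1000),
                    state = c("het", "hom"), origin = NA)),
    chrom_lengths = c(c1 = 1000)), class = "compartment_map")
  set.seed(12)
  muts <- data.frame(chrom = "c1", pos = sample(1000, 200, replace = TRUE),
                     sample = "s1")
  cc <- compartment_counts(muts, cmap)
  expect_equal(sum(cc$observed), 200)
  expect_equal(unname(cc$expected), c(120, 80))
  expect_true(cc$test$p.value > 0.01)   # uniform placement: no signal
  # weighted (composition-corrected) expectations shift accordingly
  cw <- compartment_counts(muts, cmap, weights = c(het = 2, hom = 1))
  expect_equal(unname(cw$expected), 200 * c(1200, 400) / 1600)
  # a degenerate map with no hom compartment skips the test with a warning
  cmap0 <- cmap
  cmap0$maps$s1$state <- c("het", "het")
  expect_warning(c0 <- compartment_counts(muts, cmap0), "skipped")
  expect_null(c0$test)
})

test_that("the window profile is flat under uniform placement and enriched under planting", {
  set.seed(31)
  L <- 4e5
  het <- data.frame(chrom = "c1", pos = sort(sample(L, 0.0124 * L)))
  cl <- c(c1 = L)
  avg <- nrow(het) / L
  uni <- data.frame(chrom = "c1", pos = sample(seq(3000, L - 3000), 120))
  prof <- window_het_profile(uni, het, cl, genome_average = avg)
  expect_equal(nrow(prof), 20)
  expect_true(all(abs(prof$mean - avg) <= 4 * prof$se))
  slope <- coef(lm(mean ~ distance_bp, data = prof))[["distance_bp"]]
  expect_lt(abs(slope) * 1900, 0.5 * avg)   # flat across the profiled range
  # planted proximity: mutations placed within 150 bp of a het site
  near <- data.frame(chrom = "c1",
                     pos = sample(het$pos, 120) +
                       sample(c(-150:-1, 1:150), 120, replace = TRUE))
  near <- near[near$pos > 3000 & near$pos < L - 3000, , drop = FALSE]
  prof2 <- window_het_profile(near, het, cl, genome_average = avg)
  expect_gt(prof2$mean[1], avg)
  slope2 <- coef(lm(mean ~ distance_bp, data = prof2))[["distance_bp"]]
  expect_lt(slope2, 0)
  expect_gt(prof2$mean[1], mean(prof2$mean[15:20]))
})

test_that("the Brunner-Munzel test matches its permutation oracle and controls type I error", {
  x <- c(1, 3, 5, 7, 9, 11)
  expect_equal(unname(brunner_munzel(x, x)$statistic), 0)
  expect_equal(unname(brunner_munzel(x, x)$estimate), 0.5)
  # published-style comparison: interspecific counts are stochastically higher
  counts <- peach_mutation_counts()
  intra <- counts$snv[counts$cross == "intraspecific"]
  inter <- counts$snv[counts$cross == "interspecific"]
  bm <- brunner_munzel(intra, inter)
  expect_lt(bm$p.value, 1e-3)
  expect_gt(unname(bm$estimate), 0.5)
  # studentised permutation oracle on random small data sets
  set.seed(71)
  for (i in 1:15) {
    a <- rpois(8 + i %% 4, 3)
    b <- rpois(10, 3 + (i %% 3))
    if (length(unique(c(a, b))) < 3) next
    bm_i <- suppressWarnings(brunner_munzel(a, b))
    if (!is.finite(bm_i$statistic) || is.na(bm_i$parameter)) next
    expect_lt(abs(bm_i$p.value - perm_bm_p(a, b, 1500)), 0.06)
  }
  # degenerate variance falls back to permutation with a warning
  expect_warning(dg <- brunner_munzel(rep(1, 5), rep(1, 6)), "degenerate")
  expect_gte(dg$p.value, 0.99)
  # type-I error under the null
  set.seed(81)
  rej <- mean(replicate(600, {
    brunner_munzel(rnorm(12), rnorm(12))$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("pairwise diversity equals the brute-force pair average", {
  a <- rep("A", 100)
  expect_equal(pairwise_diversity(rbind(a, a)), 0)
  h1 <- rep("A", 1e4); h2 <- h1; h2[1:124] <- "G"
  expect_equal(pairwise_diversity(rbind(h1, h2)), 0.0124)
  set.seed(5)
  m <- matrix(sample(c("A", "C"), 3 * 50, replace = TRUE), nrow = 3)
  brute <- mean(c(mean(m[1, ] != m[2, ]), mean(m[1, ] != m[3, ]),
                  mean(m[2, ] != m[3, ])))
  expect_equal(pairwise_diversity(m), brute)
  expect_error(pairwise_diversity(matrix("A", 1, 5)), "haplotypes")
})
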