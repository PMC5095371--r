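make_group <- function(n_f2, f1 = "F1") {
  pedigree_group("t", "intraspecific", f1 = f1,
                 f2 = sprintf("F2_%02d", seq_len(n_f2)))
}

test_that("rare-variant screening uses carrier counts with a strict bound", {
  grp <- make_group(5)
  samples <- group_samples(grp)
  het <- function() list(ad = c(10, 10), reads = list(A = c(5, 5), T = c(3, 3)))
  sites <- list(
    # alt in exactly 1 F2 -> candidate
    std_site(pos = 100, samples = samples,
             override = list(F2_01 = het())),
    # alt in 3 samples -> not a candidate
    std_site(pos = 200, samples = samples,
             override = list(F2_01 = het(), F2_02 = het(), F2_03 = het())),
    # alt in F1 and 1 F2 -> enters, masked later as allele_elsewhere
    std_site(pos = 300, samples = samples,
             override = list(F1 = het(), F2_02 = het())))
  fx <- build_fixture(sites, samples)
  scf <- filter_confident_sites(fx$sc, grp)
  cand <- find_rare_candidates(scf, grp)
  expect_equal(cand$pos[cand$allele == "T"], c(100, 300))
  ev <- evaluate_candidates(cand, fx$counts, scf, grp)
  ev300 <- ev[ev$pos == 300 & ev$allele == "T", ]
  expect_equal(ev300$status, "masked")
  expect_match(ev300$reasons, "allele_elsewhere")
  expect_equal(ev[ev$pos == 100, "status"], "PASS")
})

test_that("read-support evaluation applies the strand and background rules", {
  grp <- make_group(13)  # informative majority survives six missing F2s
  samples <- group_samples(grp)
  focal <- function(reads_alt) {
    list(ad = c(10, 10), reads = list(A = c(5, 5), T = reads_alt))
  }
  missing6 <- setNames(rep(list(list(ad = c(3, 0), reads = list())), 6),
                       sprintf("F2_%02d", 3:8))
  sites <- list(
    # 6 reads (4 fwd, 2 rev), informative parent, allele nowhere else -> PASS
    std_site(pos = 100, samples = samples,
             override = list(F2_01 = focal(c(4, 2)))),
    # 5 reads all forward -> no strand pair
    std_site(pos = 200, samples = samples,
             override = list(F2_01 = focal(c(5, 0)))),
    # only 4 supporting reads -> low_support
    std_site(pos = 300, samples = samples,
             override = list(F2_01 = focal(c(2, 2)))),
    # parent not informative
    modifyList(std_site(pos = 400, samples = samples,
                        override = list(F2_01 = focal(c(4, 2)))),
               list()),
    # six other F2s missing -> excess_missing (boundary is five)
    std_site(pos = 500, samples = samples,
             override = c(list(F2_01 = focal(c(4, 2))), missing6)))
  sites[[4]]$ad$F1 <- c(3, 0)
  fx <- build_fixture(sites, samples)
  scf <- filter_confident_sites(fx$sc, grp)
  cand <- find_rare_candidates(scf, grp)
  ev <- evaluate_candidates(cand, fx$counts, scf, grp)
  ev <- ev[ev$allele == "T", ]
  get <- function(p) ev[ev$pos == p & ev$sample == "F2_01", ]
  expect_equal(get(100)$status, "PASS")
  expect_equal(get(100)$reasons, "")
  expect_match(get(200)$reasons, "no_strand_pair")
  expect_match(get(300)$reasons, "low_support")
  expect_match(get(400)$reasons, "parental_background_missing")
  expect_match(get(500)$reasons, "excess_missing")
  # the stricter per-strand reading is exposed as an option
  ev2 <- evaluate_candidates(cand, fx$counts, scf, grp, min_strand_reads = 5)
  expect_match(ev2[ev2$pos == 100 & ev2$allele == "T", "reasons"],
               "no_strand_pair")
})

test_that("soft-masking conserves every candidate", {
  sim <- sim20kb(seed = 61, rate = 3e-5, cluster_artifact_rate = 1)
  scf <- filter_confident_sites(sim_site_calls(sim, 1), sim$group)
  det <- detect_mutations(list(A = scf), sim$counts, sim$group)
  cc <- det$candidates$A
  expect_equal(nrow(cc), sum(cc$status == "PASS") + sum(cc$status == "masked"))
  expect_true(all(cc$reasons[cc$status == "masked"] != ""))
  expect_true(all(cc$reasons[cc$status == "PASS"] == ""))
})

test_that("cluster masking uses sliding windows at the stated thresholds", {
  grp <- make_group(2)
  cand <- data.frame(
    chrom = "chr1",
    pos = c(10, 12, 15, 19, 100, 104, 109, 500, 510, 519, 800, 815),
    ref = "A", alt = "T", allele = "T",
    sample = "F2_01",
    type = c(rep("snv", 7), rep("indel", 5)),
    status = "PASS", reasons = "", stringsAsFactors = FALSE)
  out <- apply_cluster_mask(cand)
  # 4 SNVs in 10 bp -> masked; 3 SNVs in 10 bp -> untouched
  expect_true(all(out$status[out$pos %in% c(10, 12, 15, 19)] == "masked"))
  expect_true(all(grepl("cluster", out$reasons[out$pos <= 19])))
  expect_true(all(out$status[out$pos %in% c(100, 104, 109)] == "PASS"))
  # 3 indels within 20 bp -> masked; 2 indels -> untouched
  expect_true(all(out$status[out$pos %in% c(500, 510, 519)] == "masked"))
  expect_true(all(out$status[out$pos %in% c(800, 815)] == "PASS"))
})

test_that("caller-set union reproduces the published consistency bookkeeping", {
  mk <- function(pos, sample, type = "snv") data.frame(
    chrom = "chr1", pos = pos, ref = "A", alt = "T", sample = sample,
    type = type, stringsAsFactors = FALSE)
  shared <- mk(seq_len(213) * 100, "F2_01")
  only_a <- mk(50000 + seq_len(11) * 100, "F2_02")
  only_b <- mk(90000 + seq_len(16) * 100, "F2_03")
  rep_snv <- merge_caller_sets(rbind(shared, only_a), rbind(shared, only_b),
                               names_ab = c("UG", "HC"))
  expect_equal(unname(rep_snv$counts["snv", ]),
               c(213, 11, 16, 240))
  expect_equal(round(100 * rep_snv$consistency[["snv"]], 1), 88.8)
  sh_i <- mk(seq_len(32) * 100, "F2_01", type = "indel")
  a_i <- mk(50000 + seq_len(11) * 100, "F2_02", type = "indel")
  b_i <- mk(90000 + seq_len(3) * 100, "F2_03", type = "indel")
  rep_ind <- merge_caller_sets(rbind(sh_i, a_i), rbind(sh_i, b_i))
  expect_equal(unname(rep_ind$counts["indel", "union"]), 46)
  expect_equal(round(100 * rep_ind$consistency[["indel"]], 1), 69.6)
  # identical sets
  same <- merge_caller_sets(shared, shared)
  expect_equal(unname(same$counts["snv", c("n_only_a", "n_only_b")]), c(0, 0))
  # equivalent indel representations are normalised before comparison
  left <- data.frame(chrom = "c", pos = 10, ref = "AT", alt = "A",
                     sample = "s", type = "indel")
  right <- data.frame(chrom = "c", pos = 10, ref = "ATT", alt = "AT",
                      sample = "s", type = "indel")
  expect_equal(unname(merge_caller_sets(left, right)$counts["indel", "n_both"]),
               1)
  # conflicting alleles at one locus+sample are flagged, not merged
  confl <- merge_caller_sets(
    mk(10, "F2_01"),
    data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "G",
               sample = "F2_01", type = "snv"))
  expect_equal(length(confl$conflicts), 1)
  expect_equal(nrow(confl$union), 0)
})

test_that("shared-mutation scan respects the 2-5 carrier range", {
  grp <- make_group(7)
  samples <- group_samples(grp)
  het <- function() list(ad = c(10, 10), reads = list(A = c(5, 5), T = c(4, 4)))
  carriers3 <- setNames(rep(list(het()), 3), sprintf("F2_%02d", 1:3))
  carriers6 <- setNames(rep(list(het()), 6), sprintf("F2_%02d", 1:6))
  sites <- list(
    std_site(pos = 100, samples = samples, override = carriers3),
    std_site(pos = 200, samples = samples, override = carriers6))
  fx <- build_fixture(sites, samples)
  scf <- filter_confident_sites(fx$sc, grp)
  sh <- scan_shared_mutations(scf, fx$counts, grp)
  expect_equal(sh$pos, 100)
  expect_equal(sh$n_carriers, 3)
  # simulator round-trip: an injected shared mutation is recovered
  sim <- sim20kb(seed = 71, rate = 0, n_shared = 1, error_rate = 0)
  scf2 <- filter_confident_sites(sim_site_calls(sim, 1), sim$group)
  got <- scan_shared_mutations(scf2, sim$counts, sim$group)
  expect_true(sim$truth$shared_mutations$pos %in% got$pos)
})

test_that("detection equals a literal brute-force scan on small groups", {
  for (seed in 1:5) {
    sim <- sim20kb(seed = 100 + seed, rate = 3e-5, n_f2 = 5,
                   marker_density = 0.004)
    scf <- filter_confident_sites(sim_site_calls(sim, 1), sim$group)
    det <- detect_mutations(list(A = scf), sim$counts, sim$group)
    got <- det$candidates$A
    got <- got[got$status == "PASS", ]
    got_keys <- sort(paste(got$chrom, got$pos, got$sample, got$allele,
                           sep = ":"))
    want_keys <- sort(oracle_detect(scf, sim$counts, sim$group))
    expect_equal(got_keys, want_keys)
  }
})
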