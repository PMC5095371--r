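test_that("substitutions collapse onto the six strand-symmetric classes", {
  expect_equal(as.character(classify_substitution("G", "A")$class), "G:C>A:T")
  expect_true(classify_substitution("G", "A")$transition)
  expect_equal(as.character(classify_substitution("T", "A")$class), "A:T>T:A")
  expect_false(classify_substitution("T", "A")$transition)
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("N", "A"), "single")
  # strand-collapse symmetry: a change and its reverse complement agree
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(1)
  for (i in 1:50) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- classify_substitution(ref, alt)
    b <- classify_substitution(comp[[ref]], comp[[alt]])
    expect_equal(a$class, b$class)
    expect_equal(a$transition, b$transition)
  }
})

test_that("the published spectra are reproduced from the class counts", {
  sp <- peach_spectrum_counts()
  intra <- spectrum_table(setNames(sp$intraspecific, sp$class))
  inter <- spectrum_table(setNames(sp$interspecific, sp$class))
  expect_equal(sum(intra$fractions), 1)
  expect_equal(sum(inter$fractions), 1)
  expect_equal(intra$total, 96)
  expect_equal(inter$total, 144)
  expect_equal(inter$ti_events, 102)
  expect_equal(round(inter$ti_events / inter$total, 3), 0.708)
  expect_equal(round(intra$fractions[["G:C>A:T"]], 3), 0.552)
  # Ti/Tv rate ratio: combined 4.76, intraspecific 4.62
  comb <- spectrum_table(setNames(sp$intraspecific + sp$interspecific,
                                  sp$class))
  expect_equal(round(titv_rate_ratio(comb), 2), 4.76)
  expect_equal(round(titv_rate_ratio(intra), 2), 4.62)
  eq <- spectrum_table(c("A:T>G:C" = 10, "G:C>A:T" = 0, "A:T>T:A" = 5,
                         "A:T>C:G" = 5, "G:C>T:A" = 0, "G:C>C:G" = 0))
  expect_equal(titv_rate_ratio(eq), 2)     # equal Ti and Tv events
})

test_that("composition-corrected AT bias matches the published folds", {
  sp <- peach_spectrum_counts()
  intra <- spectrum_table(setNames(sp$intraspecific, sp$class))
  inter <- spectrum_table(setNames(sp$interspecific, sp$class))
  expect_equal(round(at_bias_fold(intra, 0.375), 2), 6.31)
  expect_equal(round(at_bias_fold(inter, 0.375), 2), 8.96)
  bal <- spectrum_table(c("A:T>G:C" = 7, "G:C>A:T" = 7))
  expect_equal(at_bias_fold(bal, 0.5), 1)
  none <- spectrum_table(c("G:C>A:T" = 7))
  expect_warning(f <- at_bias_fold(none, 0.375), "infinite")
  expect_equal(f, Inf)
})

test_that("a simulated mutation list reproduces its own spectrum table", {
  set.seed(33)
  classes <- sample(c("A>G", "C>T", "G>T", "T>A"), 200, replace = TRUE,
                    prob = c(0.3, 0.4, 0.2, 0.1))
  ref <- substr(classes, 1, 1); alt <- substr(classes, 3, 3)
  sp <- spectrum_table(data.frame(ref = ref, alt = alt))
  expect_equal(sp$total, 200)
  expect_equal(unname(sp$counts["G:C>A:T"]), sum(classes == "C>T"))
  expect_equal(unname(sp$counts["A:T>G:C"]), sum(classes == "A>G"))
})

test_that("the Yates statistic reproduces the published tests and clamps at zero", {
  t1 <- yates_chisq(c(7, 1), 8 * c(3, 1) / 4)
  expect_equal(round(t1$statistic, 3), 0.167)
  t2 <- yates_chisq(c(14, 4), 18 * c(3, 1) / 4)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p.value, 1)
  t3 <- yates_chisq(c(121, 133), c(131.7, 122.3))
  expect_equal(round(t3$statistic, 2), 1.64)
  expect_equal(round(t3$p.value, 2), 0.20)
  expect_equal(yates_chisq(c(10, 10), c(10, 10))$statistic, 0)
  expect_error(yates_chisq(c(1, 2), c(0, 3)), "positive")
  # agrees with the textbook formula whenever the clamp is inactive
  set.seed(5)
  for (i in 1:200) {
    o <- rpois(2, 20) + 1
    e <- sum(o) * c(0.4, 0.6)
    if (any(abs(o - e) < 0.5)) next
    textbook <- sum((abs(o - e) - 0.5)^2 / e)
    expect_equal(yates_chisq(o, e)$statistic, textbook, tolerance = 1e-6)
  }
})

test_that("selection tests reproduce the published coding statistics", {
  sel <- peach_selection_counts()
  fs <- matrix(c(1, 5, 5, 35), nrow = 2, byrow = TRUE,
               dimnames = list(c("coding", "noncoding"),
                               c("mult3", "not_mult3")))
  rep_intra <- selection_report(n_coding = 9, n_noncoding = 105,
                                coding_fraction = 0.13,
                                n_nonsyn = 7, n_syn = 1,
                                frameshift_table = fs)
  expect_equal(round(rep_intra$nonsyn$test$statistic, 3), 0.167)
  expect_equal(round(rep_intra$frameshift$p.value, 2), 0.59)
  rep_inter <- selection_report(n_coding = 23, n_noncoding = 149,
                                coding_fraction = 0.13,
                                n_nonsyn = 14, n_syn = 4)
  expect_equal(rep_inter$nonsyn$test$statistic, 0)
  expect_equal(rep_inter$nonsyn$test$p.value, 1)
  # combined frameshift cells come straight from the bundled table
  intra_fs <- sel[sel$item %in% c("frame_shift", "non_frame_shift"), ]
  expect_equal(sum(intra_fs$intra_indel, intra_fs$inter_indel, na.rm = TRUE),
               6)
})

test_that("coding-effect classification follows the genetic code on a crafted genome", {
  seq <- paste0(
    strrep("T", 30),
    "ATGGCTGGAGAATAG",          # M A G E * at 31..45, frame 0
    strrep("T", 55))
  g <- structure(list(
    chrom = data.frame(name = "chr1", length = nchar(seq)),
    seq = Biostrings::DNAStringSet(c(chr1 = seq)),
    coding = data.frame(chrom = "chr1", start = 31, end = 45, strand = "+",
                        frame = 0L),
    gc_fraction = 0.375), class = "genome_model")
  muts <- data.frame(
    chrom = "chr1",
    pos = c(39, 38, 10, 50),
    ref = c("A", "G", "T", "T"),
    alt = c("G", "C", "TAA", "A"),   # GGA>GGG syn; GGA>GCA nonsyn; 2bp ins; snv
    stringsAsFactors = FALSE)
  rep <- selection_tests(muts, g)
  expect_equal(unname(rep$nonsyn$observed), c(1, 1))
  expect_equal(unname(rep$coding$observed), c(2, 2))
  expect_equal(unname(rep$frameshift$table["noncoding", "not_mult3"]), 1)
})

test_that("triplet analysis conserves counts and flags CpG context", {
  g <- make_genome(c(chr1 = 5e4), gc_fraction = 0.5, seed = 21)
  set.seed(22)
  pos <- sample(3:(5e4 - 2), 300)
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(g$seq[[1]], p, p)), character(1))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  muts <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  half <- data.frame(chrom = "chr1", start = c(1, 25001),
                     end = c(25000, 50000))
  tr <- triplet_analysis(muts, g, compartments = list(
    left = half[1, ], right = half[2, ]))
  expect_equal(tr$n_mutations, 300)
  # expected counts over a partition conserve the observed total
  expect_lt(abs(sum(tr$expected) - 300) / 300, 0.02)
  # every mutation at a CpG cytosine/guanine is counted as CpG context
  cen <- pedimut:::mutation_triplets(g, muts$chrom, muts$pos)[, "centre"]
  manual <- sum((ref == "C" & substr(cen, 3, 3) == "G") |
                  (ref == "G" & substr(cen, 1, 1) == "C"))
  expect_equal(tr$cpg$count, manual)
  # contig-edge mutations lacking context are excluded, not dropped silently
  edge <- rbind(muts, data.frame(chrom = "chr1", pos = 1, ref = "A",
                                 alt = "C"))
  tr2 <- triplet_analysis(edge, g)
  expect_equal(tr2$n_excluded, 1)
})
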