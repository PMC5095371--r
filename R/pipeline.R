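#' Run the full analysis pipeline on a (simulated) pedigree group
#'
#' Orchestrates simulate -> write files -> re-read -> confident-site filter
#' and markers -> candidate detection (two emulated callers, union) ->
#' group summary, callable-fraction injection and rate estimation ->
#' spectrum and selection statistics -> compartments and the
#' heterozygosity-distance profile.  All randomness derives from
#' `config$seed`, so a rerun reproduces the report exactly.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `seed` (integer); `genome` (args to [make_genome()]: `chrom_lengths`,
#'   `gc_fraction`, `coding_fraction`); `sim` (args to [sim_config()]);
#'   `n_inject` (callable-injection count, default 500); `dir` (output
#'   directory, default a tempdir).
#' @return a `pedimut_report` with every stage result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dir <- config$dir %||% file.path(tempdir(), paste0("pedimut_run_", seed))
  gargs <- config$genome %||% list(chrom_lengths = c(chr1 = 1e6))
  gargs$chrom_lengths <- unlist(gargs$chrom_lengths)
  gargs$seed <- seed
  sargs <- config$sim %||% list()
  sargs$seed <- seed
  stage <- function(name, expr) {
    message("[pedimut] stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  genome <- stage("genome", do.call(make_genome, gargs))
  sim <- stage("simulate", simulate_group(genome, do.call(sim_config, sargs)))
  paths <- stage("write", write_group(sim, dir))
  group <- read_group(paths["group"])
  counts <- stage("read", read_counts_table(paths["counts"]))
  sv_mask <- read_sv_mask(paths["bed"])
  caller_names <- names(sim$config$caller_profiles)
  calls <- stage("markers", lapply(caller_names, function(cn) {
    filter_confident_sites(
      read_site_calls(paths[paste0("vcf_", cn)], group_samples(group)), group)
  }))
  names(calls) <- caller_names
  markers <- build_marker_set(calls[[1]], group$f1, sv_mask,
                              origins = sim$truth$markers)
  det <- stage("detect", detect_mutations(calls, counts, group,
                                          sv_mask = sv_mask))
  summary <- stage("summarize", summarize_group(det$mutations, group))
  callable <- stage("callable", estimate_callable_fraction(
    sim, n_injected = config$n_inject %||% 500, sv_mask = sv_mask,
    seed = seed + 1))
  L <- genome_length(genome)
  rates <- list(snv = estimate_rate(summary, callable, L, type = "snv"),
                indel = estimate_rate(summary, callable, L, type = "indel"))
  spec <- stage("spectrum", spectrum_table(det$mutations))
  selection <- NULL
  if (nrow(genome$coding) && nrow(det$mutations))
    selection <- stage("selection", selection_tests(det$mutations, genome))
  cmap <- stage("compartments", assign_compartments(
    markers, genotype_classes(calls[[1]])[
      match(paste(markers$chrom, markers$pos),
            paste(calls[[1]]$info$chrom, calls[[1]]$info$pos)),
      group$f2, drop = FALSE],
    stats::setNames(genome$chrom$length, genome$chrom$name)))
  comp <- if (nrow(det$mutations))
    compartment_counts(det$mutations, cmap) else NULL
  het_avg <- nrow(markers) / L
  prof <- stage("hetscan", window_het_profile(
    det$mutations[det$mutations$type == "snv", , drop = FALSE],
    markers, stats::setNames(genome$chrom$length, genome$chrom$name),
    genome_average = het_avg))
  shared <- stage("shared_scan", scan_shared_mutations(calls[[1]], counts,
                                                       group))
  structure(list(config = config, group = group, paths = paths, sim = sim,
                 markers = markers, detection = det, summary = summary,
                 callable = callable, rates = rates, spectrum = spec,
                 selection = selection, compartments = cmap,
                 compartment_counts = comp, window_profile = prof,
                 shared_mutations = shared),
            class = "pedimut_report")
}

#' @export
print.pedimut_report <- function(x, ...) {
  cat("== pedimut report: group", x$group$id, "==\n")
  cat(nrow(x$markers), "confident markers\n")
  print(x$summary)
  print(x$callable)
  print(x$rates$snv); print(x$rates$indel)
  cat("spectrum:\n"); print(x$spectrum)
  if (!is.null(x$selection)) print(x$selection)
  if (!is.null(x$compartment_counts) && !is.null(x$compartment_counts$test))
    cat(sprintf("het/hom compartments: obs %d/%d, chi2 = %.2f (p = %.2f)\n",
                x$compartment_counts$observed["het"],
                x$compartment_counts$observed["hom"],
                x$compartment_counts$test$statistic,
                x$compartment_counts$test$p.value))
  cat("shared (2-5 F2) point mutations:", nrow(x$shared_mutations), "\n")
  invisible(x)
}
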