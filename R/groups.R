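#' Define a pedigree group (one F1 parent and its selfed F2 progeny)
#'
#' @param id group identifier, e.g. `"I"`.
#' @param cross_type `"intraspecific"` or `"interspecific"`.
#' @param f1 F1 sample name.
#' @param f2 character vector of F2 sample names (non-empty).
#' @param grandparents optional named character vector of grandparental sample
#'   names (enables parental haplotype-of-origin tags on markers).
#' @param genome_length reference genome length in bp (optional; taken from
#'   the genome model when simulating).
#' @param gc_fraction genome G:C fraction, default 0.375.
#' @param coverage optional callable-coverage fraction for rate work.
#' @export
pedigree_group <- function(id, cross_type = c("intraspecific", "interspecific"),
                           f1, f2, grandparents = NULL,
                           genome_length = NA_real_, gc_fraction = 0.375,
                           coverage = NA_real_) {
  cross_type <- match.arg(cross_type)
  f2 <- as.character(f2)
  if (!length(f2)) stop("a pedigree group needs at least one F2 sample")
  samples <- c(f1, f2, grandparents)
  if (anyDuplicated(samples)) stop("sample names must be unique")
  structure(list(id = id, cross_type = cross_type, f1 = f1, f2 = f2,
                 grandparents = grandparents, genome_length = genome_length,
                 gc_fraction = gc_fraction, coverage = coverage),
            class = "pedigree_group")
}

#' @export
print.pedigree_group <- function(x, ...) {
  cat("Pedigree group", x$id, sprintf("(%s):", x$cross_type),
      "F1 =", x$f1, "+", length(x$f2), "selfed F2s\n")
  invisible(x)
}

group_samples <- function(group) c(group$f1, group$f2)

#' Read / write a group configuration as YAML
#' @rdname pedigree_group
#' @param path file path.
#' @export
read_group <- function(path) {
  y <- yaml::read_yaml(path)
  pedigree_group(id = y$id, cross_type = y$cross_type, f1 = y$f1,
                 f2 = y$f2, grandparents = y$grandparents,
                 genome_length = y$genome_length %||% NA_real_,
                 gc_fraction = y$gc_fraction %||% 0.375,
                 coverage = y$coverage %||% NA_real_)
}

#' @rdname pedigree_group
#' @param group a `pedigree_group`.
#' @export
write_group_yaml <- function(group, path) {
  yaml::write_yaml(unclass(group), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
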