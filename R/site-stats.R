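#' Per-sequence GC content
#'
#' GC content is computed per ungapped sequence as `100 * (G + C) / (A + C +
#' G + T)`; gaps and ambiguity codes are excluded from both numerator and
#' denominator.
#'
#' @param residues Character vector of (aligned or unaligned) sequences.
#' @return Numeric vector of GC percentages.
#' @examples
#' gc_content(c("ATGC", "GGCC", "AT-N-GC"))
#' @export
gc_content <- function(residues) {
  residues <- toupper(residues)
  counts <- function(seq, chars) {
    s <- strsplit(seq, "", fixed = TRUE)[[1]]
    sum(s %in% chars)
  }
  gc <- vapply(residues, counts, numeric(1), chars = c("G", "C"))
  acgt <- vapply(residues, counts, numeric(1), chars = .BASES)
  if (any(acgt == 0)) {
    abort("GC content undefined: sequence(s) with no unambiguous bases")
  }
  unname(100 * gc / acgt)
}

#' Classify alignment columns
#'
#' Assigns every alignment column one of four labels and tallies them:
#'
#' * `all_missing` -- no unambiguous base in the column;
#' * `gap_containing` -- at least one gap or ambiguity code (these columns
#'   are excluded from the conserved/variable classification);
#' * `conserved` -- all residues are unambiguous bases and identical;
#' * `variable` -- all residues are unambiguous bases with >= 2 distinct
#'   states.
#'
#' A variable column is additionally *parsimony-informative* when at least
#' two states are each present in at least two sequences.  The aberration
#' rate is `100 * variable / alignment_length`: gap-containing columns count
#' in the denominator but can never be classified variable, which is the
#' convention under which conserved + variable sums to the number of
#' gap-free columns.
#'
#' @param aln A [marker_alignment()].
#' @return An object of class `site_classification`: a list with `counts`
#'   (one-row tibble of the tallies and aberration rate) and `columns`
#'   (per-column tibble with `column`, `class`, `informative`).
#' @examples
#' aln <- marker_alignment(c("s1", "s2", "s3"), c("A", "A", "B"),
#'                         c("AAA", "AAA", "AAT"), "demo")
#' classify_sites(aln)$counts
#' @export
classify_sites <- function(aln) {
  m <- aln_matrix(aln)
  if (ncol(m) == 0) {
    abort("alignment has zero columns")
  }
  n <- nrow(m)
  base_counts <- vapply(.BASES, function(b) colSums(m == b),
                        numeric(ncol(m)))
  if (ncol(m) == 1) base_counts <- matrix(base_counts, nrow = 1)
  n_unamb <- rowSums(base_counts)
  n_states <- rowSums(base_counts > 0)
  n_shared_states <- rowSums(base_counts >= 2)

  pure <- n_unamb == n
  all_missing <- n_unamb == 0
  gap_containing <- !pure & !all_missing
  conserved <- pure & n_states == 1
  variable <- pure & n_states >= 2
  informative <- variable & n_shared_states >= 2

  cls <- rep("all_missing", ncol(m))
  cls[gap_containing] <- "gap_containing"
  cls[conserved] <- "conserved"
  cls[variable] <- "variable"

  counts <- tibble(
    alignment_length = ncol(m),
    conserved_sites = sum(conserved),
    variable_sites = sum(variable),
    informative_sites = sum(informative),
    gap_containing_sites = sum(gap_containing),
    all_missing_sites = sum(all_missing),
    aberration_rate_percent = 100 * sum(variable) / ncol(m)
  )
  structure(
    list(
      counts = counts,
      columns = tibble(column = seq_len(ncol(m)), class = cls,
                       informative = informative)
    ),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.site_classification <- function(x, ...) {
  x$columns
}

#' @export
glance.site_classification <- function(x, ...) {
  x$counts
}

#' Mean pairwise sequence similarity
#'
#' Average over sample pairs of `100 * identical comparable columns /
#' comparable columns`, where a column is comparable for a pair when both
#' residues are unambiguous bases (pairwise deletion of gaps and ambiguity
#' codes).  The scope restricts which pairs enter the average.
#'
#' @param aln A [marker_alignment()].
#' @param scope `"all"` (default), `"interspecific"` (heterospecific pairs
#'   only) or `"intraspecific"` (conspecific pairs only).
#' @return Mean similarity in percent.  Pairs with no comparable columns are
#'   skipped with a warning.
#' @export
mean_pairwise_similarity <- function(aln,
                                     scope = c("all", "interspecific",
                                               "intraspecific")) {
  scope <- match.arg(scope)
  m <- aln_matrix(aln)
  ok <- matrix(m %in% .BASES, nrow = nrow(m))
  pairs <- combn(nrow(m), 2)
  same_species <- aln$species[pairs[1, ]] == aln$species[pairs[2, ]]
  keep <- switch(scope,
    all = rep(TRUE, ncol(pairs)),
    interspecific = !same_species,
    intraspecific = same_species
  )
  if (!any(keep)) {
    abort(paste0("no ", scope, " sample pairs in the alignment"))
  }
  pairs <- pairs[, keep, drop = FALSE]
  sims <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp)) return(NA_real_)
    100 * sum(m[i, comp] == m[j, comp]) / sum(comp)
  }, numeric(1))
  if (anyNA(sims)) {
    warn(paste0(sum(is.na(sims)),
                " pair(s) with no comparable columns skipped"))
    sims <- sims[!is.na(sims)]
  }
  if (length(sims) == 0) {
    abort("similarity undefined: every pair lacked comparable columns")
  }
  mean(sims)
}

#' Per-marker sequence characteristics
#'
#' One-row summary of a marker alignment in the format barcode surveys
#' report: ungapped sequence-length range, per-sequence GC range, site
#' classification tallies, aberration rate and mean pairwise similarity.
#'
#' @param aln A [marker_alignment()].
#' @return A one-row tibble of class `sequence_characteristics`.
#' @export
sequence_characteristics <- function(aln) {
  ungapped <- nchar(gsub("-", "", aln$residues, fixed = TRUE))
  gc <- gc_content(aln$residues)
  cls <- classify_sites(aln)$counts
  out <- dplyr::bind_cols(
    tibble(
      marker = aln$marker[1],
      n_samples = nrow(aln),
      n_species = length(unique(aln$species)),
      length_min = min(ungapped),
      length_max = max(ungapped),
      gc_min = min(gc),
      gc_max = max(gc)
    ),
    cls,
    tibble(mean_similarity_percent = mean_pairwise_similarity(aln))
  )
  class(out) <- c("sequence_characteristics", class(out))
  out
}
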