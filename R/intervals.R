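#' Which query intervals overlap a subject set
#'
#' Overlap rule is >= 1 bp everywhere in the package. Backed by the IRanges
#' interval tree; results are identical to a linear scan.
#'
#' @param query,subject interval data frames (0-based half-open).
#' @return logical vector, one per query row.
#' @export
overlaps_any <- function(query, subject) {
  check_regions(query, "query")
  overlaps_any_region(query, subject)
}

#' Mutual overlap counts between two region sets
#'
#' Counts how many members of A overlap at least one member of B, and vice
#' versa (each member counted once however many partners it has) — the
#' quantities behind a Venn-style comparison of two DMR sets.
#'
#' @param a,b interval data frames.
#' @return named integer vector `c(a_in_b = ..., b_in_a = ...)`.
#' @export
overlap_count <- function(a, b) {
  c(a_in_b = sum(overlaps_any_region(a, b)),
    b_in_a = sum(overlaps_any_region(b, a)))
}

#' ChIP-peak / DMR overlap analysis
#'
#' DMRs are expanded by `flank` bp (methylation deposits flank the binding
#' site), then the fraction of peaks overlapping any expanded DMR is
#' compared to the fraction overlapping equally expanded matched background
#' windows, with a Fisher exact test on the peak counts.
#'
#' @param dmrs DMR interval data frame.
#' @param peaks peak interval data frame.
#' @param chrom_lengths named chromosome lengths (for flank clipping and
#'   background placement).
#' @param flank bp added to each DMR side before overlap.
#' @param background optional pre-drawn background matched to `dmrs`;
#'   drawn via [sample_background()] when `NULL`.
#' @param seed RNG seed for background sampling.
#' @return list with `fraction` (peaks overlapping expanded DMRs),
#'   `background_fraction`, `p`, and counts.
#' @export
peak_overlap_analysis <- function(dmrs, peaks, chrom_lengths, flank = 100,
                                  background = NULL, seed = NULL) {
  check_regions(dmrs, "dmrs"); check_regions(peaks, "peaks")
  if (is.null(background))
    background <- sample_background(dmrs, chrom_lengths, seed = seed)
  exp_dmrs <- expand_flanks(dmrs, flank, chrom_lengths)
  exp_bg <- expand_flanks(background, flank, chrom_lengths)
  a <- sum(overlaps_any_region(peaks, exp_dmrs))
  c_ <- sum(overlaps_any_region(peaks, exp_bg))
  n <- nrow(peaks)
  list(fraction = if (n) a / n else 0,
       background_fraction = if (n) c_ / n else 0,
       p = if (n) stats::fisher.test(matrix(c(a, n - a, c_, n - c_), 2))$p.value
         else 1,
       peaks_in = a, peaks_in_background = c_, n_peaks = n)
}
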