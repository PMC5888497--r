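# internal helpers shared across modules

# Evaluate expr with a temporarily seeded RNG; restores the caller's RNG
# state so seeded helpers never perturb an enclosing simulation.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate a 0-based half-open interval data frame (chrom/start/end).
check_regions <- function(regions, what = "regions") {
  if (!is.data.frame(regions) ||
      !all(c("chrom", "start", "end") %in% names(regions)))
    stop(what, " must be a data frame with chrom/start/end columns")
  if (nrow(regions) && any(regions$start < 0))
    stop(what, ": negative start coordinate")
  if (nrow(regions) && any(regions$end <= regions$start))
    stop(what, ": end must be greater than start (0-based half-open)")
  invisible(regions)
}

# 0-based half-open data.frame -> named list of IRanges (1-based closed).
ranges_by_chrom <- function(regions) {
  sp <- split(regions, regions$chrom)
  lapply(sp, function(d) IRanges::IRanges(start = d$start + 1L, end = d$end))
}

# logical per query row: overlaps >= 1 bp with any subject interval
overlaps_any_region <- function(query, subject) {
  out <- logical(nrow(query))
  if (!nrow(query) || !is.data.frame(subject) || !nrow(subject)) return(out)
  subj <- ranges_by_chrom(subject)
  for (ch in unique(query$chrom)) {
    sel <- query$chrom == ch
    if (is.null(subj[[ch]])) next
    q <- IRanges::IRanges(start = query$start[sel] + 1L, end = query$end[sel])
    out[sel] <- IRanges::overlapsAny(q, subj[[ch]])
  }
  out
}

# Sum m and n over sites within +/- window/2 bp of each position.
# pos must be sorted, strictly increasing, integer.
window_sums <- function(pos, m, n, window) {
  half <- window / 2
  cm <- c(0, cumsum(as.numeric(m)))
  cn <- c(0, cumsum(as.numeric(n)))
  lo <- findInterval(pos - half - 0.5, pos)      # sites strictly below window
  hi <- findInterval(pos + half + 0.5, pos)      # sites inside or below window
  list(m = cm[hi + 1L] - cm[lo + 1L], n = cn[hi + 1L] - cn[lo + 1L])
}

clamp01 <- function(x) pmin(1, pmax(0, x))

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
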