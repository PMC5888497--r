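#' Matched random background windows
#'
#' Draws the same number of windows as the input region set, with lengths
#' resampled (with replacement) from the input length multiset and placement
#' uniform over the genome (chromosome chosen proportional to length among
#' chromosomes that can hold the window). This is the null set for all
#' "falls into" enrichment tests.
#'
#' @param regions interval data frame (0-based half-open).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n number of windows (default: same as input).
#' @param seed RNG seed; identical seeds give identical windows.
#' @return data frame `chrom, start, end`.
#' @export
sample_background <- function(regions, chrom_lengths, n = NULL, seed = NULL) {
  check_regions(regions)
  if (!nrow(regions)) stop("regions must be nonempty")
  if (is.null(n)) n <- nrow(regions)
  lens <- regions$end - regions$start
  if (min(chrom_lengths) < min(lens) && max(lens) > max(chrom_lengths))
    stop("a region is longer than every chromosome")
  with_seed(seed, {
    w <- sample(lens, n, replace = TRUE)
    chrom <- character(n)
    start <- integer(n)
    for (i in seq_len(n)) {
      ok <- chrom_lengths >= w[i]
      if (!any(ok)) stop("region length ", w[i],
                         " exceeds every chromosome length")
      ch <- sample(names(chrom_lengths)[ok], 1,
                   prob = chrom_lengths[ok])
      chrom[i] <- ch
      start[i] <- sample.int(chrom_lengths[ch] - w[i] + 1L, 1) - 1L
    }
    data.frame(chrom = chrom, start = start, end = start + w)
  })
}

odds_ratio_2x2 <- function(a, b, c, d) {
  if (b * c == 0) return(if (a * d == 0) NA_real_ else Inf)
  (a * d) / (b * c)
}

#' Feature-class enrichment of a region set vs matched background
#'
#' A region "falls into" a feature class when it overlaps any class interval
#' by at least 1 bp; a region may count in several classes. Per class, the
#' 2x2 table (in/out x region/background) is tested with the two-sided
#' Fisher exact test; the odds ratio is the sample cross-product
#' `(a*d)/(b*c)`. An empty feature class is reported with `p = 1`.
#'
#' @param regions region set (e.g. DMRs or ChIP peaks).
#' @param background matched windows from [sample_background()].
#' @param features named list of feature interval data frames.
#' @return data frame of class `enrichment_result`: per class the counts,
#'   fractions, odds ratio and exact-test p.
#' @export
feature_enrichment <- function(regions, background, features) {
  check_regions(regions); check_regions(background, "background")
  out <- lapply(names(features), function(cl) {
    f <- features[[cl]]
    if (is.null(f) || !nrow(f)) {
      warning("empty feature class '", cl, "'; reported with p = 1")
      return(data.frame(class = cl, regions_in = 0L,
                        regions_total = nrow(regions), background_in = 0L,
                        background_total = nrow(background),
                        odds_ratio = NA_real_, p = 1))
    }
    a <- sum(overlaps_any_region(regions, f))
    c_ <- sum(overlaps_any_region(background, f))
    b <- nrow(regions) - a
    d <- nrow(background) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    data.frame(class = cl, regions_in = a, regions_total = nrow(regions),
               background_in = c_, background_total = nrow(background),
               odds_ratio = odds_ratio_2x2(a, b, c_, d), p = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Fraction of regions falling into DHS core intervals
#'
#' The core is the DHS interval itself (flanks excluded); overlap rule is
#' >= 1 bp. Compared against the matched background with the Fisher exact
#' test.
#'
#' @param regions region set.
#' @param dhs DHS interval data frame.
#' @param background matched windows.
#' @return list with `fraction`, `background_fraction`, `p`, and counts.
#' @export
dhs_core_fraction <- function(regions, dhs, background) {
  check_regions(regions); check_regions(background, "background")
  a <- sum(overlaps_any_region(regions, dhs))
  c_ <- sum(overlaps_any_region(background, dhs))
  b <- nrow(regions) - a
  d <- nrow(background) - c_
  list(fraction = a / nrow(regions),
       background_fraction = c_ / nrow(background),
       p = stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
       regions_in = a, regions_total = nrow(regions),
       background_in = c_, background_total = nrow(background))
}

#' Methylation metaplot over DHS with scaled bodies and fixed flanks
#'
#' Each DHS body is length-scaled into `body_bins` bins; the 1 kb flanks on
#' each side are split into `flank_bins` fixed-width bins. Bin values are
#' the unweighted mean of passing per-site methylation fractions (counts
#' pooled within each sample group). Each non-control group is compared to
#' the control by a Wilcoxon matched-pairs signed-rank test over per-DHS
#' mean body methylation (same DHS paired across groups; DHS with no
#' passing site in either member of a pair are dropped).
#'
#' @param x a [methylome].
#' @param groups named list of sample-name vectors (one entry per group).
#' @param dhs DHS interval data frame.
#' @param control name of the control group in `groups`.
#' @param flank flank width in bp (1 kb each side).
#' @param body_bins,flank_bins bin counts.
#' @param min_depth depth filter.
#' @return object of class `dhs_metaplot`: list with `profile` (data frame
#'   `group, bin, zone, mean_methylation`) and `tests` (per treated group:
#'   `n_pairs, statistic, p`).
#' @export
dhs_metaplot <- function(x, groups, dhs, control, flank = 1000,
                         body_bins = 20, flank_bins = 10, min_depth = 4) {
  stopifnot(inherits(x, "methylome"))
  check_regions(dhs, "dhs")
  if (!control %in% names(groups)) stop("control group not in groups")
  nbin <- 2 * flank_bins + body_bins

  # per-group pooled per-site levels
  lv <- sapply(groups, function(s) {
    s <- resolve_samples(x, s)
    M <- x$M[, s, drop = FALSE]; N <- x$N[, s, drop = FALSE]
    pass <- N >= min_depth
    m <- rowSums(M * pass); n <- rowSums(N * pass)
    ifelse(n > 0, m / n, NA_real_)
  })

  bin_sum <- matrix(0, nbin, length(groups),
                    dimnames = list(NULL, names(groups)))
  bin_n <- bin_sum
  dhs_mean <- array(NA_real_, c(nrow(dhs), length(groups)),
                    dimnames = list(NULL, names(groups)))
  for (i in seq_len(nrow(dhs))) {
    ch <- dhs$chrom[i]; s0 <- dhs$start[i]; e0 <- dhs$end[i]
    sel <- which(x$sites$chrom == ch & x$sites$pos >= s0 - flank &
                   x$sites$pos < e0 + flank)
    if (!length(sel)) next
    pos <- x$sites$pos[sel]
    bin <- integer(length(pos))
    up <- pos < s0; down <- pos >= e0
    body <- !up & !down
    bin[up] <- pmin(flank_bins,
                    1L + as.integer((pos[up] - (s0 - flank)) / (flank / flank_bins)))
    bin[body] <- flank_bins +
      pmin(body_bins, 1L + as.integer((pos[body] - s0) / ((e0 - s0) / body_bins)))
    bin[down] <- flank_bins + body_bins +
      pmin(flank_bins, 1L + as.integer((pos[down] - e0) / (flank / flank_bins)))
    for (g in names(groups)) {
      v <- lv[sel, g]
      ok <- !is.na(v)
      if (any(ok)) {
        bs <- tapply(v[ok], bin[ok], sum)
        bc <- tapply(v[ok], bin[ok], length)
        idx <- as.integer(names(bs))
        bin_sum[idx, g] <- bin_sum[idx, g] + bs
        bin_n[idx, g] <- bin_n[idx, g] + bc
      }
      okb <- ok & body
      if (any(okb)) dhs_mean[i, g] <- mean(v[okb])
    }
  }
  zone <- c(rep("upstream", flank_bins), rep("body", body_bins),
            rep("downstream", flank_bins))
  profile <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, bin = seq_len(nbin), zone = zone,
               mean_methylation = ifelse(bin_n[, g] > 0,
                                         bin_sum[, g] / bin_n[, g], NA_real_))))
  tests <- do.call(rbind, lapply(setdiff(names(groups), control), function(g) {
    ok <- !is.na(dhs_mean[, g]) & !is.na(dhs_mean[, control])
    diffs <- dhs_mean[ok, g] - dhs_mean[ok, control]
    if (!length(diffs) || all(diffs == 0)) {
      data.frame(group = g, n_pairs = sum(ok), statistic = NA_real_, p = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(
        dhs_mean[ok, g], dhs_mean[ok, control], paired = TRUE))
      data.frame(group = g, n_pairs = sum(ok),
                 statistic = unname(wt$statistic), p = wt$p.value)
    }
  }))
  structure(list(profile = profile, tests = tests, control = control,
                 flank = flank, body_bins = body_bins,
                 flank_bins = flank_bins),
            class = "dhs_metaplot")
}

#' @export
print.dhs_metaplot <- function(x, ...) {
  cat("dhs_metaplot:", length(unique(x$profile$group)), "groups, control =",
      x$control, "\n")
  if (!is.null(x$tests) && nrow(x$tests)) print.data.frame(x$tests)
  invisible(x)
}

#' @export
plot.dhs_metaplot <- function(x, ...) {
  groups <- unique(x$profile$group)
  cols <- grDevices::hcl.colors(length(groups), "Dark 3")
  graphics::plot(NA, xlim = c(1, max(x$profile$bin)),
                 ylim = c(0, max(x$profile$mean_methylation, na.rm = TRUE)),
                 xlab = "bin (flank | scaled DHS body | flank)",
                 ylab = "mean methylation", ...)
  for (i in seq_along(groups)) {
    p <- x$profile[x$profile$group == groups[i], ]
    graphics::lines(p$bin, p$mean_methylation, col = cols[i], lwd = 2)
  }
  graphics::abline(v = c(x$flank_bins + 0.5,
                         x$flank_bins + x$body_bins + 0.5), lty = 3)
  graphics::legend("topleft", legend = groups, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

# DNAStringSet of window sequences, in row order of `windows`
extract_windows <- function(genome, windows) {
  check_regions(windows, "windows")
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!windows$chrom %in% names(genome)) ||
      any(windows$end > lens[windows$chrom]) || any(windows$start < 0))
    stop("window outside the genome")
  out <- character(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    out[idx] <- as.character(Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(start = windows$start[idx] + 1L,
                       end = windows$end[idx])))
  }
  Biostrings::DNAStringSet(out)
}

# occurrences of pattern on the forward strand plus occurrences of its
# reverse complement on the forward strand (= both-strand count);
# overlapping occurrences all counted; N in the pattern is a wildcard
count_both_strands <- function(seqs, pattern) {
  Biostrings::vcountPattern(pattern, seqs, fixed = FALSE) +
    Biostrings::vcountPattern(revcomp_chr(pattern), seqs, fixed = FALSE)
}

density_result <- function(windows, counts, pattern) {
  lens <- windows$end - windows$start
  k <- nchar(pattern)
  dens <- counts / (lens / 1000)
  structure(list(
    windows = cbind(windows[, c("chrom", "start", "end")],
                    count = counts, density = dens),
    pattern = pattern,
    median_density = stats::median(dens),
    sd_density = stats::sd(dens),
    total_matches = sum(counts),
    total_positions = sum(2 * pmax(0, lens - k + 1))),
    class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat("density_result (", x$pattern, "): ", nrow(x$windows),
      " windows, median ", signif(x$median_density, 4), " / kb (SD ",
      signif(x$sd_density, 4), ")\n", sep = "")
  invisible(x)
}

#' Seed-PAM motif density in genomic windows
#'
#' Counts occurrences of the guide's PAM-proximal seed followed by NGG
#' (`5'-SEED-NGG-3'`) on either DNA strand of each window, all overlapping
#' occurrences included, and normalizes per kb. The set-level summary is
#' the median density with 1 standard deviation.
#'
#' @param windows window data frame (e.g. DMRs expanded by
#'   [expand_flanks()], or background windows).
#' @param genome a [Biostrings::DNAStringSet].
#' @param guide one-row guide data frame or list with `protospacer`.
#' @param seed_len seed length (5 or 11 nt).
#' @return object of class `density_result` with per-window counts and
#'   densities plus the median/SD summary; compare two sets with
#'   [density_compare()].
#' @export
seed_pam_density <- function(windows, genome, guide, seed_len = 5) {
  pattern <- paste0(guide_seed(guide, seed_len), "NGG")
  counts <- count_both_strands(extract_windows(genome, windows), pattern)
  density_result(windows, counts, pattern)
}

#' PAM (NGG) density in genomic windows
#'
#' As [seed_pam_density()] with the bare NGG motif, the neutral yardstick
#' for seed-specific enrichment.
#'
#' @inheritParams seed_pam_density
#' @return a `density_result`.
#' @export
pam_density <- function(windows, genome) {
  counts <- count_both_strands(extract_windows(genome, windows), "NGG")
  density_result(windows, counts, "NGG")
}

#' Compare motif densities between two window sets
#'
#' Two complementary comparisons are reported: a Fisher exact test on the
#' pooled match counts against the total scanned positions of each set, and
#' a two-sample t-test on the per-window densities. Neither is privileged;
#' report both.
#'
#' @param a,b `density_result` objects for the two sets.
#' @return list with `p_fisher`, `p_t`, and the median densities.
#' @export
density_compare <- function(a, b) {
  stopifnot(inherits(a, "density_result"), inherits(b, "density_result"))
  tab <- matrix(c(a$total_matches, a$total_positions - a$total_matches,
                  b$total_matches, b$total_positions - b$total_matches), 2)
  p_f <- stats::fisher.test(tab)$p.value
  p_t <- tryCatch(stats::t.test(a$windows$density, b$windows$density)$p.value,
                  error = function(e) NA_real_)
  list(p_fisher = p_f, p_t = p_t,
       median_a = a$median_density, median_b = b$median_density)
}

#' Extend regions by flanking sequence
#'
#' Each interval grows by `flank` bp on both sides, clipped to chromosome
#' bounds when lengths are supplied. Resulting overlaps are not merged.
#' Used e.g. to add the 100 bp flanks to DMRs before seed-PAM density
#' scans, since dCas9 methyltransferases methylate CpGs flanking the
#' binding site rather than the site itself.
#'
#' @param regions interval data frame.
#' @param flank bp added to each side.
#' @param chrom_lengths optional named vector for right-clipping.
#' @return data frame with the expanded intervals (other columns kept).
#' @export
expand_flanks <- function(regions, flank = 100, chrom_lengths = NULL) {
  check_regions(regions)
  out <- regions
  out$start <- pmax(0L, regions$start - as.integer(flank))
  out$end <- regions$end + as.integer(flank)
  if (!is.null(chrom_lengths))
    out$end <- pmin(unname(chrom_lengths[out$chrom]), out$end)
  out
}
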