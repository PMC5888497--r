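#' Moving-window smoothed methylation levels
#'
#' Depth-weighted moving average: at each site the smoothed level is
#' `sum(M) / sum(N)` over passing sites within +/- `window/2` bp on the same
#' chromosome (the site itself included). Counts are pooled over the given
#' samples after a per-sample, per-site depth filter. A site whose window
#' contains no passing coverage (itself included) is missing.
#'
#' @param x a [methylome].
#' @param samples samples to pool (default all).
#' @param window smoothing window in bp (100 bp default; 0 reduces to the
#'   raw per-site ratio).
#' @param min_depth per-sample, per-site depth filter.
#' @return data frame `chrom, pos, m, n, m_w, n_w, level` where `m`/`n` are
#'   the site's own pooled passing counts and `m_w`/`n_w` the window sums.
#' @export
smooth_levels <- function(x, samples = NULL, window = 100, min_depth = 4) {
  stopifnot(inherits(x, "methylome"))
  samples <- resolve_samples(x, samples)
  M <- x$M[, samples, drop = FALSE]
  N <- x$N[, samples, drop = FALSE]
  pass <- N >= min_depth
  m <- rowSums(M * pass)
  n <- rowSums(N * pass)
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    m = m, n = n, m_w = NA_real_, n_w = NA_real_)
  for (ch in unique(out$chrom)) {
    sel <- which(out$chrom == ch)
    ws <- window_sums(out$pos[sel], m[sel], n[sel], window)
    out$m_w[sel] <- ws$m
    out$n_w[sel] <- ws$n
  }
  out$level <- ifelse(out$n_w > 0, out$m_w / out$n_w, NA_real_)
  rownames(out) <- NULL
  out
}

#' Method-of-moments beta-binomial dispersion estimate
#'
#' Estimates the overdispersion phi from replicate-to-replicate variation of
#' per-site methylation ratios, using `var(M/N) ~ p(1-p) * (phi + 1/N)`.
#' Sites where every replicate passes the depth filter and `p` is away from
#' the boundaries contribute; the median over sites is returned, clamped to
#' `[1e-4, 0.5]`.
#'
#' @param x a [methylome].
#' @param samples replicate samples of one condition (>= 2).
#' @param min_depth depth filter.
#' @return scalar phi estimate.
#' @export
estimate_dispersion <- function(x, samples, min_depth = 4) {
  samples <- resolve_samples(x, samples)
  if (length(samples) < 2) stop("need >= 2 replicates to estimate dispersion")
  M <- x$M[, samples, drop = FALSE]
  N <- x$N[, samples, drop = FALSE]
  ok <- rowSums(N >= min_depth) == length(samples)
  r <- M[ok, , drop = FALSE] / N[ok, , drop = FALSE]
  p <- rowMeans(r)
  v <- apply(r, 1, stats::var)
  inv_n <- rowMeans(1 / N[ok, , drop = FALSE])
  use <- p > 0.05 & p < 0.95
  if (!any(use)) return(1e-4)
  phi <- stats::median(v[use] / (p[use] * (1 - p[use])) - inv_n[use])
  min(0.5, max(1e-4, phi))
}

#' Per-CpG two-condition Wald test on smoothed levels
#'
#' For each CpG covered in both conditions after smoothing, computes
#' `z = (p1s - p2s) / sqrt(pbar * (1 - pbar) * (1/n1 + 1/n2) + phi0)` with
#' `n1`, `n2` the summed passing depths in the smoothing window, `pbar` the
#' pooled smoothed level with one methylated and one unmethylated
#' pseudo-read, and `phi0` a prior dispersion floor absorbing
#' beta-binomial extra-binomial variance. Two-sided p-values come from the
#' standard normal. This is a fully specified, deliberately simple stand-in
#' for shrinkage-based WGBS testing; p-values are not multiplicity-adjusted
#' (region calling uses the per-CpG `P <= 0.01` convention directly).
#'
#' @param x a [methylome].
#' @param samples_a,samples_b samples of conditions A and B (deltas and DMR
#'   directions are A relative to B).
#' @param window smoothing window in bp.
#' @param min_depth depth filter.
#' @param phi0 prior dispersion floor. `NULL` (default) uses 0.004, or a
#'   method-of-moments estimate when both conditions have >= 2 replicates.
#' @return data frame of class `cpg_test_set`: `chrom, pos, p1s, p2s,
#'   delta, z, p`, sorted by position; sites with no passing coverage in
#'   either condition are skipped (count in attribute `n_skipped`).
#' @export
dmr_test <- function(x, samples_a, samples_b, window = 100, min_depth = 4,
                     phi0 = NULL) {
  sa <- smooth_levels(x, samples_a, window, min_depth)
  sb <- smooth_levels(x, samples_b, window, min_depth)
  if (is.null(phi0)) {
    phi0 <- if (length(resolve_samples(x, samples_a)) >= 2 &&
                length(resolve_samples(x, samples_b)) >= 2)
      mean(c(estimate_dispersion(x, samples_a, min_depth),
             estimate_dispersion(x, samples_b, min_depth)))
    else 0.004
  }
  keep <- sa$n_w > 0 & sb$n_w > 0
  n_skipped <- sum(!keep)
  p1s <- sa$level[keep]; p2s <- sb$level[keep]
  n1 <- sa$n_w[keep]; n2 <- sb$n_w[keep]
  pbar <- (sa$m_w[keep] + sb$m_w[keep] + 1) / (n1 + n2 + 2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2) + phi0)
  delta <- p1s - p2s
  z <- delta / se
  out <- data.frame(chrom = sa$chrom[keep], pos = sa$pos[keep],
                    p1s = p1s, p2s = p2s, delta = delta, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "phi0") <- phi0
  class(out) <- c("cpg_test_set", "data.frame")
  out
}

#' Call differentially methylated regions
#'
#' Seed CpGs are those with `p <= p_max` and `|delta| >= delta_min`. Runs of
#' same-direction seeds with inter-CpG gaps of at most `merge_gap` bp form
#' candidate regions; candidates are kept when they contain at least
#' `min_cpg` seeds, span at least `min_len` bp, and their mean member delta
#' passes `delta_min`. The region interval runs from the first member CpG to
#' the last member CpG + 2 bp, covering the closing CpG dinucleotide (the
#' stated minimum length depends on this boundary convention). Candidate
#' regions are disjoint by construction.
#'
#' @param tests a `cpg_test_set` from [dmr_test()].
#' @param delta_min minimum |methylation difference| (default 0.1).
#' @param p_max per-CpG p-value threshold (default 0.01).
#' @param min_cpg minimum member CpGs (default 3).
#' @param min_len minimum region length in bp (default 10).
#' @param merge_gap maximum gap between consecutive member CpGs (bp).
#' @return data frame of class `dmr_set`: `chrom, start, end, direction,
#'   n_cpg, mean_delta, p_min, area_stat`. Rejected candidates (with the
#'   first failing rule) are in attribute `rejected`.
#' @export
call_dmrs <- function(tests, delta_min = 0.1, p_max = 0.01, min_cpg = 3,
                      min_len = 10, merge_gap = 100) {
  stopifnot(is.data.frame(tests))
  seeds <- tests[!is.na(tests$p) & tests$p <= p_max &
                   abs(tests$delta) >= delta_min, , drop = FALSE]
  out <- list()
  rejected <- list()
  if (nrow(seeds)) {
    seeds <- seeds[order(seeds$chrom, seeds$pos), ]
    dirn <- ifelse(seeds$delta > 0, "hyper", "hypo")
    new_run <- c(TRUE, seeds$chrom[-1] != seeds$chrom[-nrow(seeds)] |
                   diff(seeds$pos) > merge_gap |
                   dirn[-1] != dirn[-nrow(seeds)])
    run_id <- cumsum(new_run)
    for (id in unique(run_id)) {
      mem <- seeds[run_id == id, , drop = FALSE]
      start <- mem$pos[1]
      end <- mem$pos[nrow(mem)] + 2L
      cand <- data.frame(chrom = mem$chrom[1], start = start, end = end,
                         direction = if (mem$delta[1] > 0) "hyper" else "hypo",
                         n_cpg = nrow(mem), mean_delta = mean(mem$delta),
                         p_min = min(mem$p), area_stat = sum(mem$z))
      reason <- if (nrow(mem) < min_cpg) "min_cpg"
        else if (end - start < min_len) "min_len"
        else if (abs(cand$mean_delta) < delta_min) "mean_delta"
        else NA_character_
      if (is.na(reason)) out[[length(out) + 1L]] <- cand
      else rejected[[length(rejected) + 1L]] <- cbind(cand, reason = reason)
    }
  }
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), n_cpg = integer(),
                      mean_delta = numeric(), p_min = numeric(),
                      area_stat = numeric())
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    cbind(empty, reason = character())
  attr(res, "params") <- list(delta_min = delta_min, p_max = p_max,
                              min_cpg = min_cpg, min_len = min_len,
                              merge_gap = merge_gap)
  class(res) <- c("dmr_set", "data.frame")
  res
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("dmr_set:", nrow(x), "regions (",
      sum(x$direction == "hyper"), "hyper /",
      sum(x$direction == "hypo"), "hypo )\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' @export
summary.dmr_set <- function(object, ...) {
  if (!nrow(object)) {
    cat("no DMRs\n")
    return(invisible(object))
  }
  len <- object$end - object$start
  cat("DMRs:", nrow(object), "\n")
  for (d in c("hyper", "hypo")) {
    s <- object[object$direction == d, ]
    if (!nrow(s)) next
    cat(sprintf("  %s: n=%d, mean length %.0f bp, mean CpGs %.1f, mean |delta| %.2f\n",
                d, nrow(s), mean(s$end - s$start), mean(s$n_cpg),
                mean(abs(s$mean_delta))))
  }
  invisible(object)
}
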