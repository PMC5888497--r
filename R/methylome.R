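#' Per-cytosine bisulfite count container
#'
#' A `methylome` holds methylated (`M`) and total (`N`) read counts for a
#' fixed, sorted set of cytosine sites across one or more samples. It is the
#' central matrix every downstream stage (summaries, DMR calling, the
#' monotonicity filter, metaplots) consumes.
#'
#' Coordinates are 0-based; a CpG site is addressed by the position of the C
#' on the forward strand, with reads from both strands pooled at that
#' position.
#'
#' @param sites data frame with columns `chrom`, `pos` (0-based integer) and
#'   optionally `strand` and `context` (one of `"CpG"`, `"CHG"`, `"CHH"`;
#'   defaults `"+"` and `"CpG"`). Must be sorted by (chrom, pos) with no
#'   duplicate sites.
#' @param M,N integer matrices, sites x samples, with `0 <= M <= N`.
#'   Column names are sample identifiers.
#' @return An object of class `methylome` with elements `sites`, `M`, `N`.
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = c(10L, 25L))
#' me <- methylome(sites, M = cbind(s1 = c(2L, 5L)), N = cbind(s1 = c(4L, 10L)))
#' site_methylation(me$M[, 1], me$N[, 1])
#' @export
methylome <- function(sites, M, N) {
  if (!is.data.frame(sites) || !all(c("chrom", "pos") %in% names(sites)))
    stop("sites must be a data frame with chrom and pos columns")
  M <- as.matrix(M)
  N <- as.matrix(N)
  if (!identical(dim(M), dim(N)))
    stop("M and N must have identical dimensions")
  if (nrow(sites) != nrow(M))
    stop("sites and count matrices disagree on the number of sites")
  if (is.null(colnames(M)))
    colnames(M) <- paste0("s", seq_len(ncol(M)))
  colnames(N) <- colnames(M)
  if (is.null(sites$strand)) sites$strand <- "+"
  if (is.null(sites$context)) sites$context <- "CpG"
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    M <- M[ord, , drop = FALSE]
    N <- N[ord, , drop = FALSE]
  }
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stop("duplicate site: ", key[which(duplicated(key))[1]])
  bad <- which(M > N | M < 0)
  if (length(bad)) {
    i <- (bad[1] - 1L) %% nrow(M) + 1L
    stop("invalid counts (M > N or M < 0) at ", sites$chrom[i], ":", sites$pos[i])
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, M = M, N = N), class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat("methylome: ", nrow(x$sites), " sites, ", ncol(x$M), " sample(s)\n", sep = "")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  samples:", paste(colnames(x$M), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.methylome` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(ncol(x$M))
  methylome(x$sites[i, , drop = FALSE],
            x$M[i, j, drop = FALSE],
            x$N[i, j, drop = FALSE])
}

#' Sample identifiers of a methylome
#' @param x a [methylome] object.
#' @return character vector of sample names.
#' @export
sample_names <- function(x) colnames(x$M)

resolve_samples <- function(x, samples) {
  if (is.null(samples)) return(colnames(x$M))
  missing <- setdiff(samples, colnames(x$M))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  samples
}

#' Per-site methylation level with depth filtering
#'
#' The methylation level of a site is `M / N` when its read depth passes the
#' filter, and missing (`NA`) otherwise. Sites with depth below `min_depth`
#' (default 4 reads) are excluded from all downstream means; missing never
#' silently becomes 0.
#'
#' @param M,N methylated and total read counts (vectors of equal length).
#' @param min_depth minimum total reads for a site to be considered.
#' @return numeric vector of fractions in \[0, 1\], `NA` where `N < min_depth`.
#' @examples
#' site_methylation(c(1, 2, 0), c(3, 4, 10))  # NA, 0.5, 0
#' @export
site_methylation <- function(M, N, min_depth = 4) {
  if (length(M) != length(N)) stop("M and N must have equal length")
  if (any(M > N, na.rm = TRUE))
    stop("M > N at position ", which(M > N)[1])
  if (any(M < 0 | N < 0, na.rm = TRUE)) stop("negative counts")
  out <- ifelse(N >= min_depth, M / N, NA_real_)
  out
}

#' Bisulfite conversion rate from a lambda spike-in
#'
#' The unmethylated lambda phage genome is carried through library
#' construction as a conversion control: any methylated call on it reflects a
#' failed conversion. The rate is `100 * (1 - sum(M) / sum(N))` over all
#' lambda cytosines, all contexts, with no depth filter. It is invariant
#' under splitting the table into chunks and pooling.
#'
#' @param lambda a [methylome] of lambda spike-in cytosines (any contexts).
#' @return conversion rate as a percentage.
#' @export
conversion_rate <- function(lambda) {
  stopifnot(inherits(lambda, "methylome"))
  n <- sum(as.numeric(lambda$N))
  if (n == 0) stop("lambda table has zero total reads")
  100 * (1 - sum(as.numeric(lambda$M)) / n)
}

#' Mean methylation over a genomic region
#'
#' Depth weighting (`"depth"`, the default) pools reads: `sum(M) / sum(N)`
#' over passing sites in the region. `"unweighted"` averages the per-site
#' fractions. Replicates/samples are pooled by summing counts, keeping the
#' depth weighting of the pooled estimate. Returns `NA` when no site in the
#' region passes the depth filter.
#'
#' @param x a [methylome].
#' @param chrom,start,end region, 0-based half-open.
#' @param samples samples to pool (default all).
#' @param weighting `"depth"` or `"unweighted"`.
#' @param min_depth per-sample, per-site depth filter.
#' @return fraction in \[0, 1\] or `NA`.
#' @export
region_mean <- function(x, chrom, start, end, samples = NULL,
                        weighting = c("depth", "unweighted"), min_depth = 4) {
  stopifnot(inherits(x, "methylome"))
  weighting <- match.arg(weighting)
  samples <- resolve_samples(x, samples)
  sel <- x$sites$chrom == chrom & x$sites$pos >= start & x$sites$pos < end
  if (!any(sel)) return(NA_real_)
  M <- x$M[sel, samples, drop = FALSE]
  N <- x$N[sel, samples, drop = FALSE]
  pass <- N >= min_depth
  if (!any(pass)) return(NA_real_)
  if (weighting == "depth") {
    sum(M[pass]) / sum(N[pass])
  } else {
    m <- rowSums(M * pass)
    n <- rowSums(N * pass)
    r <- m[n > 0] / n[n > 0]
    if (!length(r)) return(NA_real_)
    mean(r)
  }
}

#' Per-chromosome and genome-wide methylation summary
#'
#' Unweighted mean of passing per-site methylation fractions, grouped by
#' chromosome and sequence context, per sample, plus genome-wide rows
#' (`chrom = "all"`).
#'
#' @param x a [methylome].
#' @param samples samples to summarize (default all).
#' @param min_depth depth filter.
#' @return data frame with columns `sample`, `chrom`, `context`,
#'   `mean_methylation`, `n_sites`.
#' @export
global_summary <- function(x, samples = NULL, min_depth = 4) {
  stopifnot(inherits(x, "methylome"))
  samples <- resolve_samples(x, samples)
  out <- list()
  for (s in samples) {
    lv <- site_methylation(x$M[, s], x$N[, s], min_depth)
    grp <- interaction(x$sites$chrom, x$sites$context, drop = TRUE)
    for (g in levels(grp)) {
      sel <- grp == g & !is.na(lv)
      parts <- strsplit(g, ".", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = parts[1], context = parts[2],
        mean_methylation = if (any(sel)) mean(lv[sel]) else NA_real_,
        n_sites = sum(sel))
    }
    for (cx in unique(x$sites$context)) {
      sel <- x$sites$context == cx & !is.na(lv)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = "all", context = cx,
        mean_methylation = if (any(sel)) mean(lv[sel]) else NA_real_,
        n_sites = sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Methylation profile around gRNA target sites
#'
#' For every CpG within `max_dist` bp of a protospacer, reports the signed
#' distance to the nearest protospacer edge (negative upstream of the
#' protospacer interval in genome orientation, positive downstream, 0 for
#' CpGs inside the protospacer), an interior flag, the pooled methylation in
#' two sample groups, and their difference. dCas9 binding blocks the fused
#' methyltransferase, so interior CpGs are expected to show no treatment
#' effect; the most efficient de novo methylation concentrates 10-50 bp to
#' either side.
#'
#' @param x a [methylome].
#' @param guides guide data frame as returned by [place_guides()]
#'   (needs `chrom`, `start`, `end`).
#' @param samples_a,samples_b sample names of the two groups
#'   (e.g. treated and control); counts are pooled within each group.
#' @param max_dist maximum distance from a protospacer edge (bp).
#' @param min_depth depth filter.
#' @return data frame sorted by distance with columns `chrom`, `pos`,
#'   `guide`, `distance`, `interior`, `meth_a`, `meth_b`, `delta`; class
#'   `ontarget_profile`.
#' @export
ontarget_profile <- function(x, guides, samples_a, samples_b,
                             max_dist = 300, min_depth = 4) {
  stopifnot(inherits(x, "methylome"))
  if (!is.data.frame(guides) || !nrow(guides))
    stop("guides must be a nonempty data frame")
  if (!all(c("chrom", "start", "end") %in% names(guides)))
    stop("guide without genomic site: chrom/start/end required")
  samples_a <- resolve_samples(x, samples_a)
  samples_b <- resolve_samples(x, samples_b)
  rows <- list()
  for (k in seq_len(nrow(guides))) {
    g <- guides[k, ]
    sel <- which(x$sites$chrom == g$chrom &
                   x$sites$pos >= g$start - max_dist &
                   x$sites$pos < g$end + max_dist)
    if (!length(sel)) next
    pos <- x$sites$pos[sel]
    dist <- ifelse(pos < g$start, pos - g$start,
                   ifelse(pos >= g$end, pos - g$end + 1L, 0L))
    keep <- abs(dist) <= max_dist
    sel <- sel[keep]; pos <- pos[keep]; dist <- dist[keep]
    if (!length(sel)) next
    pool <- function(samples) {
      M <- x$M[sel, samples, drop = FALSE]
      N <- x$N[sel, samples, drop = FALSE]
      pass <- N >= min_depth
      m <- rowSums(M * pass); n <- rowSums(N * pass)
      ifelse(n > 0, m / n, NA_real_)
    }
    ma <- pool(samples_a); mb <- pool(samples_b)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, pos = pos,
      guide = if (!is.null(g$name)) g$name else paste0("guide", k),
      distance = dist, interior = dist == 0L,
      meth_a = ma, meth_b = mb, delta = ma - mb)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), guide = character(),
               distance = integer(), interior = logical(),
               meth_a = numeric(), meth_b = numeric(), delta = numeric())
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ontarget_profile", "data.frame")
  out
}

#' @export
plot.ontarget_profile <- function(x, ...) {
  graphics::plot(x$distance, 100 * x$meth_a, col = "firebrick", pch = 16,
                 xlab = "distance to protospacer edge (bp)",
                 ylab = "%mCpG", ylim = c(0, 100), ...)
  graphics::points(x$distance, 100 * x$meth_b, col = "grey40", pch = 1)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = c("group A", "group B"),
                   col = c("firebrick", "grey40"), pch = c(16, 1), bty = "n")
  invisible(x)
}
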