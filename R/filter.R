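#' Declarative inequality-chain designs for stochastic-DMR exclusion
#'
#' Authentic dCas9-methyltransferase DMRs must track enzyme dose and guide
#' presence: a hypermethylated region should show methylation that does not
#' decrease from the pUC19 control through enzyme-only and low-dose groups
#' to the full-dose group, and DNMT3B (less active) should not exceed
#' DNMT3A. Each chain is an ordered list of group ids whose region-level
#' methylation must be non-decreasing for hyper-DMRs and non-increasing for
#' hypo-DMRs (the hypo chains are the mirror image of the hyper chains;
#' exact ties pass).
#'
#' Built-in designs:
#' * `uPA`: chains (9, 5, 7, 1), (2, 1), (6, 2)
#' * `TGFBR3`: chains (9, 5, 8, 3), (4, 3), (6, 4)
#'
#' @param design `"uPA"`, `"TGFBR3"`, or `"custom"` with `chains` supplied.
#' @param chains for `"custom"`: list of integer vectors of group ids, each
#'   read as non-decreasing (hyper) / non-increasing (hypo) along the
#'   vector.
#' @return object of class `filter_design`.
#' @export
filter_design <- function(design = c("uPA", "TGFBR3", "custom"),
                          chains = NULL) {
  design <- match.arg(design)
  chains <- switch(design,
    uPA = list(c(9L, 5L, 7L, 1L), c(2L, 1L), c(6L, 2L)),
    TGFBR3 = list(c(9L, 5L, 8L, 3L), c(4L, 3L), c(6L, 4L)),
    custom = chains)
  if (is.null(chains) || !length(chains) ||
      !all(vapply(chains, length, 0L) >= 2))
    stop("chains must be a nonempty list of group-id vectors (length >= 2)")
  structure(list(design = design, chains = chains), class = "filter_design")
}

#' @export
print.filter_design <- function(x, ...) {
  cat("filter_design (", x$design, "):\n", sep = "")
  for (ch in x$chains)
    cat("  hyper:", paste(ch, collapse = " <= "),
        "| hypo:", paste(ch, collapse = " >= "), "\n")
  invisible(x)
}

chained_groups <- function(fdesign) sort(unique(unlist(fdesign$chains)))

#' Group-level mean methylation over a DMR interval
#'
#' Depth-weighted mean (`sum M / sum N` over passing sites, replicates
#' pooled) per group over the DMR interval only, no flank. A group with no
#' passing site in the interval gets a missing level, which marks the DMR
#' unresolvable for any chain using that group.
#'
#' @param x a [methylome].
#' @param chrom,start,end DMR interval (0-based half-open).
#' @param groups named list mapping group id (as character) to the group's
#'   sample names.
#' @param min_depth depth filter.
#' @return named numeric vector of levels, `NA` where unresolvable.
#' @export
group_levels <- function(x, chrom, start, end, groups, min_depth = 4) {
  vapply(groups, function(s)
    region_mean(x, chrom, start, end, samples = s, weighting = "depth",
                min_depth = min_depth), 0)
}

#' Evaluate inequality chains on group methylation levels
#'
#' Every inequality is non-strict; exact ties pass. A configurable slack
#' `eps` is exposed because sampling noise makes exact ordering brittle;
#' the default 0 matches the strict reading of the design.
#'
#' @param levels named numeric vector (names are group ids).
#' @param fdesign a [filter_design()].
#' @param direction `"hyper"` (levels non-decreasing along each chain) or
#'   `"hypo"` (non-increasing).
#' @param eps slack: hyper requires `left <= right + eps`.
#' @return list with `pass` (`TRUE`, `FALSE`, or `NA` when a chained
#'   group's level is missing: unresolvable, distinct from failing) and
#'   `failed` (label of the first failing comparison, or `NA`).
#' @export
passes_chains <- function(levels, fdesign, direction = c("hyper", "hypo"),
                          eps = 0) {
  direction <- match.arg(direction)
  need <- as.character(chained_groups(fdesign))
  if (!all(need %in% names(levels)))
    stop("levels missing for group(s): ",
         paste(setdiff(need, names(levels)), collapse = ", "))
  if (anyNA(levels[need]))
    return(list(pass = NA, failed = NA_character_))
  for (chain in fdesign$chains) {
    ids <- as.character(chain)
    for (i in seq_len(length(ids) - 1L)) {
      l <- levels[[ids[i]]]; r <- levels[[ids[i + 1L]]]
      ok <- if (direction == "hyper") l <= r + eps else l >= r - eps
      if (!ok) {
        lab <- if (direction == "hyper")
          paste0("g", ids[i], "<=g", ids[i + 1L]) else
            paste0("g", ids[i], ">=g", ids[i + 1L])
        return(list(pass = FALSE, failed = lab))
      }
    }
  }
  list(pass = TRUE, failed = NA_character_)
}

#' Filter DMRs by dose/gRNA monotonicity chains
#'
#' Hyper-DMRs are tested against the design's chains read as non-decreasing,
#' hypo-DMRs as non-increasing. The output partitions the input exhaustively
#' and disjointly into kept, dropped (with the first failing comparison
#' annotated) and unresolvable (some chained group had no passing coverage
#' over the interval).
#'
#' @param dmrs a [call_dmrs()] `dmr_set` (needs `chrom,start,end,direction`).
#' @param x a [methylome] covering all chained groups.
#' @param groups named list mapping group id (character) to sample names.
#' @param fdesign a [filter_design()].
#' @param eps ordering slack passed to [passes_chains()].
#' @param min_depth depth filter.
#' @return object of class `dmr_filter`: list with data frames `kept`,
#'   `dropped`, `unresolvable` (each the DMR rows plus `failed` and the
#'   per-group levels), and `all` with a `status` column.
#' @export
filter_dmrs <- function(dmrs, x, groups, fdesign, eps = 0, min_depth = 4) {
  stopifnot(is.data.frame(dmrs))
  need <- as.character(chained_groups(fdesign))
  if (!all(need %in% names(groups)))
    stop("groups must provide samples for group(s): ",
         paste(setdiff(need, names(groups)), collapse = ", "))
  groups <- groups[need]
  n <- nrow(dmrs)
  status <- character(n)
  failed <- rep(NA_character_, n)
  lv_mat <- matrix(NA_real_, n, length(need),
                   dimnames = list(NULL, paste0("level_g", need)))
  for (i in seq_len(n)) {
    lv <- group_levels(x, dmrs$chrom[i], dmrs$start[i], dmrs$end[i], groups,
                       min_depth = min_depth)
    names(lv) <- need
    lv_mat[i, ] <- lv
    res <- passes_chains(lv, fdesign, direction = dmrs$direction[i], eps = eps)
    status[i] <- if (is.na(res$pass)) "unresolvable"
      else if (res$pass) "kept" else "dropped"
    failed[i] <- res$failed
  }
  all <- cbind(as.data.frame(dmrs), status = status, failed = failed, lv_mat)
  out <- list(kept = all[status == "kept", , drop = FALSE],
              dropped = all[status == "dropped", , drop = FALSE],
              unresolvable = all[status == "unresolvable", , drop = FALSE],
              all = all, design = fdesign)
  class(out) <- "dmr_filter"
  out
}

#' @export
print.dmr_filter <- function(x, ...) {
  cat("dmr_filter (", x$design$design, " design): ",
      nrow(x$kept), " kept, ", nrow(x$dropped), " dropped, ",
      nrow(x$unresolvable), " unresolvable\n", sep = "")
  invisible(x)
}

#' Map a study design to group -> sample-name lists
#'
#' Builds the `groups` argument of [filter_dmrs()] from a [group_design()]
#' data frame and the `g<group>_r<replicate>` sample naming used by
#' [simulate_counts()].
#'
#' @param design a [group_design()]-style data frame.
#' @param replicates replicates per group.
#' @return named list of sample-name vectors, names are group ids.
#' @export
design_groups <- function(design, replicates = NULL) {
  if (is.null(replicates)) replicates <- attr(design, "replicates")
  if (is.null(replicates)) replicates <- 1L
  stats::setNames(
    lapply(design$group, function(g) paste0("g", g, "_r", seq_len(replicates))),
    as.character(design$group))
}
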