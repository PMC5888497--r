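# File formats. All genomic arithmetic in this package is 0-based
# half-open; BED is native, 1-based inputs (supplementary-style DMR
# tables) are converted at the boundary.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval data frame
#'
#' BED3 through BED6 plus any extra columns (kept as `V7`, `V8`, ...).
#' Malformed lines (fewer than 3 fields, non-numeric coordinates,
#' `end <= start`) are reported with their line numbers.
#'
#' @param path BED file; `track`/`browser`/`#` lines are skipped.
#' @return data frame `chrom, start, end[, name, score, strand, ...]`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 fields")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- is.na(starts) | is.na(ends)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": non-numeric coordinates")
  bad <- ends <= starts | starts < 0
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": end must be greater than start")
  out <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = starts, end = ends)
  extras <- c("name", "score", "strand")
  for (k in seq_len(max(nf) - 3)) {
    col <- if (k <= 3) extras[k] else paste0("V", k + 3)
    out[[col]] <- vapply(fields, function(f) if (length(f) >= k + 3)
      f[k + 3] else NA_character_, "")
  }
  if (!is.null(out$score))
    out$score <- suppressWarnings(as.numeric(out$score))
  out
}

#' Write intervals as BED
#'
#' Writes `chrom, start, end` plus `name`, `score`, `strand` and any
#' further columns present, tab-separated without header. Round-trips with
#' [read_bed()].
#'
#' @param regions interval data frame (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  check_regions(regions)
  lead <- c("chrom", "start", "end", "name", "score", "strand")
  cols <- c(intersect(lead, names(regions)), setdiff(names(regions), lead))
  # BED columns are positional: fill gaps so later columns stay in place
  need <- max(match(cols, lead), 3, na.rm = TRUE)
  df <- regions
  for (k in seq_len(need)) if (!lead[k] %in% names(df))
    df[[lead[k]]] <- if (lead[k] == "score") 0 else "."
  cols <- c(lead[seq_len(need)], setdiff(names(regions), lead))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample cytosine count table
#'
#' Tab-separated with header `chrom, pos, strand, context, M, N`
#' (0-based positions). Count errors (non-numeric, negative, `M > N`)
#' are reported with line numbers.
#'
#' @param path TSV file.
#' @return data frame with the six columns.
#' @export
read_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "character",
                                        "character", "integer", "integer"))
  need <- c("chrom", "pos", "strand", "context", "M", "N")
  if (!all(need %in% names(d)))
    stop("count table must have header: ", paste(need, collapse = ", "))
  bad <- which(is.na(d$M) | is.na(d$N) | d$M < 0 | d$N < 0)
  if (length(bad))
    stop("count parse error at line ", bad[1] + 1L, ": non-numeric or ",
         "negative counts")
  bad <- which(d$M > d$N)
  if (length(bad))
    stop("count parse error at line ", bad[1] + 1L, ": M > N")
  d[need]
}

#' Assemble a methylome from per-sample count tables
#'
#' Sites form the union over samples; a site absent from a sample gets
#' `M = N = 0` there (no coverage).
#'
#' @param paths count-table files, one per sample.
#' @param samples sample names (default: file base names).
#' @return a [methylome].
#' @export
read_methylome <- function(paths, samples = NULL) {
  if (is.null(samples))
    samples <- sub("\\.(tsv|txt)$", "", basename(paths))
  tabs <- lapply(paths, read_counts)
  all_sites <- unique(do.call(rbind, lapply(tabs, function(d)
    d[c("chrom", "pos", "strand", "context")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ]
  key <- paste(all_sites$chrom, all_sites$pos)
  M <- matrix(0L, nrow(all_sites), length(samples),
              dimnames = list(NULL, samples))
  N <- M
  for (i in seq_along(tabs)) {
    idx <- match(paste(tabs[[i]]$chrom, tabs[[i]]$pos), key)
    M[idx, i] <- tabs[[i]]$M
    N[idx, i] <- tabs[[i]]$N
  }
  methylome(all_sites, M, N)
}

#' Write a methylome as per-sample count tables
#'
#' @param x a [methylome].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the written files (one per sample), invisibly.
#' @export
write_counts <- function(x, dir, prefix = "counts") {
  stopifnot(inherits(x, "methylome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in colnames(x$M)) {
    d <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    strand = x$sites$strand, context = x$sites$context,
                    M = x$M[, s], N = x$N[, s])
    p <- file.path(dir, paste0(prefix, "_", s, ".tsv"))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a bedGraph-dialect methylation track
#'
#' Columns `chrom, start, end, pct_meth, M, N` (no header, 0-based): the
#' common per-CpG export of bisulfite pipelines. Percentages are ignored in
#' favor of the counts.
#'
#' @param path file.
#' @param sample sample name.
#' @return a single-sample [methylome].
#' @export
read_bedgraph_counts <- function(path, sample = "sample1") {
  d <- utils::read.table(path, header = FALSE, sep = "\t")
  if (ncol(d) < 6) stop("bedGraph-dialect track needs 6 columns")
  names(d)[1:6] <- c("chrom", "start", "end", "pct", "M", "N")
  bad <- which(d$M > d$N)
  if (length(bad)) stop("count parse error at line ", bad[1], ": M > N")
  sites <- data.frame(chrom = d$chrom, pos = as.integer(d$start))
  methylome(sites, M = matrix(as.integer(d$M), dimnames = list(NULL, sample)),
            N = matrix(as.integer(d$N), dimnames = list(NULL, sample)))
}

#' Read a supplementary-style DMR table
#'
#' Parses tables with header columns `chrom, start, end` plus optional
#' `length, nCpG, meanMethyl` style extras, as distributed with published
#' DMR lists. Such tables are 1-based inclusive by convention; coordinates
#' are converted to 0-based half-open on read (`one_based = FALSE` turns
#' the conversion off).
#'
#' @param path TSV file with header.
#' @param one_based whether the table's starts are 1-based (default).
#' @return data frame `chrom, start, end` plus any extra columns, with a
#'   `direction` column passed through if present.
#' @export
read_dmr_table <- function(path, one_based = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d$start <- as.integer(d$start) - if (one_based) 1L else 0L
  d$end <- as.integer(d$end)
  check_regions(d, "DMR table")
  d
}

#' Write a DMR set as TSV (BED6+ column order)
#'
#' Columns: chrom, start, end, name, area_stat (score slot), direction
#' (strand slot position), n_cpg, mean_delta, p_min.
#'
#' @param dmrs a `dmr_set`.
#' @param path output file.
#' @export
write_dmrs <- function(dmrs, path) {
  d <- as.data.frame(dmrs)
  out <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                    name = paste0("dmr_", seq_len(nrow(d))),
                    area_stat = d$area_stat, direction = d$direction,
                    n_cpg = d$n_cpg, mean_delta = d$mean_delta,
                    p_min = d$p_min)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Flat YAML-style key-value text with sections; a single file can drive a
#' full simulate / call / filter / enrich run.
#'
#' @param path file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
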