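#' Generate an annotated synthetic genome
#'
#' Builds a random genome with the feature classes used throughout the
#' package (promoter, 5'UTR, CDS, intron, 3'UTR, CpG island, CGI shore, Alu,
#' LINE1, LINE2, DHS). The sequence is CpG-depleted outside islands (as
#' mammalian genomes are) and CpG dinucleotides are planted at
#' class-specific spacings so that CpG islands have an observed/expected CpG
#' ratio well above the genome background and regulatory/repeat classes
#' carry enough CpGs to be informative for region-level statistics.
#'
#' Gene models are laid out as promoter (2 kb upstream of the TSS, mirroring
#' the usual annotation convention), 5'UTR, CDS split by one intron, and
#' 3'UTR, on the forward strand. CpG islands sit over a subset of TSSs
#' (plus intergenic orphans if the requested fraction exceeds the gene
#' count); CGI shores are the 2 kb flanking each island minus any island
#' overlap. DHS windows are placed TSS-centered for most genes, with the
#' remainder intergenic. Repeats fill intergenic space, non-overlapping
#' within each class.
#'
#' @param genome_length total genome size in bp (default 5 Mb).
#' @param n_chromosomes number of chromosomes (equal split).
#' @param feature_fractions named numeric vector: target fraction of the
#'   genome per class for `promoter`, `utr5`, `utr3`, `cds`, `intron`,
#'   `cgi`, `alu`, `line1`, `line2`, `dhs`. Must sum to <= 1. A zero
#'   promoter fraction produces no genes (and hence no gene-tied classes);
#'   an all-zero map produces a plain genome with empty annotation sets.
#' @param cgi_cpg_spacing,dhs_cpg_spacing,repeat_cpg_spacing,background_cpg_spacing
#'   mean bp between planted CpGs inside CGIs, DHS, repeats and elsewhere.
#' @param dhs_tss_fraction fraction of DHS windows anchored at TSSs.
#' @param cgi_gene_fraction not used directly; island count follows the
#'   `cgi` fraction, islands attach to TSSs first.
#' @param seed RNG seed; identical seeds reproduce identical genomes.
#' @return list with elements `genome` (a [Biostrings::DNAStringSet]),
#'   `features` (named list of 0-based half-open interval data frames),
#'   and `chrom_lengths` (named integer vector).
#' @examples
#' gen <- generate_genome(genome_length = 2e4, n_chromosomes = 1, seed = 1)
#' names(gen$features)
#' @export
generate_genome <- function(genome_length = 5e6,
                            n_chromosomes = 2,
                            feature_fractions = NULL,
                            cgi_cpg_spacing = 12,
                            dhs_cpg_spacing = 15,
                            repeat_cpg_spacing = 15,
                            background_cpg_spacing = 120,
                            dhs_tss_fraction = 0.7,
                            cgi_gene_fraction = 0.6,
                            seed = 1) {
  defaults <- c(promoter = 0.04, utr5 = 0.005, utr3 = 0.006, cds = 0.02,
                intron = 0.02, cgi = 0.015, alu = 0.02, line1 = 0.03,
                line2 = 0.015, dhs = 0.012)
  if (is.null(feature_fractions)) feature_fractions <- defaults
  ff <- defaults
  ff[names(feature_fractions)] <- feature_fractions
  if (any(ff < 0)) stop("feature fractions must be non-negative")
  if (sum(ff) > 1)
    stop("feature fractions sum to more than 1 (", round(sum(ff), 3), ")")

  with_seed(seed, {
    n_chromosomes <- as.integer(n_chromosomes)
    base_len <- floor(genome_length / n_chromosomes)
    chrom_lengths <- rep(base_len, n_chromosomes)
    chrom_lengths[n_chromosomes] <- genome_length - base_len * (n_chromosomes - 1)
    names(chrom_lengths) <- paste0("chr", seq_len(n_chromosomes))

    classes <- c("promoter", "utr5", "cds", "intron", "utr3", "cgi",
                 "shore", "alu", "line1", "line2", "dhs")
    feats <- stats::setNames(
      rep(list(data.frame(chrom = character(), start = integer(),
                          end = integer())), length(classes)), classes)
    seqs <- vector("list", n_chromosomes)

    # gene geometry derived from the fraction map
    n_genes_total <- floor(genome_length * ff["promoter"] / 2000)
    per_gene <- function(frac) {
      if (n_genes_total == 0 || frac == 0) return(0L)
      max(60L, as.integer(round(frac * genome_length / n_genes_total)))
    }
    w5 <- per_gene(ff["utr5"]); wc <- per_gene(ff["cds"])
    wi <- per_gene(ff["intron"]); w3 <- per_gene(ff["utr3"])
    unit <- 2000L + w5 + wc + wi + w3

    n_cgi_total <- floor(genome_length * ff["cgi"] / 1200)
    n_dhs_total <- floor(genome_length * ff["dhs"] / 400)
    n_alu_total <- floor(genome_length * ff["alu"] / 300)
    n_l1_total <- floor(genome_length * ff["line1"] / 2000)
    n_l2_total <- floor(genome_length * ff["line2"] / 1500)

    split_count <- function(total) {
      k <- floor(total * chrom_lengths / genome_length)
      k[1] <- k[1] + total - sum(k)
      k
    }
    n_genes <- split_count(n_genes_total)
    n_cgi <- split_count(n_cgi_total)
    n_dhs <- split_count(n_dhs_total)
    n_alu <- split_count(n_alu_total)
    n_l1 <- split_count(n_l1_total)
    n_l2 <- split_count(n_l2_total)

    add <- function(class, chrom, start, end) {
      keep <- end > start
      if (!any(keep)) return(invisible())
      feats[[class]] <<- rbind(feats[[class]], data.frame(
        chrom = chrom, start = as.integer(start[keep]),
        end = as.integer(end[keep])))
    }

    for (ci in seq_len(n_chromosomes)) {
      ch <- names(chrom_lengths)[ci]
      len <- chrom_lengths[ci]

      # --- gene placement: random non-overlapping units
      ng <- n_genes[ci]
      if (ng * unit > 0.8 * len) ng <- floor(0.8 * len / unit)
      gene_starts <- integer(0)
      if (ng > 0) {
        free <- len - ng * unit
        cuts <- sort(stats::runif(ng))
        gaps <- floor(diff(c(0, cuts, 1)) * free)
        gene_starts <- cumsum(c(gaps[1], rep(unit, ng - 1) + gaps[2:ng]))
        tss <- gene_starts + 2000L
        add("promoter", ch, gene_starts, tss)
        if (w5 > 0) add("utr5", ch, tss, tss + w5)
        if (wc > 0) {
          add("cds", ch, tss + w5, tss + w5 + wc %/% 2)
          add("cds", ch, tss + w5 + wc %/% 2 + wi, tss + w5 + wc + wi)
        }
        if (wi > 0) add("intron", ch, tss + w5 + wc %/% 2,
                        tss + w5 + wc %/% 2 + wi)
        if (w3 > 0) add("utr3", ch, tss + w5 + wc + wi, tss + w5 + wc + wi + w3)
      }

      # --- CpG islands: attached to TSSs first, intergenic orphans after
      cgi <- data.frame(chrom = character(), start = integer(), end = integer())
      if (n_cgi[ci] > 0 && ng > 0) {
        k <- min(n_cgi[ci], ng)
        pick <- sort(sample.int(ng, k))
        tssk <- gene_starts[pick] + 2000L
        cgi <- data.frame(chrom = ch, start = pmax(0L, tssk - 500L),
                          end = pmin(len, tssk + 700L))
      }

      # --- occupied space for intergenic placement
      occupied <- data.frame(chrom = character(), start = integer(),
                             end = integer())
      if (ng > 0)
        occupied <- data.frame(chrom = ch, start = gene_starts,
                               end = gene_starts + unit)
      occupied <- rbind(occupied, cgi)

      place <- function(widths) {
        placed <- place_in_gaps(len, occupied, widths)
        if (nrow(placed))
          occupied <<- rbind(occupied,
                             data.frame(chrom = ch, start = placed$start,
                                        end = placed$end))
        placed
      }

      n_orphan <- max(0L, n_cgi[ci] - ng)
      if (n_orphan > 0) {
        orph <- place(rep(1200L, n_orphan))
        if (nrow(orph))
          cgi <- rbind(cgi, data.frame(chrom = ch, start = orph$start,
                                       end = orph$end))
      }
      add("cgi", ch, cgi$start, cgi$end)

      # --- DHS: mostly TSS-centered, remainder intergenic
      dhs <- data.frame(start = integer(), end = integer())
      if (n_dhs[ci] > 0) {
        k_tss <- min(ng, round(dhs_tss_fraction * n_dhs[ci]))
        if (k_tss > 0) {
          pick <- sort(sample.int(ng, k_tss))
          tssk <- gene_starts[pick] + 2000L
          dhs <- data.frame(start = pmax(0L, tssk - 200L),
                            end = pmin(len, tssk + 200L))
        }
        k_int <- n_dhs[ci] - k_tss
        if (k_int > 0) {
          extra <- place(rep(400L, k_int))
          dhs <- rbind(dhs, extra[c("start", "end")])
        }
      }
      add("dhs", ch, dhs$start, dhs$end)

      # --- repeats in intergenic space
      alu <- place(rep(300L, n_alu[ci]))
      add("alu", ch, alu$start, alu$end)
      l1 <- place(rep(2000L, n_l1[ci]))
      add("line1", ch, l1$start, l1$end)
      l2 <- place(rep(1500L, n_l2[ci]))
      add("line2", ch, l2$start, l2$end)

      # --- sequence: random, CpG-depleted, then plant CpGs by class
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      cg <- which(s[-len] == "C" & s[-1] == "G")
      if (length(cg)) s[cg + 1L] <- "T"     # break accidental CpGs

      plant <- function(start, end, spacing) {
        if (!length(start)) return(invisible())
        for (j in seq_along(start)) {
          p <- seq(start[j] + 2, end[j] - 3, by = spacing)
          if (!length(p)) next
          p <- p + sample(0:max(1, floor(spacing / 3)), length(p), replace = TRUE)
          p <- p[p < end[j] - 1]
          s[p + 1L] <<- "C"; s[p + 2L] <<- "G"   # 0-based p -> 1-based index
        }
      }
      # background CpGs genome-wide, denser inside annotated classes
      plant(0L, len, background_cpg_spacing)
      plant(cgi$start, cgi$end, cgi_cpg_spacing)
      plant(dhs$start, dhs$end, dhs_cpg_spacing)
      plant(alu$start, alu$end, repeat_cpg_spacing)
      plant(l1$start, l1$end, repeat_cpg_spacing)
      plant(l2$start, l2$end, repeat_cpg_spacing)

      seqs[[ci]] <- paste(s, collapse = "")
    }

    # CGI shores: 2 kb flanks minus any island
    if (nrow(feats$cgi)) {
      shores <- list()
      for (ch in unique(feats$cgi$chrom)) {
        ci <- feats$cgi[feats$cgi$chrom == ch, ]
        len <- chrom_lengths[ch]
        fl <- IRanges::IRanges(
          start = pmax(1L, c(ci$start - 2000L, ci$end) + 1L),
          end = pmin(len, c(ci$start, ci$end + 2000L)))
        fl <- fl[IRanges::width(fl) > 0]
        isl <- IRanges::IRanges(start = ci$start + 1L, end = ci$end)
        sh <- IRanges::setdiff(IRanges::reduce(fl), isl)
        if (length(sh))
          shores[[length(shores) + 1L]] <- data.frame(
            chrom = ch, start = IRanges::start(sh) - 1L, end = IRanges::end(sh))
      }
      if (length(shores)) feats$shore <- do.call(rbind, shores)
    }

    for (k in names(feats)) rownames(feats[[k]]) <- NULL
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(chrom_lengths)
    list(genome = genome, features = feats, chrom_lengths = chrom_lengths)
  })
}

# Place intervals of the given widths uniformly into the gaps left between
# `occupied` intervals on a chromosome of length len. Within-call placements
# do not overlap each other or the occupied set. Returns what fits.
place_in_gaps <- function(len, occupied, widths) {
  out <- data.frame(start = integer(), end = integer())
  if (!length(widths)) return(out)
  occ <- IRanges::IRanges(start = integer(), end = integer())
  if (nrow(occupied))
    occ <- IRanges::reduce(IRanges::IRanges(start = occupied$start + 1L,
                                            end = occupied$end))
  gaps <- IRanges::gaps(occ, start = 1L, end = len)
  gs <- IRanges::start(gaps) - 1L
  ge <- IRanges::end(gaps)
  for (w in widths[sample.int(length(widths))]) {
    cap <- pmax(0L, ge - gs - w + 1L)
    if (!any(cap > 0)) break
    gi <- sample.int(length(cap), 1, prob = cap)
    off <- sample.int(cap[gi], 1) - 1L
    st <- gs[gi] + off
    out <- rbind(out, data.frame(start = st, end = st + w))
    # split the gap
    gs <- c(gs, st + w); ge <- c(ge, ge[gi])
    ge[gi] <- st
  }
  out[order(out$start), , drop = FALSE]
}

#' Place guide RNAs at protospacer-adjacent motifs
#'
#' Scans a target region (or feature class) for 20-nt protospacers followed
#' by an NGG PAM on either strand, and records guides with their genomic
#' site. For a minus-strand guide the protospacer is the reverse complement
#' of the forward-strand slice, with the PAM immediately 5' of that slice in
#' genome coordinates. Placed protospacers are verified to be present at
#' the recorded coordinates.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param n_guides number of guides to place; 0 returns an empty set.
#' @param region single-row data frame (`chrom`, `start`, `end`) to place
#'   guides in; if `NULL`, `features[[target_feature]]` is searched and the
#'   interval with the most PAM sites is used.
#' @param features named list of feature interval sets (needed when
#'   `region` is `NULL`).
#' @param target_feature feature class to target when `region` is `NULL`.
#' @param set label for the guide set (e.g. `"uPA"`, `"TGFBR3"`).
#' @param min_separation minimum bp between placed protospacer starts.
#' @param seed RNG seed.
#' @return data frame with columns `name`, `set`, `chrom`, `start`, `end`
#'   (protospacer interval, 0-based half-open), `strand`, `protospacer`,
#'   `pam`.
#' @export
place_guides <- function(genome, n_guides = 5, region = NULL, features = NULL,
                         target_feature = "promoter", set = "uPA",
                         min_separation = 30, seed = NULL) {
  empty <- data.frame(name = character(), set = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), protospacer = character(),
                      pam = character())
  if (n_guides == 0) return(empty)
  if (is.null(region)) {
    if (is.null(features) || is.null(features[[target_feature]]) ||
        !nrow(features[[target_feature]]))
      stop("no intervals available for feature class '", target_feature, "'")
    cand <- features[[target_feature]]
    region <- cand[which.max(cand$end - cand$start), , drop = FALSE]
  }
  check_regions(region, "region")
  ch <- region$chrom[1]
  sq <- as.character(Biostrings::subseq(genome[[ch]], region$start[1] + 1L,
                                        region$end[1]))
  n <- nchar(sq)
  chars <- strsplit(sq, "")[[1]]
  hits <- list()
  # forward PAM: protospacer [p-20, p), PAM [p, p+3) with GG at p+1..p+2
  gg <- which(chars == "G")
  fw <- gg[gg >= 22 & gg <= n - 1]          # 1-based index of PAM's first G
  fw <- fw[chars[fw + 1] == "G"] - 1L       # p such that seq[p+1..p+2] == GG
  for (p in fw)
    hits[[length(hits) + 1L]] <- list(strand = "+", start = p - 21L, pam_at = p - 1L)
  # reverse PAM appears as CCN on the forward strand at [q, q+3)
  cc <- which(chars == "C")
  rv <- cc[cc <= n - 22]
  rv <- rv[chars[rv + 1] == "C"]
  for (q in rv)
    hits[[length(hits) + 1L]] <- list(strand = "-", start = q + 2L, pam_at = q - 1L)
  if (length(hits) < n_guides)
    stop("insufficient PAM sites for ", n_guides, " guides in ",
         target_feature, " region ", ch, ":", region$start[1], "-", region$end[1])
  with_seed(seed, {
    ord <- sample.int(length(hits))
    chosen <- list()
    used <- integer(0)
    for (i in ord) {
      st <- hits[[i]]$start
      if (length(used) && any(abs(used - st) < min_separation)) next
      chosen[[length(chosen) + 1L]] <- hits[[i]]
      used <- c(used, st)
      if (length(chosen) == n_guides) break
    }
    if (length(chosen) < n_guides)
      stop("insufficient separated PAM sites for ", n_guides, " guides in ",
           target_feature, " region")
    chosen <- chosen[order(vapply(chosen, `[[`, 0L, "start"))]
    rows <- lapply(seq_along(chosen), function(k) {
      h <- chosen[[k]]
      g_start <- region$start[1] + h$start          # 0-based genomic
      slice <- substr(sq, h$start + 1L, h$start + 20L)
      if (h$strand == "+") {
        proto <- slice
        pam <- substr(sq, h$pam_at + 1L, h$pam_at + 3L)
      } else {
        proto <- revcomp_chr(slice)
        pam <- revcomp_chr(substr(sq, h$pam_at + 1L, h$pam_at + 3L))
      }
      data.frame(name = paste0(set, "_T", k), set = set, chrom = ch,
                 start = g_start, end = g_start + 20L, strand = h$strand,
                 protospacer = proto, pam = pam)
    })
    out <- do.call(rbind, rows)
    # post-condition: protospacers present at the recorded coordinates
    for (k in seq_len(nrow(out))) {
      slice <- as.character(Biostrings::subseq(genome[[out$chrom[k]]],
                                               out$start[k] + 1L, out$end[k]))
      want <- if (out$strand[k] == "+") out$protospacer[k] else
        revcomp_chr(out$protospacer[k])
      if (slice != want)
        stop("internal error: protospacer mismatch at ", out$chrom[k], ":",
             out$start[k])
    }
    rownames(out) <- NULL
    out
  })
}

#' PAM-proximal seed sequence of a guide
#'
#' The last `seed_len` nucleotides of the protospacer (immediately 5' of the
#' PAM); base pairing in this region dominates Cas9 off-target binding.
#'
#' @param guide one-row guide data frame or list with a `protospacer` field.
#' @param seed_len seed length in nt (5 or 11 in the analyses here).
#' @return character seed sequence.
#' @examples
#' guide_seed(list(protospacer = "GAGCCGGGCGGGAGAGGGAG"), 5)   # "GGGAG"
#' guide_seed(list(protospacer = "GAGCCGGGCGGGAGAGGGAG"), 11)  # "GGGAGAGGGAG"
#' @export
guide_seed <- function(guide, seed_len = 5) {
  proto <- if (is.data.frame(guide)) guide$protospacer[1] else guide$protospacer
  if (is.null(proto) || nchar(proto) < seed_len)
    stop("guide protospacer missing or shorter than seed_len")
  substr(proto, nchar(proto) - seed_len + 1L, nchar(proto))
}

#' Plant seed-PAM matches into DHS windows
#'
#' Writes the guide's 5-nt seed followed by an AGG PAM into the center of a
#' random fraction of DHS windows (on a random strand), creating genuine
#' off-target binding sites in open chromatin. DHS overlapping the guide's
#' own protospacer are never modified. Used by the study simulator to give
#' off-target hypermethylation a sequence-level cause that downstream
#' density scans can recover.
#'
#' @param genome a [Biostrings::DNAStringSet]; returned modified.
#' @param dhs DHS interval data frame.
#' @param guide one-row guide data frame.
#' @param fraction fraction of DHS windows to seed.
#' @param seed RNG seed.
#' @return list with `genome` (modified) and `seeded` (integer row indices
#'   of `dhs` that were given a match).
#' @export
plant_offtarget_seeds <- function(genome, dhs, guide, fraction = 0.3,
                                  seed = NULL) {
  check_regions(dhs, "dhs")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  motif <- paste0(guide_seed(guide, 5), "AGG")
  with_seed(seed, {
    avoid <- if (is.data.frame(guide) &&
                 all(c("chrom", "start", "end") %in% names(guide)))
      overlaps_any_region(dhs, guide[, c("chrom", "start", "end")])
    else rep(FALSE, nrow(dhs))
    cand <- which(!avoid)
    k <- round(fraction * nrow(dhs))
    k <- min(k, length(cand))
    pick <- if (k > 0) sort(sample(cand, k)) else integer(0)
    for (i in pick) {
      ch <- dhs$chrom[i]
      center <- (dhs$start[i] + dhs$end[i]) %/% 2
      ins <- if (stats::runif(1) < 0.5) motif else revcomp_chr(motif)
      st <- center - nchar(ins) %/% 2
      x <- genome[[ch]]
      Biostrings::subseq(x, st + 1L, st + nchar(ins)) <- Biostrings::DNAString(ins)
      genome[[ch]] <- x
    }
    list(genome = genome, seeded = pick)
  })
}
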