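#' The nine-group transfection design
#'
#' The study design crossed dCas9 methyltransferase constructs (DNMT3A or
#' DNMT3B catalytic-domain fusions), plasmid dose (50 or 500 ng) and guide
#' RNA sets (uPA promoter guides, TGFBR3 promoter guides, or none), with a
#' pUC19-transfected control:
#' group 1 DNMT3A 500 ng + uPA, 2 DNMT3B 500 ng + uPA, 3 DNMT3A 500 ng +
#' TGFBR3, 4 DNMT3B 500 ng + TGFBR3, 5 DNMT3A 500 ng only, 6 DNMT3B 500 ng
#' only, 7 DNMT3A 50 ng + uPA 50 ng, 8 DNMT3A 50 ng + TGFBR3 50 ng,
#' 9 pUC19 control.
#'
#' @param replicates libraries per group (the original study sequenced one
#'   WGBS library per group).
#' @return data frame with columns `group`, `construct`, `dose`,
#'   `grna_set` and attribute `replicates`.
#' @export
group_design <- function(replicates = 1) {
  d <- data.frame(
    group = 1:9,
    construct = c("DNMT3A", "DNMT3B", "DNMT3A", "DNMT3B", "DNMT3A",
                  "DNMT3B", "DNMT3A", "DNMT3A", "none"),
    dose = c(500, 500, 500, 500, 500, 500, 50, 50, 0),
    grna_set = c("uPA", "uPA", "TGFBR3", "TGFBR3", "none", "none",
                 "uPA", "TGFBR3", "none"))
  attr(d, "replicates") <- as.integer(replicates)
  d
}

validate_design <- function(design) {
  need <- c("group", "construct", "dose", "grna_set")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("design needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$group)) stop("duplicate group ids in design")
  if (!all(design$dose %in% c(0, 50, 500)))
    stop("doses must be drawn from {0, 50, 500} ng")
  if (9 %in% design$group) {
    g9 <- design[design$group == 9, ]
    if (g9$construct != "none" || g9$dose != 0)
      stop("group 9 must be the pUC19 control (construct none, dose 0)")
  }
  invisible(design)
}

#' Effect model for the synthetic bisulfite study
#'
#' Parameters governing where and how strongly methylation effects are
#' injected. Expected methylation at a CpG is
#' `clamp(baseline + on-target + off-target hyper - off-target hypo, 0, 1)`,
#' where each effect term is scaled by the group's construct activity and
#' dose. Catalytic mutants (E752A/E697A) have zero activity. CpGs strictly
#' inside a protospacer receive no effect (dCas9 occupancy blocks the
#' methyltransferase domain).
#'
#' @param baseline named vector of baseline methylation per feature class
#'   (classes assigned by priority `cgi > promoter > utr5 > dhs > alu >
#'   line1 > line2 > utr3 > cds > intron > shore > background`).
#' @param dispersion beta-binomial overdispersion phi (>= 0).
#' @param ontarget_delta max added methylation at protospacer flanks.
#' @param ontarget_flank bp window to each side of the protospacer that
#'   receives the on-target effect (default 1-50 bp from the edge).
#' @param near_weight weight for the first 1-9 bp of the flank (the zone
#'   closest to the bound dCas9, methylated less efficiently).
#' @param dose_scale named multipliers per dose (ng as names).
#' @param construct_scale named multipliers per construct; mutants are 0.
#' @param offtarget_hyper_delta added methylation at DHS windows carrying a
#'   seed-PAM match of an active guide.
#' @param offtarget_hypo_delta methylation removed at responsive Alu/LINE1
#'   repeats.
#' @param hypo_fraction fraction of Alu/LINE1 elements responsive to the
#'   hypomethylation effect (each assigned to one guide set).
#' @param noguide_residual residual off-target activity of the enzyme
#'   when the group carries no (or a non-matching) guide set.
#' @param conversion_rate bisulfite conversion rate.
#' @param mean_depth mean reads per CpG (Poisson).
#' @return list of class `effect_model`.
#' @export
effect_model <- function(baseline = c(cgi = 0.05, promoter = 0.08,
                                      utr5 = 0.08, dhs = 0.15, alu = 0.8,
                                      line1 = 0.8, line2 = 0.75, utr3 = 0.7,
                                      cds = 0.7, intron = 0.7, shore = 0.3,
                                      background = 0.7),
                         dispersion = 0.01,
                         ontarget_delta = 0.5,
                         ontarget_flank = c(1, 50),
                         near_weight = 0.5,
                         dose_scale = c("0" = 0, "50" = 0.6, "500" = 1),
                         construct_scale = c(DNMT3A = 1, DNMT3B = 0.65,
                                             "DNMT3A-E752A" = 0,
                                             "DNMT3B-E697A" = 0, none = 0),
                         offtarget_hyper_delta = 0.3,
                         offtarget_hypo_delta = 0.3,
                         hypo_fraction = 0.4,
                         noguide_residual = 0.25,
                         conversion_rate = 0.995,
                         mean_depth = 30) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (any(baseline < 0 | baseline > 1)) stop("baselines must be in [0, 1]")
  structure(list(baseline = baseline, dispersion = dispersion,
                 ontarget_delta = ontarget_delta,
                 ontarget_flank = ontarget_flank, near_weight = near_weight,
                 dose_scale = dose_scale, construct_scale = construct_scale,
                 offtarget_hyper_delta = offtarget_hyper_delta,
                 offtarget_hypo_delta = offtarget_hypo_delta,
                 hypo_fraction = hypo_fraction,
                 noguide_residual = noguide_residual,
                 conversion_rate = conversion_rate, mean_depth = mean_depth),
            class = "effect_model")
}

rbetabinom <- function(n, size, p, phi) {
  out <- integer(n)
  fixed <- p <= 0 | p >= 1 | phi <= 0
  if (any(fixed))
    out[fixed] <- stats::rbinom(sum(fixed), size[fixed], p[fixed])
  if (any(!fixed)) {
    s <- (1 - phi) / phi
    theta <- stats::rbeta(sum(!fixed), p[!fixed] * s, (1 - p[!fixed]) * s)
    out[!fixed] <- stats::rbinom(sum(!fixed), size[!fixed], theta)
  }
  out
}

# class assignment by priority; returns baseline per site
site_baseline <- function(sites, features, baseline) {
  priority <- c("cgi", "promoter", "utr5", "dhs", "alu", "line1", "line2",
                "utr3", "cds", "intron", "shore")
  b <- rep(unname(baseline["background"]), nrow(sites))
  assigned <- logical(nrow(sites))
  pt <- data.frame(chrom = sites$chrom, start = sites$pos,
                   end = sites$pos + 1L)
  for (cl in rev(priority)) {                 # low priority first, high overwrites
    f <- features[[cl]]
    if (is.null(f) || !nrow(f) || is.na(baseline[cl])) next
    hit <- overlaps_any_region(pt, f)
    b[hit] <- baseline[cl]
    assigned <- assigned | hit
  }
  b
}

#' Simulate multi-group bisulfite count tables with known injected effects
#'
#' For every CpG (forward-strand C of each CG dinucleotide in the genome)
#' and every sample, read depth is Poisson(`mean_depth`) and the methylated
#' count is beta-binomial around the group's expected methylation:
#' baseline by feature class, plus an on-target delta at 1-50 bp protospacer
#' flanks of the group's own guides (scaled by dose and construct activity),
#' plus a hypermethylation delta at DHS windows whose sequence carries a
#' 5nt-seed + NGG match of an active guide, minus a hypomethylation delta at
#' responsive Alu/LINE1 repeats. Unconverted cytosines add
#' `(1 - p) * (1 - conversion_rate)` to the observed level. Truth tables
#' record every interval with a nonzero injected delta and its sign.
#'
#' @param genome a [Biostrings::DNAStringSet] (after any seed planting).
#' @param features feature list from [generate_genome()].
#' @param guides guide data frame from [place_guides()] (possibly several
#'   sets row-bound together).
#' @param design a [group_design()]-style data frame (any subset of groups).
#' @param effects an [effect_model()].
#' @param replicates samples per group (overrides the design attribute).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return list with `meth` (a [methylome], samples named `g<group>_r<rep>`),
#'   `truth` (data frame: `chrom,start,end,name,score,strand,type,set` where
#'   `score` is the signed injected delta at full activity), `p_expected`
#'   (matrix of expected methylation, sites x groups, before conversion
#'   error), `design`, and `effects`.
#' @export
simulate_counts <- function(genome, features, guides, design = group_design(),
                            effects = effect_model(), replicates = NULL,
                            seed = 1) {
  validate_design(design)
  if (is.null(replicates)) replicates <- attr(design, "replicates")
  if (is.null(replicates)) replicates <- 1L
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  # CpG site catalogue
  sites <- do.call(rbind, lapply(names(genome), function(ch) {
    m <- Biostrings::matchPattern("CG", genome[[ch]])
    data.frame(chrom = ch, pos = Biostrings::start(m) - 1L)
  }))
  sites$strand <- "+"
  sites$context <- "CpG"
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  ns <- nrow(sites)

  baseline <- site_baseline(sites, features, effects$baseline)

  # protospacer interiors get no effect at all
  interior <- overlaps_any_region(
    data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L),
    guides[, c("chrom", "start", "end")])

  # on-target flank weight per site per guide set
  sets <- unique(guides$set)
  flank_lo <- effects$ontarget_flank[1]
  flank_hi <- effects$ontarget_flank[2]
  ontarget_w <- matrix(0, ns, length(sets), dimnames = list(NULL, sets))
  truth <- list()
  for (k in seq_len(nrow(guides))) {
    g <- guides[k, ]
    sel <- sites$chrom == g$chrom
    d <- ifelse(sites$pos[sel] < g$start, g$start - sites$pos[sel],
                ifelse(sites$pos[sel] >= g$end, sites$pos[sel] - g$end + 1L, 0L))
    w <- ifelse(d >= 10 & d <= flank_hi, 1,
                ifelse(d >= flank_lo & d <= 9, effects$near_weight, 0))
    ontarget_w[sel, g$set] <- pmax(ontarget_w[sel, g$set], w)
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = g$chrom,
      start = c(max(0L, g$start - flank_hi), g$end),
      end = c(g$start, min(chrom_lengths[g$chrom], g$end + flank_hi)),
      name = paste0(g$name, c("_up", "_down")),
      score = effects$ontarget_delta, strand = ".",
      type = "ontarget", set = g$set)
  }
  ontarget_w[interior, ] <- 0

  with_seed(seed, {
    # off-target hyper: DHS whose sequence carries seed5+NGG of a set's guide
    hyper_in <- matrix(FALSE, ns, length(sets), dimnames = list(NULL, sets))
    dhs <- features$dhs
    if (!is.null(dhs) && nrow(dhs)) {
      dseq <- extract_windows(genome, dhs)
      for (st in sets) {
        gset <- guides[guides$set == st, , drop = FALSE]
        cnt <- rep(0L, nrow(dhs))
        for (k in seq_len(nrow(gset)))
          cnt <- cnt + count_both_strands(dseq,
                                          paste0(guide_seed(gset[k, ], 5), "NGG"))
        resp <- which(cnt > 0)
        if (length(resp)) {
          hyper_in[, st] <- overlaps_any_region(
            data.frame(chrom = sites$chrom, start = sites$pos,
                       end = sites$pos + 1L), dhs[resp, , drop = FALSE])
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = dhs$chrom[resp], start = dhs$start[resp],
            end = dhs$end[resp],
            name = paste0("offtarget_hyper_", st, "_", resp),
            score = effects$offtarget_hyper_delta, strand = ".",
            type = "offtarget_hyper", set = st)
        }
      }
    }
    hyper_in[interior, ] <- FALSE

    # off-target hypo: responsive Alu/LINE1 elements, each tied to one set
    hypo_in <- matrix(FALSE, ns, length(sets), dimnames = list(NULL, sets))
    reps <- rbind(features$alu, features$line1)
    if (!is.null(reps) && nrow(reps) && effects$hypo_fraction > 0 &&
        length(sets)) {
      n_resp <- round(effects$hypo_fraction * nrow(reps))
      resp <- sort(sample.int(nrow(reps), n_resp))
      assigned <- sample(sets, length(resp), replace = TRUE)
      for (st in sets) {
        ri <- reps[resp[assigned == st], , drop = FALSE]
        if (!nrow(ri)) next
        hypo_in[, st] <- overlaps_any_region(
          data.frame(chrom = sites$chrom, start = sites$pos,
                     end = sites$pos + 1L), ri)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = ri$chrom, start = ri$start, end = ri$end,
          name = paste0("offtarget_hypo_", st, "_", seq_len(nrow(ri))),
          score = -effects$offtarget_hypo_delta, strand = ".",
          type = "offtarget_hypo", set = st)
      }
    }

    # expected methylation per site per group
    groups <- design$group
    p_exp <- matrix(NA_real_, ns, length(groups),
                    dimnames = list(NULL, as.character(groups)))
    for (gi in seq_along(groups)) {
      grp <- design[gi, ]
      act <- unname(effects$construct_scale[grp$construct] *
                      effects$dose_scale[as.character(grp$dose)])
      if (is.na(act)) stop("unknown construct or dose in design row ", gi)
      p <- baseline
      if (act > 0) {
        for (st in sets) {
          wt <- if (grp$grna_set == st) 1 else effects$noguide_residual
          if (grp$grna_set == st)        # on-target needs the matching guides
            p <- p + effects$ontarget_delta * act * ontarget_w[, st]
          p <- p + effects$offtarget_hyper_delta * act * wt * hyper_in[, st]
          p <- p - effects$offtarget_hypo_delta * act * wt * hypo_in[, st]
        }
      }
      p_exp[, gi] <- clamp01(p)
    }

    # draw counts
    sample_ids <- as.vector(t(outer(groups, seq_len(replicates),
                                    function(g, r) paste0("g", g, "_r", r))))
    M <- matrix(0L, ns, length(sample_ids), dimnames = list(NULL, sample_ids))
    N <- M
    conv <- effects$conversion_rate
    for (gi in seq_along(groups)) {
      p_obs <- p_exp[, gi] + (1 - p_exp[, gi]) * (1 - conv)
      for (r in seq_len(replicates)) {
        sid <- paste0("g", groups[gi], "_r", r)
        n <- stats::rpois(ns, effects$mean_depth)
        m <- rbetabinom(ns, n, p_obs, effects$dispersion)
        M[, sid] <- m
        N[, sid] <- n
      }
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character(),
                 type = character(), set = character())
    rownames(truth) <- NULL
    list(meth = methylome(sites, M, N), truth = truth, p_expected = p_exp,
         design = design, effects = effects)
  })
}

#' Simulate a null methylome for test calibration
#'
#' Every sample is drawn from the same beta-binomial at every site: the
#' two-condition CpG test should then reject at close to its nominal rate.
#' Site spacing is drawn uniformly from `spacing`, mimicking the sparse
#' background CpGs of a depleted genome.
#'
#' @param n_sites number of CpG sites.
#' @param n_samples number of samples.
#' @param mean_depth Poisson mean depth.
#' @param p true methylation level (common to all sites and samples).
#' @param dispersion beta-binomial phi.
#' @param spacing two-element range of inter-site distances (bp).
#' @param seed RNG seed.
#' @return a [methylome] with samples `s1..s<n>`.
#' @export
simulate_null_methylome <- function(n_sites = 10000, n_samples = 2,
                                    mean_depth = 30, p = 0.5,
                                    dispersion = 0.01,
                                    spacing = c(150, 250), seed = NULL) {
  with_seed(seed, {
    pos <- cumsum(sample(spacing[1]:spacing[2], n_sites, replace = TRUE))
    M <- matrix(0L, n_sites, n_samples,
                dimnames = list(NULL, paste0("s", seq_len(n_samples))))
    N <- M
    for (j in seq_len(n_samples)) {
      n <- stats::rpois(n_sites, mean_depth)
      N[, j] <- n
      M[, j] <- rbetabinom(n_sites, n, rep(p, n_sites), dispersion)
    }
    methylome(data.frame(chrom = "chr1", pos = pos), M, N)
  })
}

#' Simulate a lambda phage conversion spike-in
#'
#' The 48,502 bp lambda genome is fully unmethylated, so any methylated
#' call on it is a conversion failure: reads are methylated at rate
#' `1 - conversion_rate`.
#'
#' @param conversion_rate fraction of unmethylated C successfully
#'   converted; must be in (0, 1].
#' @param mean_depth Poisson mean reads per cytosine.
#' @param n_cytosines number of lambda cytosine sites to emit.
#' @param seed RNG seed.
#' @return single-sample [methylome] on chromosome `"lambda"`, with
#'   attribute `lambda_length = 48502`.
#' @export
simulate_lambda <- function(conversion_rate = 0.995, mean_depth = 30,
                            n_cytosines = 12000, seed = NULL) {
  if (conversion_rate <= 0 || conversion_rate > 1)
    stop("conversion_rate must be in (0, 1]")
  lambda_length <- 48502L
  with_seed(seed, {
    pos <- sort(sample.int(lambda_length, n_cytosines)) - 1L
    ctx <- sample(c("CpG", "CHG", "CHH"), n_cytosines, replace = TRUE,
                  prob = c(0.1, 0.2, 0.7))
    N <- stats::rpois(n_cytosines, mean_depth)
    M <- stats::rbinom(n_cytosines, N, 1 - conversion_rate)
    me <- methylome(data.frame(chrom = "lambda", pos = pos, strand = "+",
                               context = ctx),
                    M = cbind(lambda = M), N = cbind(lambda = N))
    attr(me, "lambda_length") <- lambda_length
    me
  })
}

#' Simulate ChIP-seq peaks at guide seed matches
#'
#' Emits a peak at every on-target protospacer plus a configurable fraction
#' of genome-wide 5nt-seed + NGG matches of the supplied guides, sampled
#' preferentially inside DHS (weight `dhs_weight` vs 1 outside). Peak
#' centers jitter up to 35 bp around the match.
#'
#' @param guides guide data frame (the set driving binding).
#' @param genome a [Biostrings::DNAStringSet].
#' @param dhs DHS interval data frame.
#' @param fraction fraction of seed matches that become peaks; 0 emits
#'   only the on-target peaks.
#' @param dhs_weight sampling weight for matches inside DHS (> 1 enriches
#'   peaks in open chromatin).
#' @param peak_halfwidth half-width of emitted peaks in bp.
#' @param jitter max |offset| of peak center from the match (bp).
#' @param seed RNG seed.
#' @return data frame `chrom,start,end,name,score,strand` of peak intervals.
#' @export
simulate_chip_peaks <- function(guides, genome, dhs, fraction = 0.3,
                                dhs_weight = 4, peak_halfwidth = 100,
                                jitter = 35, seed = NULL) {
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  matches <- list()
  for (k in seq_len(nrow(guides))) {
    pat <- paste0(guide_seed(guides[k, ], 5), "NGG")
    for (ch in names(genome)) {
      for (p in c(pat, revcomp_chr(pat))) {
        m <- Biostrings::matchPattern(p, genome[[ch]], fixed = FALSE)
        if (length(m))
          matches[[length(matches) + 1L]] <- data.frame(
            chrom = ch,
            center = Biostrings::start(m) - 1L + nchar(p) %/% 2)
      }
    }
  }
  matches <- if (length(matches)) unique(do.call(rbind, matches)) else
    data.frame(chrom = character(), center = integer())
  with_seed(seed, {
    out <- data.frame(chrom = guides$chrom,
                      center = (guides$start + guides$end) %/% 2,
                      name = paste0("ontarget_", guides$name))
    n_pick <- round(fraction * nrow(matches))
    if (n_pick > 0 && nrow(matches)) {
      in_dhs <- overlaps_any_region(
        data.frame(chrom = matches$chrom, start = matches$center,
                   end = matches$center + 1L), dhs)
      wts <- ifelse(in_dhs, dhs_weight, 1)
      pick <- sample.int(nrow(matches), min(n_pick, nrow(matches)),
                         prob = wts)
      jit <- sample(seq(-jitter, jitter), length(pick), replace = TRUE)
      out <- rbind(out, data.frame(
        chrom = matches$chrom[pick], center = matches$center[pick] + jit,
        name = paste0("peak_", seq_along(pick))))
    }
    res <- data.frame(chrom = out$chrom,
                      start = pmax(0L, out$center - peak_halfwidth),
                      end = pmin(unname(chrom_lengths[out$chrom]),
                                 out$center + peak_halfwidth),
                      name = out$name, score = 1, strand = ".")
    res <- res[order(res$chrom, res$start), ]
    rownames(res) <- NULL
    res
  })
}

#' Simulate a complete nine-group study
#'
#' Convenience wrapper chaining [generate_genome()], [place_guides()] (5 uPA
#' guides in one promoter, 3 TGFBR3 guides in another),
#' [plant_offtarget_seeds()] (uPA and TGFBR3 seed-PAM matches written into
#' disjoint DHS subsets) and [simulate_counts()].
#'
#' @param genome_length,n_chromosomes passed to [generate_genome()].
#' @param design,effects passed to [simulate_counts()].
#' @param n_upa_guides,n_tgfbr3_guides guides per set.
#' @param upa_seed_fraction,tgfbr3_seed_fraction fraction of DHS receiving
#'   seed matches of each set's dominant (second) guide.
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return list with `genome`, `features`, `chrom_lengths`, `guides`,
#'   `meth`, `truth`, `p_expected`, `design`, `effects`.
#' @export
simulate_study <- function(genome_length = 5e6, n_chromosomes = 2,
                           design = group_design(), effects = effect_model(),
                           n_upa_guides = 5, n_tgfbr3_guides = 3,
                           upa_seed_fraction = 0.4,
                           tgfbr3_seed_fraction = 0.3, seed = 1) {
  gen <- generate_genome(genome_length = genome_length,
                         n_chromosomes = n_chromosomes, seed = seed)
  prom <- gen$features$promoter
  if (nrow(prom) < 2) stop("genome too small: need at least two promoters")
  # target CpG-island promoters (the targeted loci are dense, hypomethylated
  # CGI promoters): use the promoter/CGI overlap when available
  cgi_hit <- overlaps_any_region(prom, gen$features$cgi)
  pick <- c(which(cgi_hit), which(!cgi_hit))[1:2]
  target_region <- function(i) {
    p <- prom[i, , drop = FALSE]
    if (!cgi_hit[i]) return(p)
    cg <- gen$features$cgi
    cg <- cg[cg$chrom == p$chrom & cg$start < p$end & cg$end > p$start, ,
             drop = FALSE][1, ]
    data.frame(chrom = p$chrom, start = max(p$start, cg$start),
               end = min(p$end, cg$end))
  }
  guides_upa <- place_guides(gen$genome, n_guides = n_upa_guides,
                             region = target_region(pick[1]), set = "uPA",
                             seed = seed + 101L)
  guides_tg <- place_guides(gen$genome, n_guides = n_tgfbr3_guides,
                            region = target_region(pick[2]), set = "TGFBR3",
                            seed = seed + 102L)
  guides <- rbind(guides_upa, guides_tg)

  dhs <- gen$features$dhs
  dominant_upa <- guides_upa[min(2, nrow(guides_upa)), ]
  dominant_tg <- guides_tg[min(2, nrow(guides_tg)), ]
  pl1 <- plant_offtarget_seeds(gen$genome, dhs, dominant_upa,
                               fraction = upa_seed_fraction, seed = seed + 201L)
  remaining <- dhs[-pl1$seeded, , drop = FALSE]
  pl2 <- plant_offtarget_seeds(pl1$genome, remaining, dominant_tg,
                               fraction = tgfbr3_seed_fraction /
                                 max(1e-9, 1 - upa_seed_fraction),
                               seed = seed + 202L)
  genome <- pl2$genome

  sim <- simulate_counts(genome, gen$features, guides, design = design,
                         effects = effects, seed = seed + 301L)
  c(list(genome = genome, features = gen$features,
         chrom_lengths = gen$chrom_lengths, guides = guides), sim)
}
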