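test_that("simulated counts conserve reads and are seed-deterministic", {
  st <- small_study()
  expect_true(all(st$meth$M <= st$meth$N))
  expect_true(all(st$meth$M >= 0))
  expect_setequal(colnames(st$meth$M), paste0("g", 1:9, "_r1"))

  gen <- generate_genome(genome_length = 5e4, n_chromosomes = 1, seed = 2)
  gd <- place_guides(gen$genome, n_guides = 2, features = gen$features,
                     target_feature = "promoter", seed = 4)
  s1 <- simulate_counts(gen$genome, gen$features, gd, seed = 77)
  s2 <- simulate_counts(gen$genome, gen$features, gd, seed = 77)
  expect_identical(s1$meth, s2$meth)
  expect_identical(s1$truth, s2$truth)
})

test_that("expected methylation follows baseline, interior and dose rules", {
  st <- small_study()
  sites <- st$meth$sites
  eff <- st$effects
  p <- st$p_expected

  # control group: baseline everywhere (CGI CpGs far from guides)
  cgi <- st$features$cgi
  in_cgi <- overlaps_any(data.frame(chrom = sites$chrom, start = sites$pos,
                                    end = sites$pos + 1L), cgi)
  expect_true(all(p[in_cgi, "9"] %in% eff$baseline))
  expect_true(stats::median(p[in_cgi, "9"]) == eff$baseline[["cgi"]])

  # CpGs strictly inside a protospacer keep the baseline in every group
  interior <- overlaps_any(data.frame(chrom = sites$chrom, start = sites$pos,
                                      end = sites$pos + 1L),
                           st$guides[, c("chrom", "start", "end")])
  expect_gt(sum(interior), 0)
  expect_equal(p[interior, "1"], p[interior, "9"])

  # dose/construct ordering at on-target flank CpGs of the uPA guides
  gu <- st$guides[st$guides$set == "uPA", ]
  flank <- !interior & overlaps_any(
    data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L),
    data.frame(chrom = gu$chrom, start = gu$start - 50L, end = gu$end + 50L))
  expect_gt(sum(flank), 0)
  expect_true(all(p[flank, "1"] >= p[flank, "7"]))
  expect_true(all(p[flank, "7"] >= p[flank, "9"]))
  expect_gt(mean(p[flank, "1"] - p[flank, "9"]), 0.2)
})

test_that("simulated on-target methylation tracks the closed-form dose effect", {
  st <- small_study()
  sites <- st$meth$sites
  gu <- st$guides[st$guides$set == "uPA", ][1, ]
  flank_idx <- which(sites$chrom == gu$chrom &
                       ((sites$pos >= gu$start - 50 & sites$pos < gu$start) |
                          (sites$pos >= gu$end & sites$pos < gu$end + 50)))
  expect_gt(length(flank_idx), 0)
  i <- flank_idx[1]
  p1 <- st$p_expected[i, "1"]; p7 <- st$p_expected[i, "7"]
  expect_gt(p1, p7)
  # Monte-Carlo at the site: 2000 draws per group at depth 30
  set.seed(42)
  draw_mean <- function(pp) {
    n <- rep(30L, 2000)
    mean(guidemeth:::rbetabinom(2000, n, rep(pp, 2000),
                                st$effects$dispersion) / n)
  }
  m1 <- draw_mean(p1); m7 <- draw_mean(p7)
  expect_gt(m1, m7)
  se <- sqrt(p1 * (1 - p1) * 1.3 / 30 / 2000) * 3
  expect_lt(abs(m1 - p1), 3 * se + 0.01)
})

test_that("catalytic-mutant constructs are distributionally identical to control", {
  gen <- generate_genome(genome_length = 2e5, n_chromosomes = 1, seed = 6)
  gd <- place_guides(gen$genome, n_guides = 2, features = gen$features,
                     target_feature = "promoter", set = "uPA", seed = 1)
  design <- data.frame(group = c(1L, 2L, 9L),
                       construct = c("DNMT3A-E752A", "DNMT3B-E697A", "none"),
                       dose = c(500, 500, 0),
                       grna_set = c("uPA", "uPA", "none"))
  sim <- simulate_counts(gen$genome, gen$features, gd, design = design,
                         seed = 13)
  expect_equal(sim$p_expected[, "1"], sim$p_expected[, "9"])
  expect_equal(sim$p_expected[, "2"], sim$p_expected[, "9"])
  # two-sample check on simulated per-site levels at truth intervals
  tr <- sim$truth
  in_truth <- overlaps_any(data.frame(chrom = sim$meth$sites$chrom,
                                      start = sim$meth$sites$pos,
                                      end = sim$meth$sites$pos + 1L), tr)
  idx <- which(in_truth)[seq_len(min(1000, sum(in_truth)))]
  r_mut <- sim$meth$M[idx, "g1_r1"] / pmax(1, sim$meth$N[idx, "g1_r1"])
  r_ctl <- sim$meth$M[idx, "g9_r1"] / pmax(1, sim$meth$N[idx, "g9_r1"])
  expect_gt(stats::t.test(r_mut, r_ctl)$p.value, 0.01)
})

test_that("lambda spike-in reflects the conversion rate", {
  perfect <- simulate_lambda(conversion_rate = 1, seed = 1)
  expect_true(all(perfect$M == 0))
  expect_equal(attr(perfect, "lambda_length"), 48502L)
  expect_error(simulate_lambda(conversion_rate = 0), "conversion_rate")
  expect_error(simulate_lambda(conversion_rate = 1.2), "conversion_rate")

  lam <- simulate_lambda(conversion_rate = 0.995, mean_depth = 30,
                         n_cytosines = 4000, seed = 8)
  est <- conversion_rate(lam)
  n_reads <- sum(lam$N)
  se <- 100 * sqrt(0.005 * 0.995 / n_reads)
  expect_lt(abs(est - 99.5), 3 * se)
  expect_gt(est, 99)
})

test_that("chip peaks sit at seed matches and prefer open chromatin", {
  st <- small_study()
  gu <- st$guides[st$guides$set == "uPA", ]
  only_on <- simulate_chip_peaks(gu, st$genome, st$features$dhs,
                                 fraction = 0, seed = 1)
  expect_equal(nrow(only_on), nrow(gu))
  expect_true(all(grepl("^ontarget_", only_on$name)))

  pk <- simulate_chip_peaks(gu, st$genome, st$features$dhs, fraction = 0.4,
                            dhs_weight = 6, peak_halfwidth = 100, seed = 2)
  off <- pk[!grepl("^ontarget_", pk$name), ]
  expect_gt(nrow(off), 0)
  # every off-target center within +/- 35 bp of a genome-wide seed match
  centers <- (off$start + off$end) %/% 2
  hits <- lapply(unique(gu$set), function(s) NULL)
  match_pos <- integer(0)
  for (k in seq_len(nrow(gu))) {
    pat <- paste0(guide_seed(gu[k, ], 5), "NGG")
    for (p in c(pat, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pat))))) {
      m <- Biostrings::matchPattern(p, st$genome[[1]], fixed = FALSE)
      match_pos <- c(match_pos, Biostrings::start(m) - 1L + nchar(p) %/% 2)
    }
  }
  mind <- vapply(centers, function(cc) min(abs(match_pos - cc)), 0)
  expect_true(all(mind <= 35))
  # open-chromatin preference
  in_dhs <- mean(overlaps_any(off, st$features$dhs))
  bg_frac <- sum(st$features$dhs$end - st$features$dhs$start) /
    sum(st$chrom_lengths)
  expect_gt(in_dhs, bg_frac)
})
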