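test_that("background sampling matches count, lengths and seed", {
  st <- small_study()
  regions <- random_regions(40, chrom_len = 4e5)
  bg1 <- sample_background(regions, st$chrom_lengths, seed = 9)
  bg2 <- sample_background(regions, st$chrom_lengths, seed = 9)
  expect_identical(bg1, bg2)
  expect_equal(nrow(bg1), nrow(regions))
  expect_true(all((bg1$end - bg1$start) %in% (regions$end - regions$start)))
  expect_true(all(bg1$start >= 0))
  expect_true(all(bg1$end <= st$chrom_lengths[bg1$chrom]))
  expect_error(sample_background(regions[0, ], st$chrom_lengths), "nonempty")
})

test_that("feature enrichment reproduces the 2x2 arithmetic and exact p", {
  # 100 unit regions, 30 covered by the feature; background 100, 10 covered
  regions <- data.frame(chrom = "chr1", start = seq(0, 990, 10),
                        end = seq(0, 990, 10) + 2L)
  background <- data.frame(chrom = "chr1", start = seq(5000, 5990, 10),
                           end = seq(5000, 5990, 10) + 2L)
  feat <- rbind(regions[1:30, ], background[1:10, ])
  er <- feature_enrichment(regions, background, list(f = feat))
  expect_equal(er$regions_in, 30)
  expect_equal(er$background_in, 10)
  expect_equal(er$odds_ratio, (30 * 90) / (70 * 10))
  expect_equal(er$p, fisher_oracle(30, 70, 10, 90), tolerance = 1e-12)
  # identical sets: odds ratio 1, p 1
  er2 <- feature_enrichment(regions, regions, list(f = feat))
  expect_equal(er2$odds_ratio, 1)
  expect_equal(er2$p, 1)
  expect_warning(feature_enrichment(regions, background,
                                    list(empty = regions[0, ])), "empty")
})

test_that("exact-test p equals the hypergeometric tail sum on random tables", {
  set.seed(17)
  for (i in 1:60) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    c_ <- sample(0:40, 1); d <- sample(0:40, 1)
    if ((a + b) * (c_ + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    expect_lt(abs(p_pkg - fisher_oracle(a, b, c_, d)), 1e-10)
  }
})

test_that("DHS core fractions use the bare interval", {
  dhs <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                    end = c(1400L, 5400L))
  inside <- data.frame(chrom = "chr1", start = c(1100L, 5100L),
                       end = c(1150L, 5200L))
  outside <- data.frame(chrom = "chr1", start = c(9000L, 9500L),
                        end = c(9100L, 9600L))
  r1 <- dhs_core_fraction(inside, dhs, outside)
  expect_equal(r1$fraction, 1)
  r2 <- dhs_core_fraction(outside, dhs, outside)
  expect_equal(r2$fraction, 0)
  expect_equal(r2$p, 1)
  # a region overlapping only the flank does not count
  flanky <- data.frame(chrom = "chr1", start = 1400L, end = 1450L)
  expect_equal(dhs_core_fraction(flanky, dhs, outside)$fraction, 0)
})

test_that("seed and PAM densities match a brute-force scan", {
  guide <- list(protospacer = "GAGCCGGGCGGGAGAGGGAG")
  expect_equal(guide_seed(guide, 5), "GGGAG")
  expect_equal(guide_seed(guide, 11), "GGGAGAGGGAG")

  genome <- Biostrings::DNAStringSet(c(chr1 = "TTGGGAGAGGCCAAAAAAAAAA"))
  w <- data.frame(chrom = "chr1", start = 0L, end = 12L)
  dr <- seed_pam_density(w, genome, guide, seed_len = 5)
  expect_equal(dr$windows$count, 1)   # GGGAG at offset 2 followed by AGG
  w0 <- data.frame(chrom = "chr1", start = 12L, end = 22L)
  expect_equal(seed_pam_density(w0, genome, guide)$windows$count, 0)

  pg <- Biostrings::DNAStringSet(c(chr1 = "AGGAGGGGAAAA"))
  expect_equal(pam_density(data.frame(chrom = "chr1", start = 0L, end = 4L),
                           pg)$windows$count, 1)     # AGG fwd, TCCT rev
  expect_equal(pam_density(data.frame(chrom = "chr1", start = 4L, end = 8L),
                           pg)$windows$count, 2)     # GGG twice fwd
  expect_equal(pam_density(data.frame(chrom = "chr1", start = 8L, end = 12L),
                           pg)$windows$count, 0)

  # random windows vs the all-offset both-strand oracle
  st <- small_study()
  set.seed(31)
  ws <- random_regions(40, chrom_len = 4e5, min_w = 30, max_w = 120)
  for (pat in c("GGGAG", "GGGAGAGGGAG")) {
    dd <- seed_pam_density(ws, st$genome, list(protospacer = pat),
                           seed_len = nchar(pat))
    seqs <- as.character(Biostrings::DNAStringSet(
      mapply(function(s, e) as.character(
        Biostrings::subseq(st$genome[[1]], s + 1, e)), ws$start, ws$end)))
    want <- vapply(seqs, brute_scan, 0L, pattern = paste0(pat, "NGG"))
    expect_equal(dd$windows$count, unname(want))
  }
  dpam <- pam_density(ws, st$genome)
  seqs <- vapply(seq_len(nrow(ws)), function(i) as.character(
    Biostrings::subseq(st$genome[[1]], ws$start[i] + 1, ws$end[i])), "")
  expect_equal(dpam$windows$count,
               unname(vapply(seqs, brute_scan, 0L, pattern = "NGG")))
  # densities are counts per kb; summary is median with SD
  expect_equal(dpam$windows$density,
               dpam$windows$count / ((ws$end - ws$start) / 1000))
  expect_equal(dpam$median_density, stats::median(dpam$windows$density))
})

test_that("density scans are invariant under reverse-complementing the genome", {
  st <- small_study()
  L <- unname(st$chrom_lengths[1])
  rc_genome <- Biostrings::DNAStringSet(
    c(chr1 = as.character(Biostrings::reverseComplement(st$genome[[1]]))))
  set.seed(13)
  ws <- random_regions(25, chrom_len = 4e5, min_w = 40, max_w = 150)
  ws_rc <- data.frame(chrom = "chr1", start = L - ws$end, end = L - ws$start)
  guide <- st$guides[1, ]
  d1 <- seed_pam_density(ws, st$genome, guide)
  d2 <- seed_pam_density(ws_rc, rc_genome, guide)
  expect_equal(d1$windows$count, d2$windows$count)
  p1 <- pam_density(ws, st$genome); p2 <- pam_density(ws_rc, rc_genome)
  expect_equal(p1$windows$count, p2$windows$count)
})

test_that("density comparison reports both exact-test and t-test p values", {
  st <- small_study()
  guide <- st$guides[st$guides$set == "uPA", ][2, ]
  seeded <- st$truth[st$truth$type == "offtarget_hyper" &
                       st$truth$set == "uPA", c("chrom", "start", "end")]
  bg <- sample_background(seeded, st$chrom_lengths, seed = 3)
  cmp <- density_compare(seed_pam_density(seeded, st$genome, guide),
                         seed_pam_density(bg, st$genome, guide))
  expect_true(is.finite(cmp$p_fisher))
  expect_lt(cmp$p_fisher, 0.05)
  expect_gt(cmp$median_a, cmp$median_b)
})

test_that("flank expansion extends and clips without merging", {
  r <- data.frame(chrom = "chr1", start = c(1000L, 5L), end = c(1060L, 20L))
  ex <- expand_flanks(r, 100, c(chr1 = 10000L))
  expect_equal(ex$start, c(900L, 0L))
  expect_equal(ex$end, c(1160L, 120L))
  expect_equal(nrow(ex), 2)
  # length grows by exactly 2*flank except at clips
  expect_equal(ex$end[1] - ex$start[1], (r$end[1] - r$start[1]) + 200L)
  near_end <- data.frame(chrom = "chr1", start = 9950L, end = 9990L)
  ex2 <- expand_flanks(near_end, 100, c(chr1 = 10000L))
  expect_equal(ex2$end, 10000L)
})

test_that("metaplots are flat on constant methylomes and detect DHS gain", {
  pos <- seq(0, 20000, by = 40)
  me <- make_methylome(pos, M = cbind(a = rep(5L, length(pos)),
                                      b = rep(5L, length(pos))),
                       N = cbind(a = rep(10L, length(pos)),
                                 b = rep(10L, length(pos))))
  dhs <- data.frame(chrom = "chr1", start = c(4000L, 12000L),
                    end = c(4400L, 12400L))
  mp <- dhs_metaplot(me, groups = list(ctl = "a", trt = "b"), dhs,
                     control = "ctl")
  vals <- mp$profile$mean_methylation
  expect_true(all(abs(vals[!is.na(vals)] - 0.5) < 1e-12))
  expect_equal(mp$tests$p, 1)   # identical pairs

  st <- small_study()
  mp2 <- dhs_metaplot(st$meth, groups = list(control = "g9_r1",
                                             treated = "g1_r1"),
                      st$features$dhs, control = "control")
  expect_lt(mp2$tests$p, 0.05)
  prof <- mp2$profile
  body_t <- prof$mean_methylation[prof$group == "treated" & prof$zone == "body"]
  body_c <- prof$mean_methylation[prof$group == "control" & prof$zone == "body"]
  expect_gt(mean(body_t, na.rm = TRUE), mean(body_c, na.rm = TRUE))

  # reversing the pair order: complementary statistic, identical p
  mp3 <- dhs_metaplot(st$meth, groups = list(control = "g1_r1",
                                             treated = "g9_r1"),
                      st$features$dhs, control = "control")
  expect_equal(mp2$tests$p, mp3$tests$p, tolerance = 1e-12)
})
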