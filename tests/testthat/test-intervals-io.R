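test_that("overlap counts agree with an all-pairs scan", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  b <- data.frame(chrom = "chr1", start = 5L, end = 15L)
  expect_equal(unname(overlap_count(a, b)), c(1L, 1L))
  c_ <- data.frame(chrom = "chr1", start = 20L, end = 30L)
  expect_equal(unname(overlap_count(a, c_)), c(0L, 0L))
  # adjacent half-open intervals do not overlap
  d <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  expect_equal(unname(overlap_count(a, d)), c(0L, 0L))

  set.seed(23)
  ra <- rbind(random_regions(50, chrom = "chr1"),
              random_regions(50, chrom = "chr2"))
  rb <- rbind(random_regions(50, chrom = "chr1"),
              random_regions(50, chrom = "chr2"))
  expect_equal(unname(overlap_count(ra, rb)),
               c(sum(brute_overlaps_any(ra, rb)),
                 sum(brute_overlaps_any(rb, ra))))
})

test_that("the interval index equals a linear scan at scale", {
  set.seed(29)
  subject <- random_regions(10000, chrom_len = 1e6, min_w = 5, max_w = 200)
  query <- random_regions(1000, chrom_len = 1e6, min_w = 5, max_w = 200)
  got <- overlaps_any(query, subject)
  want <- brute_overlaps_any(query, subject)
  expect_identical(got, want)
})

test_that("peak overlap analysis uses the expanded DMRs", {
  dmrs <- data.frame(chrom = "chr1", start = 1000L, end = 1060L)
  peaks <- data.frame(chrom = "chr1", start = 1150L, end = 1200L)
  res <- peak_overlap_analysis(dmrs, peaks, c(chr1 = 1e5), flank = 100,
                               background = data.frame(chrom = "chr1",
                                                       start = 50000L,
                                                       end = 50060L))
  expect_equal(res$fraction, 1)    # expanded to [900, 1160) hits [1150, 1200)
  res0 <- peak_overlap_analysis(dmrs, peaks[0, ], c(chr1 = 1e5), flank = 100,
                                background = data.frame(chrom = "chr1",
                                                        start = 50000L,
                                                        end = 50060L))
  expect_equal(res0$fraction, 0)
})

test_that("BED round-trips and reports malformed lines by number", {
  set.seed(37)
  r <- random_regions(1000, chrom_len = 1e6)
  r$name <- paste0("iv", seq_len(nrow(r)))
  r$score <- round(runif(nrow(r)), 3)
  r$strand <- sample(c("+", "-", "."), nrow(r), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, path)
  back <- read_bed(path)
  expect_equal(back$chrom, r$chrom)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_equal(back$name, r$name)
  expect_equal(back$score, r$score)
  expect_equal(back$strand, r$strand)

  bad1 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t25"), bad1)
  expect_error(read_bed(bad1), "line 2.*greater than start")
  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# header", "chr1\t10\t20", "chr1\tx\t40"), bad2)
  expect_error(read_bed(bad2), "line 3.*non-numeric")
})

test_that("count tables round-trip through files and validate counts", {
  st <- small_study()
  sub <- st$meth[1:200, c("g1_r1", "g9_r1")]
  dir <- withr::local_tempdir()
  paths <- write_counts(sub, dir)
  expect_length(paths, 2)
  back <- read_methylome(paths, samples = c("g1_r1", "g9_r1"))
  expect_equal(back$sites$pos, sub$sites$pos)
  expect_equal(unname(back$M), unname(sub$M))
  expect_equal(unname(back$N), unname(sub$N))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tstrand\tcontext\tM\tN",
               "chr1\t10\t+\tCpG\t3\t8",
               "chr1\t20\t+\tCpG\t7\t5"), bad)
  expect_error(read_counts(bad), "line 3.*M > N")
})

test_that("bedGraph-dialect methylation tracks import as methylomes", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t102\t50\t5\t10",
               "chr1\t200\t202\t0\t0\t8"), path)
  me <- read_bedgraph_counts(path, sample = "x")
  expect_s3_class(me, "methylome")
  expect_equal(me$sites$pos, c(100L, 200L))
  expect_equal(unname(me$M[, 1]), c(5L, 0L))
})

test_that("supplementary-style DMR tables convert to 0-based coordinates", {
  # synthetic stand-in mimicking a published DMR list layout
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tlength\tnCpG\tmeanMethyl\tdirection",
               "chr1\t101\t180\t80\t6\t0.42\thyper",
               "chr2\t501\t540\t40\t4\t-0.21\thypo"), path)
  d <- read_dmr_table(path)
  expect_equal(d$start, c(100L, 500L))
  expect_equal(d$end, c(180L, 540L))
  expect_equal(d$nCpG, c(6L, 4L))
  expect_equal(d$direction, c("hyper", "hypo"))
  d1 <- read_dmr_table(path, one_based = FALSE)
  expect_equal(d1$start, c(101L, 501L))
})

test_that("FASTA, DMR-table and config output round-trip", {
  st <- small_study()
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(st$genome, fa)
  back <- read_fasta(fa)
  expect_equal(as.character(back), as.character(st$genome))

  dmrs <- call_dmrs(dmr_test(st$meth, "g1_r1", "g9_r1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dmrs(dmrs, tsv)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(dmrs))
  expect_equal(tab$direction, dmrs$direction)

  cfgp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- list(simulate = list(genome_length = 5e5, seed = 11),
              call = list(delta = 0.1, p = 0.01, min_cpg = 3, min_len = 10),
              filter = list(design = "uPA"))
  write_config(cfg, cfgp)
  expect_equal(read_config(cfgp), cfg)
})
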