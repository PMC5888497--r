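# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 0.5 Mb single-chromosome study for unit tests
small_study <- function() cached("small",
  simulate_study(genome_length = 5e5, n_chromosomes = 1, seed = 11))

# default-sized study for the acceptance suite
full_study <- function() cached("full", simulate_study(seed = 2024))

full_dmrs_upa <- function() cached("full_dmrs", {
  st <- full_study()
  call_dmrs(dmr_test(st$meth, "g1_r1", "g9_r1"))
})

# constructed methylome from explicit counts (single or multi sample)
make_methylome <- function(pos, M, N, chrom = "chr1") {
  if (is.vector(M)) M <- cbind(s1 = M)
  if (is.vector(N)) N <- cbind(s1 = N)
  colnames(N) <- colnames(M)
  methylome(data.frame(chrom = chrom, pos = as.integer(pos)), M, N)
}

# cpg_test_set rows built by hand for call_dmrs fixtures
make_tests <- function(pos, delta, p, chrom = "chr1") {
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    p1s = 0.5 + delta / 2, p2s = 0.5 - delta / 2,
                    delta = delta, z = sign(delta) * stats::qnorm(1 - p / 2),
                    p = p)
  class(out) <- c("cpg_test_set", "data.frame")
  out
}

# independent two-sided Fisher oracle: hypergeometric tail sum over tables
# no more probable than the observed one (same tolerance as fisher.test)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# brute-force both-strand motif scan (N is a wildcard), all offsets
brute_scan <- function(seqchr, pattern) {
  patv <- strsplit(pattern, "")[[1]]
  count_one <- function(s) {
    k <- length(patv); n <- nchar(s); cnt <- 0L
    if (n < k) return(0L)
    sv <- strsplit(s, "")[[1]]
    for (i in seq_len(n - k + 1)) {
      w <- sv[i:(i + k - 1)]
      if (all(patv == "N" | patv == w)) cnt <- cnt + 1L
    }
    cnt
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqchr)))
  count_one(seqchr) + count_one(rc)
}

# quadratic all-pairs overlap scan (0-based half-open)
brute_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, TRUE)
}

random_regions <- function(n, chrom_len = 1e5, min_w = 10, max_w = 500,
                           chrom = "chr1") {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(chrom_len - wi, 1), 0L)
  data.frame(chrom = chrom, start = s, end = s + w)
}
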