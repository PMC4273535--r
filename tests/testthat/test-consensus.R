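test_that("k-mer counting window arithmetic and canonicalisation contracts hold", {
  kt <- count_kmers("ACGTACGT", k = 4)
  expect_equal(sum(kt$count), 5)
  r <- "ACGGTAGCCATGAGATTCAGCCATG"
  both <- count_kmers(c(r, revcomp(r)), k = 11)
  single <- count_kmers(r, k = 11)
  m <- merge(both, single, by = "kmer")
  expect_equal(nrow(m), nrow(single))
  expect_equal(m$count.x, 2L * m$count.y)
  expect_warning(count_kmers(c("ACGT", r), k = 11), "skipped")
})

test_that("planted k-mers dominate error-free array reads", {
  set.seed(21)
  mono <- random_clean_monomer(60, 11)
  reads <- tiling_reads(mono, 40, 130)
  kt <- count_kmers(reads, k = 11)
  dbl <- paste0(mono, substr(mono, 1, 10))
  truth <- unique(canonical_kmer(substring(dbl, 1:60, 11:70)))
  expect_setequal(kt$kmer, truth)   # no spurious k-mers at zero error
  expect_equal(length(truth), 60)
})

test_that("noiseless walks recover planted monomers exactly up to rotation and strand", {
  set.seed(42)
  cases <- data.frame(L = sample(20:1000, 30, replace = TRUE))
  cases$k <- ifelse(cases$L <= 100, 11L, ifelse(cases$L <= 500, 17L, 25L))
  for (i in seq_len(nrow(cases))) {
    L <- cases$L[i]; k <- cases$k[i]
    mono <- random_clean_monomer(L, k)
    reads <- tiling_reads(mono, n_reads = max(10, ceiling(L / 15)),
                          read_len = L + k + 10)
    cm <- walk_consensus(count_kmers(reads, k = k))
    expect_true(cm$closed, info = paste("case", i, "L", L, "k", k))
    expect_equal(cm$length, L, info = paste("case", i))
    expect_equal(cm$sequence, canonical_rotation(mono), info = paste("case", i))
  }
})

test_that("walks stay open on non-repetitive input", {
  set.seed(3)
  lin <- random_dna_local(5000, 0.4)
  starts <- seq(1, 4800, by = 40)
  reads <- substring(lin, starts, starts + 199)
  cm <- walk_consensus(count_kmers(reads, k = 25))
  expect_false(cm$closed)
})

test_that("reconstruction is invariant to rotation and strand of the source array", {
  set.seed(9)
  mono <- random_clean_monomer(90, 11)
  variants <- list(mono,
                   paste0(substr(mono, 31, 90), substr(mono, 1, 30)),
                   revcomp(mono),
                   revcomp(paste0(substr(mono, 61, 90), substr(mono, 1, 60))))
  res <- lapply(variants, function(v) {
    walk_consensus(count_kmers(tiling_reads(v, 30, 140), k = 11))$sequence
  })
  expect_equal(res[[2]], res[[1]])
  expect_equal(res[[3]], res[[1]])
  expect_equal(res[[4]], res[[1]])
  expect_equal(res[[1]], canonical_rotation(mono))
})

test_that("noisy reads at >= 50x coverage still recover length and sequence", {
  set.seed(14)
  ok <- 0L
  n_runs <- 20L
  for (r in seq_len(n_runs)) {
    mono <- random_clean_monomer(200, 17)
    reads <- tiling_reads(mono, n_reads = 70, read_len = 250, error = 0.01,
                          seed = 100 + r)
    cm <- walk_consensus(count_kmers(reads, k = 17))
    if (cm$closed && abs(cm$length - 200) <= 1 &&
        pairwise_identity(cm$sequence, canonical_rotation(mono)) >= 99) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_runs, 0.95)
})

test_that("canonical rotation matches brute force and is idempotent", {
  # exhaustive oracle over all rotations of both strands
  brute <- function(s) {
    n <- nchar(s)
    cands <- character(0)
    for (str in c(s, revcomp(s))) {
      for (i in seq_len(n)) {
        cands <- c(cands, paste0(substr(str, i, n), substr(str, 1, i - 1)))
      }
    }
    min(cands)
  }
  expect_equal(canonical_rotation("GTAC"), brute("GTAC"))
  expect_equal(canonical_rotation("AAAA"), "AAAA")
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna_local(sample(5:40, 1))
    cr <- canonical_rotation(s)
    expect_equal(cr, brute(s))
    expect_equal(canonical_rotation(cr), cr)
  }
})

test_that("logo rows are exact for error-free reads and track error rates", {
  set.seed(6)
  mono <- random_clean_monomer(60, 11)
  reads <- tiling_reads(mono, 30, 100)
  cm <- walk_consensus(count_kmers(reads, k = 11))
  logo <- build_logo(cm, reads)
  expect_equal(nrow(logo), 60)
  rows <- as.matrix(logo[, c("fA", "fC", "fG", "fT")])
  expect_true(all(abs(rowSums(rows) - 1) < 1e-9))
  maxf <- apply(rows, 1, max)
  expect_true(all(maxf[!logo$uncovered] == 1))
  consensus_from_logo <- c("A", "C", "G", "T")[apply(rows, 1, which.max)]
  expect_equal(paste(consensus_from_logo, collapse = ""), cm$sequence)

  noisy <- tiling_reads(mono, 60, 100, error = 0.02, seed = 4)
  logo2 <- build_logo(cm, noisy)
  rows2 <- as.matrix(logo2[, c("fA", "fC", "fG", "fT")])
  mean_max <- mean(apply(rows2, 1, max))
  expect_gt(mean_max, 0.955)   # ~ 1 - 0.02 * 4/3, binomial noise around it
  expect_lt(mean_max, 0.995)
})

test_that("a planted 50/50 variant site shows up as a two-base logo row", {
  set.seed(8)
  mono <- random_clean_monomer(50, 11)
  alt <- mono
  base0 <- substr(mono, 25, 25)
  newb <- setdiff(c("A", "C", "G", "T"), base0)[1]
  substr(alt, 25, 25) <- newb
  reads <- c(tiling_reads(mono, 30, 80), tiling_reads(alt, 30, 80))
  logo <- build_logo(mono, reads)
  row <- as.numeric(logo[25, c("fA", "fC", "fG", "fT")])
  names(row) <- c("A", "C", "G", "T")
  expect_gt(row[base0], 0.4); expect_lt(row[base0], 0.6)
  expect_gt(row[newb], 0.4); expect_lt(row[newb], 0.6)
})

test_that("secondary monomers are recovered after the primary walk", {
  set.seed(12)
  m1 <- random_clean_monomer(80, 11)
  m2 <- random_clean_monomer(50, 11)
  reads <- c(tiling_reads(m1, 60, 120), tiling_reads(m2, 30, 90))
  monos <- walk_monomers(count_kmers(reads, k = 11), max_monomers = 3)
  expect_gte(length(monos), 2)
  lens <- vapply(monos, `[[`, integer(1), "length")
  expect_setequal(lens[1:2], c(80L, 50L))
})
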