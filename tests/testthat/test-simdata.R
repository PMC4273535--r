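test_that("zero-divergence genome layout places exact tandem blocks and a conserving truth table", {
  fam <- satellite_family("sat", monomer = strrep("ACGT", 10),
                          copies_per_1C = 100, locus_count = 1, divergence = 0)
  g <- build_genome(genome_spec(10000, list(fam), seed = 7))
  expect_equal(nchar(g$sequence), 10000)
  expect_true(grepl(strrep("ACGT", 100 * 10 / 4), g$sequence, fixed = TRUE))
  sat <- dplyr::filter(g$features, family == "sat")
  expect_equal(sum(sat$end - sat$start + 1), 4000)
  # conservation: footprints tile the genome exactly
  expect_equal(sum(g$features$end - g$features$start + 1), 10000)
  expect_equal(g$features$start[-1], g$features$end[-nrow(g$features)] + 1)

  # background-only genome
  g0 <- build_genome(genome_spec(5000, seed = 1))
  expect_equal(unique(g0$features$family), "background")
  expect_equal(nchar(g0$sequence), 5000)
})

test_that("multi-locus satellites split copies across the requested number of arrays", {
  fam <- satellite_family("sat", length = 50, copies_per_1C = 90,
                          locus_count = 3, divergence = 0)
  g <- build_genome(genome_spec(20000, list(fam), seed = 2))
  sat <- dplyr::filter(g$features, family == "sat")
  expect_equal(nrow(sat), 3)
  expect_equal(sum(sat$end - sat$start + 1), 90 * 50)
})

test_that("per-copy divergence produces the expected mean pairwise copy identity", {
  fam <- satellite_family("sat", length = 249, gc = 0.44, copies_per_1C = 40,
                          locus_count = 1, divergence = 0.02)
  g <- build_genome(genome_spec(30000, list(fam), seed = 11))
  arr <- dplyr::filter(g$features, family == "sat")
  block <- substr(g$sequence, arr$start, arr$end)
  copies <- substring(block, seq(1, 40 * 249, 249), seq(249, 40 * 249, 249))
  set.seed(5)
  pairs <- t(replicate(30, sample(40, 2)))
  ids <- apply(pairs, 1, function(p) {
    oracle_overlap_identity(copies[p[1]], copies[p[2]])
  })
  expect_gt(mean(ids), 94.5)
  expect_lt(mean(ids), 97.5)
})

test_that("capacity errors fire when repeats cannot fit the genome", {
  fam <- satellite_family("sat", length = 100, copies_per_1C = 200)
  expect_error(genome_spec(10000, list(fam)), "capacity")
})

test_that("shear_reads hits the coverage target with uniform starts and exact substrings", {
  fam <- satellite_family("sat", length = 200, copies_per_1C = 100,
                          divergence = 0)
  g <- build_genome(genome_spec(200000, list(fam), seed = 3))
  rs <- shear_reads(g, coverage_fraction = 0.5, read_length_mean = 350,
                    read_length_sd = 50, seed = 9)
  expect_equal(attr(rs, "total_bases"), sum(nchar(rs$sequence)))
  expect_lt(abs(attr(rs, "total_bases") - 0.5 * 200000), 600)
  # expected read count ~ coverage * G / mean length, within 5%
  expect_lt(abs(nrow(rs) - 0.5 * 200000 / 350) / (0.5 * 200000 / 350), 0.05)
  # error-free reads are exact substrings of the genome on one strand
  dbl <- g$sequence
  hit <- vapply(rs$sequence[1:25], function(s) {
    grepl(s, dbl, fixed = TRUE) || grepl(revcomp(s), dbl, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
})

test_that("shearing is deterministic under a fixed seed and warns at tiny coverage", {
  g <- build_genome(genome_spec(50000, seed = 4))
  a <- shear_reads(g, coverage_fraction = 0.1, seed = 42)
  b <- shear_reads(g, coverage_fraction = 0.1, seed = 42)
  expect_identical(a, b)
  expect_warning(shear_reads(g, coverage_fraction = 0.004, seed = 1),
                 "reads")
})

test_that("satellite-labelled reads inside an array match a rotation of the monomer array", {
  fam <- satellite_family("sat", length = 80, copies_per_1C = 100,
                          divergence = 0)
  g <- build_genome(genome_spec(30000, list(fam), seed = 8))
  rs <- shear_reads(g, coverage_fraction = 0.3, read_length_mean = 120,
                    read_length_sd = 10, seed = 2)
  arr <- dplyr::filter(g$features, family == "sat")
  inside <- rs$start >= arr$start & (rs$start + rs$length - 1) <= arr$end
  sat_reads <- rs$sequence[rs$true_family == "sat" & inside]
  expect_gt(length(sat_reads), 5)
  dbl <- strrep(g$monomers$sat, 4)
  ok <- vapply(sat_reads, function(s) {
    grepl(s, dbl, fixed = TRUE) || grepl(revcomp(s), dbl, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("quality filter applies length and N-fraction rules and recounts", {
  rs <- satkit:::as_read_set(tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c(strrep("A", 40), strrep("C", 350), strrep("G", 350))
  ))
  out <- quality_filter(rs, min_length = 50)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "total_reads"), 2)

  rs2 <- satkit:::as_read_set(tibble::tibble(
    id = c("a", "b"), sequence = c(strrep("A", 200),
                                   paste0(strrep("A", 199), "N"))
  ))
  expect_equal(nrow(quality_filter(rs2, min_length = 50, max_n_fraction = 0)), 1)
  # recount matches a direct recount on simulated reads
  g <- build_genome(genome_spec(50000, seed = 10))
  rs3 <- shear_reads(g, coverage_fraction = 0.2, read_length_mean = 120,
                     read_length_sd = 30, seed = 3)
  expect_equal(nrow(quality_filter(rs3, min_length = 100)),
               sum(nchar(rs3$sequence) >= 100))
  expect_error(quality_filter(rs2, min_length = 500), "every read")
})

test_that("slot-blot simulation is proportional when noiseless and has the stated CV when noisy", {
  tbl <- simulate_slot_blot(0.10, genomic_amounts_ng = 100,
                            standard_amounts_ng = c(1, 10), noise_cv = 0)
  expect_equal(tbl$signal[tbl$role == "sample"], 10)
  expect_equal(tbl$signal[tbl$role == "standard" & tbl$amount_ng == 10], 10)
  z <- simulate_slot_blot(0, noise_cv = 0)
  expect_true(all(z$signal[z$role == "sample"] == 0))
  # Monte-Carlo CV check
  sig <- vapply(1:1000, function(i) {
    simulate_slot_blot(0.5, genomic_amounts_ng = 10,
                       standard_amounts_ng = c(1, 2), noise_cv = 0.05,
                       seed = i)$signal[3]
  }, numeric(1))
  cv <- stats::sd(sig) / mean(sig)
  expect_gt(cv, 0.04); expect_lt(cv, 0.06)
})

test_that("genome build is byte-identical for identical specs and seeds", {
  fam <- satellite_family("sat", length = 60, copies_per_1C = 20,
                          divergence = 0.05, indel_rate = 0.01)
  s1 <- build_genome(genome_spec(20000, list(fam), seed = 77))
  s2 <- build_genome(genome_spec(20000, list(fam), seed = 77))
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$features, s2$features)
})
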