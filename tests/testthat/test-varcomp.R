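test_that("pairwise identity follows the ends-free convention and a DP oracle", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA", strand_normalize = FALSE), 75)
  expect_equal(pairwise_identity("ACGT", "TGCA"), 100)  # reverse complement
  # truncated clone against full monomer: overhang does not depress identity
  set.seed(3)
  full <- random_dna_local(120)
  trunc <- substr(full, 30, 90)
  expect_equal(pairwise_identity(trunc, full), 100)

  # oracle equivalence on mutated copies, the regime monomer comparison
  # lives in (random-vs-random pairs have many co-optimal alignments, where
  # tie-breaking rather than the alignment model decides the identity)
  for (i in 1:25) {
    a <- random_dna_local(sample(40:120, 1))
    ch <- strsplit(a, "")[[1]]
    hit <- which(stats::runif(length(ch)) < 0.1)
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    if (length(ch) > 45 && runif(1) < 0.5) ch <- ch[-sample(length(ch), 2)]
    b <- paste(ch, collapse = "")
    expect_equal(pairwise_identity(a, b, strand_normalize = FALSE),
                 oracle_overlap_identity(a, b),
                 tolerance = 1e-9, info = paste("pair", i))
  }
})

test_that("identity matrices are symmetric, bounded, with a 100 diagonal", {
  set.seed(8)
  seqs <- tibble::tibble(
    id = sprintf("s%d", 1:6),
    group = rep(c("g1", "g2"), each = 3),
    sequence = replicate(6, random_dna_local(80))
  )
  im <- identity_matrix(seqs)
  expect_true(isSymmetric(im$matrix))
  expect_true(all(diag(im$matrix) == 100))
  expect_true(all(im$matrix >= 0 & im$matrix <= 100))
})

test_that("rotation normalisation removes origin offsets before comparison", {
  set.seed(5)
  ref <- random_clean_monomer(100, 11)
  rot <- paste0(substr(ref, 41, 100), substr(ref, 1, 40))
  expect_equal(normalize_to_reference(rot, ref), ref)
  expect_equal(normalize_to_reference(revcomp(rot), ref), ref)
  # identity of rotated clones against the reference is restored to 100
  im <- identity_matrix(tibble::tibble(id = c("a", "b"), group = "g",
                                       sequence = c(ref, rot)),
                        reference = ref)
  expect_equal(im$matrix["a", "b"], 100)
})

test_that("group summaries separate within from between ranges", {
  g1 <- strrep("ACGTT", 20)
  g2ch <- strsplit(g1, "")[[1]]
  flip <- seq(3, 100, by = 10)   # 10 substitutions -> 90% identity
  for (i in flip) g2ch[i] <- setdiff(c("A", "C", "G", "T"), g2ch[i])[1]
  g2 <- paste(g2ch, collapse = "")
  seqs <- tibble::tibble(id = c("a1", "a2", "b1", "b2"),
                         group = c("A", "A", "B", "B"),
                         sequence = c(g1, g1, g2, g2))
  gs <- group_summary(identity_matrix(seqs, strand_normalize = FALSE))
  within <- gs[gs$type == "within", ]
  between <- gs[gs$type == "between", ]
  expect_true(all(within$min_identity == 100))
  expect_equal(between$min_identity, 90)
  expect_equal(between$max_identity, 90)

  # singleton group reports NA within-range
  seqs2 <- tibble::tibble(id = c("a1", "a2", "c1"),
                          group = c("A", "A", "C"),
                          sequence = c(g1, g1, g2))
  gs2 <- group_summary(identity_matrix(seqs2))
  expect_true(is.na(gs2$min_identity[gs2$group_a == "C" & gs2$type == "within"]))
})

test_that("shuffling group labels moves between-ranges but not the global extremes", {
  set.seed(13)
  seqs <- tibble::tibble(
    id = sprintf("s%d", 1:8),
    group = rep(c("A", "B"), each = 4),
    sequence = replicate(8, random_dna_local(60))
  )
  im <- identity_matrix(seqs, strand_normalize = FALSE)
  base <- group_summary(im)
  im_shuf <- im
  im_shuf$labels$group <- sample(im$labels$group)
  shuf <- group_summary(im_shuf)
  off <- im$matrix[upper.tri(im$matrix)]
  expect_equal(min(c(base$min_identity)), min(off))
  expect_equal(min(c(shuf$min_identity)), min(off))
  expect_equal(max(c(base$max_identity)), max(off))
})

test_that("distance export round-trips through PHYLIP and NEXUS", {
  set.seed(2)
  seqs <- tibble::tibble(id = sprintf("tax%d", 1:3), group = "g",
                         sequence = replicate(3, random_dna_local(50)))
  im <- identity_matrix(seqs)
  for (fmt in c("phylip", "nexus")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_distances(im, f, format = fmt)
    back <- read_distances(f, format = fmt)
    expect_equal(unname(diag(back)), rep(0, 3))
    expect_equal(unname(back), unname(100 - im$matrix), tolerance = 1e-6)
    expect_equal(rownames(back), im$labels$id)
  }
})

test_that("a 66-clone matrix exports NEXUS distances that reparse identically", {
  clones <- synthetic_clone_set(seed = 4)
  sub <- clones[seq(1, 66, by = 6), ]   # keep the runtime modest
  im <- identity_matrix(sub, reference = synthetic_monomer())
  f <- withr::local_tempfile(fileext = ".nex")
  export_distances(im, f, format = "nexus")
  back <- read_distances(f, format = "nexus")
  expect_equal(unname(back), unname(100 - im$matrix), tolerance = 1e-6)
})
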