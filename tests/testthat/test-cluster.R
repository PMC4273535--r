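make_read_set <- function(seqs, prefix = "r") {
  satkit:::as_read_set(tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_along(seqs)), sequence = seqs))
}

test_that("identical reads and reverse complements produce single full edges", {
  set.seed(1)
  s <- random_dna_local(350)
  rs <- make_read_set(c(s, s))
  e <- find_edges(rs)
  expect_equal(nrow(e), 1)
  expect_equal(e$identity_pct, 100)
  expect_equal(e$overlap_fraction, 1)

  rs2 <- make_read_set(c(s, revcomp(s)))
  e2 <- find_edges(rs2)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$identity_pct, 100)
})

test_that("seeded edge finding equals the all-pairs alignment route on two planted families", {
  set.seed(77)
  m1 <- random_dna_local(300, 0.45)
  m2 <- random_dna_local(300, 0.45)
  reads <- c(tiling_reads(m1, 20, 180, error = 0.02, seed = 1),
             tiling_reads(m2, 20, 180, error = 0.02, seed = 2))
  rs <- make_read_set(reads)
  seeded <- find_edges(rs)
  brute <- find_edges(rs, all_pairs = TRUE)
  expect_equal(seeded[order(seeded$read_a, seeded$read_b), ],
               brute[order(brute$read_a, brute$read_b), ])
  # no cross-family edges
  fam <- rep(c(1, 2), each = 20)
  ia <- as.integer(sub("r", "", seeded$read_a))
  ib <- as.integer(sub("r", "", seeded$read_b))
  expect_true(all(fam[ia] == fam[ib]))
})

test_that("connected components, sizes and proportions follow the edge list", {
  e <- tibble::tibble(read_a = c("r1", "r2"), read_b = c("r2", "r3"),
                      identity_pct = c(95, 95), overlap_fraction = c(1, 1))
  cl <- cluster_graph(e, 10)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3L)
  expect_equal(cl$proportion_pct, 30)
  expect_equal(sort(cl$read_ids[[1]]), c("r1", "r2", "r3"))

  empty <- cluster_graph(satkit:::empty_edges(), 10)
  expect_equal(nrow(empty), 0)
})

test_that("planted two-family simulation is recovered to >= 99% co-clustering", {
  fams <- list(satellite_family("satA", length = 150, copies_per_1C = 40,
                                divergence = 0.02),
               satellite_family("satB", length = 220, copies_per_1C = 30,
                                divergence = 0.02))
  g <- build_genome(genome_spec(30000, fams, seed = 5))
  rs <- shear_reads(g, coverage_fraction = 0.9, read_length_mean = 200,
                    read_length_sd = 20, substitution_error = 0.01, seed = 6)
  rs <- quality_filter(rs, min_length = 100)
  cl <- cluster_graph(find_edges(rs), rs)
  # map each cluster to its dominant truth family
  truth <- stats::setNames(rs$true_family, rs$id)
  repeat_reads <- rs$id[truth[rs$id] %in% c("satA", "satB")]
  correct <- 0L
  for (i in seq_len(nrow(cl))) {
    fams_in <- truth[cl$read_ids[[i]]]
    correct <- correct + max(table(fams_in))
  }
  expect_gte(correct / length(repeat_reads), 0.99)
  # conservation: cluster sizes + singletons = total reads
  singles <- nrow(rs) - sum(cl$size)
  expect_gte(singles, 0)
  expect_equal(sum(cl$size) + singles, nrow(rs))
})

test_that("cluster membership is invariant to read order and strand flips", {
  set.seed(10)
  m <- random_dna_local(200, 0.45)
  reads <- c(tiling_reads(m, 12, 150, error = 0.01, seed = 3),
             replicate(6, random_dna_local(150)))
  rs <- make_read_set(reads)
  base <- cluster_graph(find_edges(rs), rs)

  perm <- sample(nrow(rs))
  rs_perm <- satkit:::as_read_set(rs[perm, ])
  perm_cl <- cluster_graph(find_edges(rs_perm), rs_perm)
  expect_equal(lapply(base$read_ids, sort), lapply(perm_cl$read_ids, sort))

  flip <- rs
  idx <- c(2, 5, 9)
  flip$sequence[idx] <- revcomp(flip$sequence[idx])
  flip_cl <- cluster_graph(find_edges(satkit:::as_read_set(flip)), flip)
  expect_equal(lapply(base$read_ids, sort), lapply(flip_cl$read_ids, sort))
})

test_that("the proportion cut is strict at the boundary", {
  cl <- tibble::tibble(cluster_id = c("CL0001", "CL0002", "CL0003"),
                       size = c(2500L, 6L, 5L),
                       proportion_pct = 100 * c(2500, 6, 5) / 50000,
                       graph_density = 1,
                       read_ids = list("x", "y", "z"),
                       classification = "unclassified")
  class(cl) <- c("cluster_set", class(cl))
  kept <- top_clusters(cl, 0.01)
  expect_equal(kept$cluster_id, c("CL0001", "CL0002"))  # 0.01% exactly excluded

  three <- tibble::tibble(cluster_id = sprintf("CL%04d", 1:3),
                          size = c(500L, 50L, 1L),
                          proportion_pct = c(5, 0.5, 0.005),
                          graph_density = 1, read_ids = list("a", "b", "c"),
                          classification = "unclassified")
  class(three) <- c("cluster_set", class(three))
  expect_equal(nrow(top_clusters(three, 0.01)), 2)
})

test_that("graphml export writes a parseable graph", {
  e <- tibble::tibble(read_a = c("r1", "r2"), read_b = c("r2", "r3"),
                      identity_pct = c(95, 96), overlap_fraction = c(1, 1))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(e, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
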