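# All-vs-all read similarity graph and its connected-component clusters.
#
# Edge criterion: two reads are joined when their best local alignment (on
# either strand) reaches `min_identity_pct` identity over at least
# `min_overlap_fraction` of the shorter read. Candidate pairs are generated by
# shared-k-mer seeding before alignment; the contract is stated against an
# unseeded all-pairs aligner, so seeding must not lose edges.

#' Find similarity edges between reads
#'
#' @param reads A `read_set` tibble.
#' @param min_identity_pct Identity threshold over the aligned region (0-100).
#' @param min_overlap_fraction Minimum aligned length as a fraction of the
#'   shorter read.
#' @param seed_k Seeding k-mer length for candidate-pair generation. Two reads
#'   are aligned only if they share at least one canonical `seed_k`-mer; at
#'   the default 12 bp, overlaps at the identity threshold share a seed with
#'   overwhelming probability while unrelated reads rarely do.
#' @param all_pairs If `TRUE`, skip seeding and align every pair (the
#'   brute-force reference route; quadratic, for small inputs).
#' @return Tibble of class `similarity_edges`: `read_a`, `read_b` (with
#'   `read_a < read_b`), `identity_pct`, `overlap_fraction`.
#' @export
find_edges <- function(reads, min_identity_pct = 90, min_overlap_fraction = 0.55,
                       seed_k = 12, all_pairs = FALSE) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1,
            min_identity_pct > 0, min_identity_pct <= 100,
            min_overlap_fraction > 0, min_overlap_fraction <= 1)
  ids <- reads$id
  seqs <- stats::setNames(reads$sequence, ids)
  n <- length(ids)
  cand <- if (all_pairs || n <= 2) {
    if (n < 2) matrix(integer(0), ncol = 2) else t(utils::combn(n, 2L))
  } else {
    seed_candidates(seqs, seed_k)
  }
  if (nrow(cand) == 0) return(empty_edges())
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  dna <- Biostrings::DNAStringSet(seqs)
  dna_rc <- Biostrings::reverseComplement(dna)
  # vectorise over the alignment engine: one call per subject read, with all
  # of its candidate partners as patterns (both strands)
  rows <- vector("list", n)
  for (j in sort(unique(cand[, 2]))) {
    is <- cand[cand[, 2] == j, 1]
    fwd <- Biostrings::pairwiseAlignment(dna[is], dna[[j]], type = "local",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 2, gapExtension = 1)
    rev <- Biostrings::pairwiseAlignment(dna_rc[is], dna[[j]], type = "local",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 2, gapExtension = 1)
    use_fwd <- Biostrings::score(fwd) >= Biostrings::score(rev)
    len <- ifelse(use_fwd, Biostrings::nchar(fwd), Biostrings::nchar(rev))
    nm <- ifelse(use_fwd, Biostrings::nmatch(fwd), Biostrings::nmatch(rev))
    ident <- ifelse(len > 0, 100 * nm / len, 0)
    ovl <- pmin(1, len / pmin(nchar(seqs[is]), nchar(seqs[j])))
    keep <- len > 0 & ident >= min_identity_pct & ovl >= min_overlap_fraction
    if (any(keep)) {
      a <- ids[is[keep]]; b <- rep(ids[j], sum(keep))
      rows[[j]] <- tibble::tibble(read_a = pmin(a, b), read_b = pmax(a, b),
                                  identity_pct = ident[keep],
                                  overlap_fraction = unname(ovl[keep]))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_edges())
  out <- dplyr::distinct(dplyr::arrange(out, .data$read_a, .data$read_b),
                         .data$read_a, .data$read_b, .keep_all = TRUE)
  class(out) <- c("similarity_edges", class(out))
  out
}

empty_edges <- function() {
  out <- tibble::tibble(read_a = character(0), read_b = character(0),
                        identity_pct = numeric(0), overlap_fraction = numeric(0))
  class(out) <- c("similarity_edges", class(out))
  out
}

# candidate pairs sharing >= 1 canonical seed k-mer; returns 2-column index
# matrix with i < j (read x k-mer incidence crossproduct keeps this sparse)
seed_candidates <- function(seqs, seed_k) {
  n <- length(seqs)
  tabs <- lapply(seqs, function(s) unique(canonical_kmer(kmer_windows(s, seed_k))))
  all_kmers <- unique(unlist(tabs, use.names = FALSE))
  if (length(all_kmers) == 0) return(matrix(integer(0), ncol = 2))
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(tabs)),
    j = match(unlist(tabs, use.names = FALSE), all_kmers),
    x = 1, dims = c(n, length(all_kmers))
  )
  shared <- Matrix::tcrossprod(inc)
  hits <- Matrix::which(shared > 0, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  unname(hits)
}

#' Partition reads into repeat clusters
#'
#' Clusters are the connected components of the undirected similarity graph.
#' Singleton reads (no edges) are excluded from the cluster list but counted
#' in the genome-proportion denominator, which is the total
#' (quality-filtered) read count.
#'
#' @param edges A `similarity_edges` tibble from [find_edges()].
#' @param reads The `read_set` the edges were computed on (or a total read
#'   count).
#' @return A `cluster_set` tibble ordered by decreasing size: `cluster_id`
#'   (CL0001...), `size`, `proportion_pct`, `graph_density`, `read_ids`
#'   (list-column), `classification` (filled by [classify_clusters()]).
#' @export
cluster_graph <- function(edges, reads) {
  total_reads <- if (is.data.frame(reads)) nrow(reads) else as.integer(reads)
  stopifnot(total_reads > 0)
  if (nrow(edges) == 0) {
    out <- tibble::tibble(cluster_id = character(0), size = integer(0),
                          proportion_pct = numeric(0), graph_density = numeric(0),
                          read_ids = list(), classification = character(0))
    attr(out, "total_reads") <- total_reads
    class(out) <- c("cluster_set", class(out))
    return(out)
  }
  g <- igraph::graph_from_data_frame(edges[, c("read_a", "read_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  sizes <- lengths(memb)
  ord <- order(sizes, vapply(memb, min, character(1)), decreasing = c(TRUE, FALSE),
               method = "radix")
  memb <- memb[ord]; sizes <- sizes[ord]
  dens <- vapply(seq_along(memb), function(i) {
    sg <- igraph::induced_subgraph(g, memb[[i]])
    igraph::edge_density(sg)
  }, numeric(1))
  out <- tibble::tibble(
    cluster_id = sprintf("CL%04d", seq_along(memb)),
    size = as.integer(unname(sizes)),
    proportion_pct = unname(100 * sizes / total_reads),
    graph_density = dens,
    read_ids = lapply(memb, sort),
    classification = rep("unclassified", length(memb))
  )
  attr(out, "total_reads") <- total_reads
  attr(out, "graph") <- g
  class(out) <- c("cluster_set", class(out))
  out
}

#' Keep clusters above a genome-proportion cut
#'
#' Returns the clusters whose genome proportion strictly exceeds the cut
#' (a cluster sitting exactly at the threshold is excluded).
#'
#' @param clusters A `cluster_set` from [cluster_graph()].
#' @param min_cluster_proportion_pct Reporting cut in percent (default 0.01).
#' @return The filtered `cluster_set`.
#' @export
top_clusters <- function(clusters, min_cluster_proportion_pct = 0.01) {
  out <- dplyr::filter(clusters, .data$proportion_pct > min_cluster_proportion_pct)
  attr(out, "total_reads") <- attr(clusters, "total_reads")
  class(out) <- unique(c("cluster_set", class(out)))
  out
}

#' Export a cluster's similarity graph as GraphML
#'
#' @param edges A `similarity_edges` tibble.
#' @param path Output file path (.graphml).
#' @param read_ids Optional subset of read ids (e.g. one cluster's members).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path, read_ids = NULL) {
  e <- edges
  if (!is.null(read_ids)) {
    e <- dplyr::filter(e, .data$read_a %in% read_ids & .data$read_b %in% read_ids)
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
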