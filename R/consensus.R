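# Circular consensus monomer reconstruction by k-mer frequency walking.
#
# Reads from a tandem satellite cluster tile the circular monomer many times
# over, so the monomer's k-mers dominate the cluster's k-mer spectrum. A
# greedy walk over the most frequent k-mers reconstructs the monomer: it
# closes into a circle for a tandem repeat and stays open for anything else,
# which is also the backbone of the satellite classifier.

#' Count canonical k-mers of a read set
#'
#' Every k-window of every read is counted once under canonicalisation (a
#' k-mer and its reverse complement are the same key, keyed by the
#' lexicographically smaller of the two), making the spectrum strand-agnostic.
#'
#' @param reads A `read_set` tibble (or character vector of sequences).
#' @param k k-mer length (default 25).
#' @return A `kmer_table` tibble: `kmer` (canonical), `count`, sorted by
#'   decreasing count; attribute `k`.
#' @export
count_kmers <- function(reads, k = 25) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs), k >= 2)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k = ", k, " skipped")
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no reads of length >= k")
  km <- unlist(lapply(seqs, kmer_windows, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  km <- canonical_kmer(km)
  cnt <- sort(table(km), decreasing = TRUE)
  out <- tibble::tibble(kmer = names(cnt), count = as.integer(cnt))
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_table", class(out))
  out
}

#' Greedy k-mer walk to a circular consensus monomer
#'
#' Starts at the most frequent k-mer and repeatedly appends the base whose
#' successor k-mer has the highest count (ties broken by alphabetical order of
#' the appended base, for reproducibility). The walk terminates *closed* when
#' it re-enters its starting k-mer -- the reconstructed sequence is then a
#' circular monomer whose length equals the number of steps taken -- or *open*
#' when no successor reaches the count floor `max(2, floor_frac *
#' start_count)`. Closed monomers are reported in canonical rotation and
#' strand ([canonical_rotation()]).
#'
#' @param kmers A `kmer_table` from [count_kmers()].
#' @param floor_frac Successor-count floor as a fraction of the starting
#'   k-mer's count (default 0.01).
#' @param max_steps Safety cap on walk length.
#' @return A `consensus_monomer` list: `sequence`, `length`, `k`, `closed`,
#'   `start_kmer`, `start_count`, `canonical_rotation_applied`.
#' @export
walk_consensus <- function(kmers, floor_frac = 0.01, max_steps = 100000L) {
  walk_monomers(kmers, floor_frac = floor_frac, max_steps = max_steps,
                max_monomers = 1L)[[1]]
}

#' Walk out multiple monomers from one k-mer spectrum
#'
#' After a closed walk, the k-mers it consumed are removed and the walk
#' restarts on the remaining most frequent k-mer, provided its count is at
#' least `restart_frac` of the first start's count -- this surfaces secondary
#' satellites co-clustered with the primary one.
#'
#' @inheritParams walk_consensus
#' @param max_monomers Maximum number of monomers to extract.
#' @param restart_frac Restart threshold relative to the first start count.
#' @return List of `consensus_monomer` objects (first = primary).
#' @export
walk_monomers <- function(kmers, floor_frac = 0.01, max_steps = 100000L,
                          max_monomers = 3L, restart_frac = 0.10) {
  stopifnot(inherits(kmers, "kmer_table") || is.data.frame(kmers))
  if (nrow(kmers) == 0) stop("empty k-mer table")
  k <- attr(kmers, "k") %||% nchar(kmers$kmer[1])
  counts <- stats::setNames(kmers$count, kmers$kmer)
  first_start_count <- NULL
  out <- list()
  repeat {
    if (length(counts) == 0 || length(out) >= max_monomers) break
    top <- which.max(counts)
    if (!is.null(first_start_count) &&
        counts[top] < restart_frac * first_start_count) break
    mono <- walk_one(counts, names(counts)[top], k, floor_frac, max_steps)
    if (is.null(first_start_count)) first_start_count <- mono$start_count
    out[[length(out) + 1L]] <- mono
    if (!mono$closed) break
    counts <- counts[setdiff(names(counts), mono$used_kmers)]
  }
  lapply(out, function(m) { m$used_kmers <- NULL; m })
}

# one greedy walk from a given start k-mer over a named canonical count vector
walk_one <- function(counts, start, k, floor_frac, max_steps) {
  lookup <- function(km) {
    v <- counts[canonical_kmer(km)]
    ifelse(is.na(v), 0L, v)
  }
  start_count <- unname(lookup(start))
  floor_cnt <- max(2, floor_frac * start_count)
  cur <- start
  appended <- character(0)
  used <- canonical_kmer(start)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(start, TRUE, envir = visited)
  closed <- FALSE
  for (step in seq_len(max_steps)) {
    succ <- paste0(substr(cur, 2L, k), DNA_BASES)
    sc <- lookup(succ)
    if (max(sc) < floor_cnt) break
    best <- which.max(sc)  # which.max takes the first maximum: A < C < G < T
    nxt <- succ[best]
    appended <- c(appended, DNA_BASES[best])
    if (nxt == start) { closed <- TRUE; break }
    if (exists(nxt, envir = visited, inherits = FALSE)) break # cycle avoiding start
    assign(nxt, TRUE, envir = visited)
    used <- c(used, canonical_kmer(nxt))
    cur <- nxt
  }
  if (closed) {
    seq_out <- paste(appended, collapse = "")
    L <- nchar(seq_out)
    canon <- if (L > 0) canonical_rotation(seq_out) else seq_out
    structure(list(sequence = canon, length = L, k = k, closed = TRUE,
                   start_kmer = start, start_count = start_count,
                   canonical_rotation_applied = TRUE, used_kmers = used),
              class = "consensus_monomer")
  } else {
    contig <- paste0(start, paste(appended, collapse = ""))
    structure(list(sequence = contig, length = nchar(contig), k = k,
                   closed = FALSE, start_kmer = start,
                   start_count = start_count,
                   canonical_rotation_applied = FALSE, used_kmers = used),
              class = "consensus_monomer")
  }
}

#' @export
print.consensus_monomer <- function(x, ...) {
  cat("<consensus_monomer> ", if (x$closed) "closed circular" else "open",
      ", length ", x$length, " bp, k = ", x$k, "\n", sep = "")
  cat(substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-position base-frequency profile (sequence logo) of a monomer
#'
#' Aligns each cluster read (better strand of the two) to a concatenation of
#' monomer copies long enough to hold a full read, and tallies the base each
#' read carries at every circular monomer position. Rows are normalised to
#' sum to 1; positions with no coverage are flagged and given a uniform row.
#'
#' @param monomer A closed `consensus_monomer` (or a plain monomer string).
#' @param reads A `read_set` tibble or character vector of read sequences.
#' @return A `consensus_logo` tibble: `position` (1-based circular), `fA`,
#'   `fC`, `fG`, `fT`, `coverage`, `uncovered`.
#' @export
build_logo <- function(monomer, reads) {
  mono <- if (inherits(monomer, "consensus_monomer")) {
    if (!monomer$closed) stop("logo requires a closed monomer")
    monomer$sequence
  } else toupper(monomer)
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  L <- nchar(mono)
  n_rep <- max(2L, ceiling(max(nchar(seqs)) / L) + 1L)
  subject <- Biostrings::DNAString(paste(rep(mono, n_rep), collapse = ""))
  counts <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  dna <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::pairwiseAlignment(dna, subject, type = "global-local")
  rev <- Biostrings::pairwiseAlignment(Biostrings::reverseComplement(dna),
                                       subject, type = "global-local")
  use_fwd <- Biostrings::score(fwd) >= Biostrings::score(rev)
  for (i in seq_along(seqs)) {
    aln <- if (use_fwd[i]) fwd[i] else rev[i]
    pat <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    sub <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    pos0 <- Biostrings::start(Biostrings::subject(aln))
    # subject position of each column: advance only on non-gap subject chars
    spos <- pos0 - 1L + cumsum(sub != "-")
    keep <- sub != "-" & pat %in% DNA_BASES
    circ <- ((spos[keep] - 1L) %% L) + 1L
    for (bb in DNA_BASES) {
      sel <- circ[pat[keep] == bb]
      if (length(sel)) {
        tb <- tabulate(sel, nbins = L)
        counts[, bb] <- counts[, bb] + tb
      }
    }
  }
  cov <- rowSums(counts)
  freq <- counts
  freq[cov > 0, ] <- counts[cov > 0, , drop = FALSE] / cov[cov > 0]
  freq[cov == 0, ] <- 0.25
  out <- tibble::tibble(position = seq_len(L),
                        fA = freq[, "A"], fC = freq[, "C"],
                        fG = freq[, "G"], fT = freq[, "T"],
                        coverage = cov, uncovered = cov == 0)
  class(out) <- c("consensus_logo", class(out))
  out
}
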