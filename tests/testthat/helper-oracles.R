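# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check: plain dynamic
# programming, exhaustive rotation scans, and sliding-window loops.

# ends-free global alignment identity by dynamic programming (linear gap
# penalty; free leading/trailing gaps), returning percent identity over the
# aligned columns between the first and last aligned pair. O(nm); short
# sequences only.
oracle_overlap_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up, 3 left
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      cand <- c(H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
      w <- which.max(cand)
      H[i + 1, j + 1] <- cand[w]; P[i + 1, j + 1] <- w
    }
  }
  # best end on last row or column (free trailing gaps)
  ends <- rbind(cbind(n + 1, seq_len(m + 1)), cbind(seq_len(n + 1), m + 1))
  best <- ends[which.max(H[ends]), ]
  i <- best[1]; j <- best[2]
  matches <- 0L; cols <- 0L
  while (i > 1 && j > 1) {
    if (P[i, j] == 1L) {
      cols <- cols + 1L
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (P[i, j] == 2L) {
      cols <- cols + 1L; i <- i - 1
    } else {
      cols <- cols + 1L; j <- j - 1
    }
  }
  if (cols == 0) return(0)
  100 * matches / cols
}

# exhaustive circular motif count: test every rotation start once
oracle_circular_count <- function(s, motif, max_mismatch = 0) {
  L <- nchar(s); w <- nchar(motif)
  dbl <- paste0(s, s)
  mv <- strsplit(motif, "")[[1]]
  hits <- 0L
  for (p in seq_len(L)) {
    win <- strsplit(substr(dbl, p, p + w - 1), "")[[1]]
    if (sum(win != mv) <= max_mismatch) hits <- hits + 1L
  }
  hits
}

# sliding-window IUPAC match positions (linear, top strand)
oracle_iupac_positions <- function(s, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A","G"),
               Y = c("C","T"), S = c("G","C"), W = c("A","T"), K = c("G","T"),
               M = c("A","C"), B = c("C","G","T"), D = c("A","G","T"),
               H = c("A","C","T"), V = c("A","C","G"), N = c("A","C","G","T"))
  p <- strsplit(toupper(pattern), "")[[1]]
  ch <- strsplit(toupper(s), "")[[1]]
  L <- length(ch); w <- length(p)
  out <- integer(0)
  for (i in seq_len(L - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(ch[i + j - 1] %in% sets[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# brute-force primary period by circular autocorrelation: smallest lag with
# >= frac exact position matches
oracle_autocorr_period <- function(s, frac = 0.9) {
  ch <- strsplit(toupper(s), "")[[1]]
  L <- length(ch)
  for (lag in 1:(L - 1)) {
    span <- L - lag
    if (mean(ch[1:span] == ch[(1:span) + lag]) >= frac) return(lag)
  }
  NA_integer_
}

# reads tiling a circular monomer: evenly spaced starts over the doubled
# array, optional per-base substitution error; strands alternate
tiling_reads <- function(monomer, n_reads, read_len, error = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(monomer)
  arr <- paste(rep(monomer, ceiling(read_len / L) + 2), collapse = "")
  starts <- (round(seq(0, by = max(1, floor(L / n_reads) + 1), length.out = n_reads)) %% L) + 1
  reads <- substring(arr, starts, starts + read_len - 1)
  if (error > 0) {
    reads <- vapply(reads, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < error)
      for (i in hit) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  flip <- seq_along(reads) %% 2 == 0
  reads[flip] <- revcomp(reads[flip])
  reads
}

# random monomer that avoids repeated canonical k-mers (so the circular
# sequence is reconstructable at that k)
random_clean_monomer <- function(L, k, gc = 0.5, max_tries = 50) {
  for (t in seq_len(max_tries)) {
    m <- random_dna_local(L, gc)
    dbl <- paste0(m, substr(m, 1, k - 1))
    kms <- substring(dbl, 1:L, 1:L + k - 1)
    rc <- revcomp(kms)
    canon <- ifelse(kms <= rc, kms, rc)
    if (!anyDuplicated(canon)) return(m)
  }
  stop("could not generate a clean monomer")
}

random_dna_local <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# simulate one cluster's reads from a tandem array genome (satellite) or a
# multi-locus dispersed element; returns character vector of read sequences
simulate_cluster_reads <- function(kind = c("satellite", "dispersed"),
                                   monomer_len = 120, copies = 60,
                                   element_len = 2500, n_loci = 8,
                                   read_len = 150, coverage = 60,
                                   error = 0.005, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "satellite") {
    fam <- satellite_family("sat", length = monomer_len, gc = 0.45,
                            copies_per_1C = copies, divergence = 0.01)
    footprint <- monomer_len * copies
    gsize <- footprint * 2
    spec <- genome_spec(gsize, list(fam), background_gc = 0.4, seed = seed)
    n_target_bases <- coverage * monomer_len
  } else {
    fam <- dispersed_family("disp", element_length = element_len,
                            copies = n_loci, divergence = 0.01)
    footprint <- element_len * n_loci
    gsize <- footprint * 2
    spec <- genome_spec(gsize, dispersed_families = list(fam),
                        background_gc = 0.4, seed = seed)
    n_target_bases <- coverage * element_len / 4
  }
  g <- build_genome(spec)
  rs <- shear_reads(g, coverage_fraction = min(0.9, n_target_bases / gsize),
                    read_length_mean = read_len, read_length_sd = read_len / 10,
                    substitution_error = error, seed = seed + 1)
  rs$sequence[rs$true_family != "background"]
}
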