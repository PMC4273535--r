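# Pairwise monomer comparison: global alignment with free end gaps, identity
# matrices with within/between-group ranges, and distance-matrix export for
# external split-network and phylogeny software.

#' Pairwise identity of two monomer sequences
#'
#' Global alignment with free end gaps (ends-free), unit scoring (match +1,
#' mismatch -1, gap open -2, gap extend -1). Identity is matches divided by
#' alignment columns excluding the terminal overhangs, so a truncated clone
#' compares sensibly against a full-length monomer. With
#' `strand_normalize = TRUE` the better-scoring strand of `seq_b` is used.
#'
#' @param seq_a,seq_b DNA strings.
#' @param strand_normalize Compare against both strands of `seq_b`.
#' @return Identity in percent (0-100).
#' @export
pairwise_identity <- function(seq_a, seq_b, strand_normalize = TRUE) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  cand <- c(toupper(seq_b), if (strand_normalize) revcomp(seq_b))
  best <- -Inf; best_pid <- 0
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (b in cand) {
    # linear gap cost of 2 per gapped base (opening 0): the unit-scoring
    # convention stated for monomer comparison
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(seq_a)),
                                         Biostrings::DNAString(b),
                                         type = "overlap",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 0, gapExtension = 2)
    if (Biostrings::score(aln) > best) {
      best <- Biostrings::score(aln)
      len <- Biostrings::nchar(aln)    # columns of the trimmed (ends-free) region
      best_pid <- if (len > 0) 100 * Biostrings::nmatch(aln) / len else 0
    }
  }
  best_pid
}

#' Rotate and strand-normalise a monomer against a reference
#'
#' Circular monomers cloned at arbitrary origins must be re-phased before
#' comparison, or origin offsets masquerade as divergence. The sequence is
#' aligned (both strands) to a doubled copy of the reference; the winning
#' strand is rotated so it starts at the position matching the reference
#' origin.
#'
#' @param sequence Monomer string (possibly rotated/reversed).
#' @param reference Reference monomer string.
#' @return The normalised sequence string.
#' @export
normalize_to_reference <- function(sequence, reference) {
  s <- toupper(sequence); ref <- toupper(reference)
  dbl <- Biostrings::DNAString(paste0(ref, ref))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL; best_score <- -Inf
  for (cand in c(s, revcomp(s))) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(cand), dbl,
                                         type = "global-local",
                                         substitutionMatrix = sub_mat,
                                         gapOpening = 2, gapExtension = 1)
    if (Biostrings::score(aln) > best_score) {
      best_score <- Biostrings::score(aln)
      L <- nchar(ref); n <- nchar(cand)
      off <- ((Biostrings::start(Biostrings::subject(aln)) - 1L) %% L)
      # the clone wraps the reference origin iff it extends past position L;
      # rotate so the base aligned to the reference origin comes first
      best <- if (off == 0L || off + n <= L) cand else {
        k <- L - off
        paste0(substr(cand, k + 1L, n), substr(cand, 1L, k))
      }
    }
  }
  best
}

#' Pairwise identity matrix of grouped monomer sequences
#'
#' @param seqs A data frame with columns `id`, `group`, `sequence`, or a
#'   named character vector (names "id|group").
#' @param reference Optional reference monomer; when given, every sequence is
#'   first rotation/strand-normalised against it
#'   ([normalize_to_reference()]).
#' @param strand_normalize Passed to [pairwise_identity()].
#' @return An `identity_matrix` object: symmetric percent-identity `matrix`
#'   (diagonal 100) with `labels` tibble (`id`, `group`).
#' @export
identity_matrix <- function(seqs, reference = NULL, strand_normalize = TRUE) {
  if (is.character(seqs)) {
    parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 2)
    seqs <- tibble::tibble(id = parts[, 1],
                           group = ifelse(parts[, 2] == "", NA, parts[, 2]),
                           sequence = unname(seqs))
  }
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  if (!"group" %in% names(seqs)) seqs$group <- NA_character_
  if (anyDuplicated(seqs$id)) stop("sequence ids must be unique")
  ss <- seqs$sequence
  if (!is.null(reference)) {
    ss <- vapply(ss, normalize_to_reference, character(1), reference = reference,
                 USE.NAMES = FALSE)
  }
  n <- length(ss)
  m <- matrix(100, n, n, dimnames = list(seqs$id, seqs$id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(ss[i], ss[j],
                                                strand_normalize = strand_normalize)
      }
    }
  }
  structure(list(matrix = m,
                 labels = tibble::tibble(id = seqs$id, group = seqs$group)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat("<identity_matrix> ", nrow(x$matrix), " sequences",
      if (length(off)) paste0(", identities ", round(min(off), 1), "-",
                              round(max(off), 1), "%"), "\n", sep = "")
  invisible(x)
}

#' Within- and between-group identity ranges
#'
#' Summarises an identity matrix per group pair: the minimum and maximum
#' pairwise identity within each group and between each pair of groups.
#' Singleton groups get an NA within-group range.
#'
#' @param im An `identity_matrix`.
#' @return Tibble: `group_a`, `group_b`, `type` ("within"/"between"),
#'   `min_identity`, `max_identity`, `n_pairs`.
#' @export
group_summary <- function(im) {
  stopifnot(inherits(im, "identity_matrix"))
  lab <- im$labels
  groups <- unique(lab$group)
  rows <- list()
  for (a in seq_along(groups)) {
    for (b in a:length(groups)) {
      ia <- which(lab$group == groups[a]); ib <- which(lab$group == groups[b])
      if (a == b) {
        if (length(ia) < 2) {
          vals <- numeric(0)
        } else {
          sub <- im$matrix[ia, ia, drop = FALSE]
          vals <- sub[upper.tri(sub)]
        }
        type <- "within"
      } else {
        vals <- as.vector(im$matrix[ia, ib])
        type <- "between"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_a = groups[a], group_b = groups[b], type = type,
        min_identity = if (length(vals)) min(vals) else NA_real_,
        max_identity = if (length(vals)) max(vals) else NA_real_,
        n_pairs = length(vals)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Export an identity matrix as distances for external software
#'
#' Distance = 100 - identity, written as a PHYLIP square distance matrix or a
#' NEXUS DISTANCES block, the inputs split-network and phylogeny tools read.
#' Labels are sanitised to alphanumerics/underscore (with a warning) where
#' the format demands it.
#'
#' @param im An `identity_matrix`.
#' @param path Output file.
#' @param format "phylip" or "nexus".
#' @return `path`, invisibly.
#' @seealso [read_distances()]
#' @export
export_distances <- function(im, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  d <- 100 - im$matrix
  diag(d) <- 0
  labs <- rownames(d)
  clean <- gsub("[^A-Za-z0-9_.]", "_", labs)
  if (!identical(clean, labs)) {
    warning("labels sanitised for ", format, " export")
  }
  clean <- make.unique(clean, sep = "_")
  n <- nrow(d)
  if (format == "phylip") {
    lines <- c(sprintf("%5d", n),
               vapply(seq_len(n), function(i) {
                 paste0(formatC(clean[i], width = -12),
                        paste(sprintf("%.6f", d[i, ]), collapse = " "))
               }, character(1)))
  } else {
    lines <- c("#NEXUS", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", n),
               paste0("  TAXLABELS ", paste(clean, collapse = " "), ";"),
               "END;",
               "BEGIN DISTANCES;",
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
               "  MATRIX",
               vapply(seq_len(n), function(i) {
                 paste0("    ", formatC(clean[i], width = -12),
                        paste(sprintf("%.6f", d[i, ]), collapse = " "))
               }, character(1)),
               "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a distance matrix written by [export_distances()]
#'
#' @param path File path.
#' @param format "phylip" or "nexus".
#' @return A numeric distance matrix with taxon labels.
#' @export
read_distances <- function(path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "phylip") {
    n <- as.integer(trimws(lines[1]))
    body <- lines[2:(n + 1)]
  } else {
    i0 <- grep("^\\s*MATRIX\\s*$", lines)[1]
    i1 <- grep("^\\s*;\\s*$", lines)
    i1 <- i1[i1 > i0][1]
    body <- lines[(i0 + 1):(i1 - 1)]
    n <- length(body)
  }
  parts <- strsplit(trimws(body), "\\s+")
  labs <- vapply(parts, `[`, character(1), 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}
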