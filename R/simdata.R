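# Synthetic-data generator: genomes carrying tandem satellite arrays,
# dispersed repeat families and single-copy background; 454-style single-end
# shearing; quality filtering; slot-blot signal tables. Everything is seeded
# and deterministic so downstream stages are testable without external data.

#' Describe a tandem satellite family
#'
#' A satellite family is defined by its monomer (given explicitly or generated
#' at random with a target GC), the number of head-to-tail copies per 1C
#' genome, how many separate arrays (loci) those copies are split across, and
#' the per-copy mutation load.
#'
#' @param name Family label.
#' @param monomer Monomer sequence; if `NULL` a random monomer of `length` bp
#'   and GC fraction `gc` is generated when the genome is built.
#' @param length,gc Used only when `monomer` is `NULL` (defaults 249 bp, 0.44).
#' @param copies_per_1C Total monomer copies in the genome.
#' @param locus_count Number of contiguous arrays the copies are split across.
#' @param divergence Per-base substitution probability applied independently
#'   to each copy, in \[0, 0.2\].
#' @param indel_rate Per-base indel probability per copy, in \[0, 0.02\].
#' @return A `satellite_family` list.
#' @export
satellite_family <- function(name, monomer = NULL, length = 249, gc = 0.44,
                             copies_per_1C = 100, locus_count = 1,
                             divergence = 0, indel_rate = 0) {
  stopifnot(copies_per_1C >= 0, locus_count >= 1,
            divergence >= 0, divergence <= 0.2,
            indel_rate >= 0, indel_rate <= 0.02)
  if (!is.null(monomer)) {
    monomer <- toupper(monomer)
    if (nchar(monomer) < 20) stop("monomer length must be >= 20 bp")
  } else if (length < 20) {
    stop("monomer length must be >= 20 bp")
  }
  structure(list(name = name, monomer = monomer, length = length, gc = gc,
                 copies_per_1C = as.integer(copies_per_1C),
                 locus_count = as.integer(locus_count),
                 divergence = divergence, indel_rate = indel_rate),
            class = "satellite_family")
}

#' Describe a dispersed repeat family
#'
#' Copies of a dispersed element (transposon-like) are scattered individually
#' across the genome rather than arrayed in tandem.
#'
#' @param name Family label.
#' @param element_length Element length in bp (random element generated once).
#' @param copies Number of dispersed copies.
#' @param divergence Per-base substitution probability per copy.
#' @param gc GC fraction of the generated element.
#' @return A `dispersed_family` list.
#' @export
dispersed_family <- function(name, element_length = 5000, copies = 50,
                             divergence = 0, gc = 0.4) {
  stopifnot(element_length >= 50, copies >= 1, divergence >= 0, divergence <= 0.2)
  structure(list(name = name, element_length = as.integer(element_length),
                 copies = as.integer(copies), divergence = divergence, gc = gc),
            class = "dispersed_family")
}

#' Specify a synthetic genome
#'
#' @param genome_size_bp Total genome length (1C) in bp.
#' @param satellite_families List of [satellite_family()] objects.
#' @param dispersed_families List of [dispersed_family()] objects.
#' @param background_gc GC fraction of the single-copy background.
#' @param seed Integer seed; a fixed seed gives a byte-identical genome.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_size_bp, satellite_families = list(),
                        dispersed_families = list(), background_gc = 0.38,
                        seed = 1L) {
  stopifnot(genome_size_bp > 0, background_gc >= 0, background_gc <= 1)
  if (inherits(satellite_families, "satellite_family")) {
    satellite_families <- list(satellite_families)
  }
  if (inherits(dispersed_families, "dispersed_family")) {
    dispersed_families <- list(dispersed_families)
  }
  spec <- structure(list(genome_size_bp = as.integer(genome_size_bp),
                         satellite_families = satellite_families,
                         dispersed_families = dispersed_families,
                         background_gc = background_gc, seed = as.integer(seed)),
                    class = "genome_spec")
  foot <- sum(vapply(satellite_families, function(f) {
    f$copies_per_1C * (if (is.null(f$monomer)) f$length else nchar(f$monomer))
  }, numeric(1))) +
    sum(vapply(dispersed_families,
               function(f) as.numeric(f$copies) * f$element_length, numeric(1)))
  if (foot > genome_size_bp) {
    stop("capacity error: repeat family footprint (", foot,
         " bp) exceeds genome size (", genome_size_bp, " bp)")
  }
  spec
}

#' Build a synthetic genome with a position-level truth table
#'
#' Lays out each satellite family as `locus_count` contiguous head-to-tail
#' arrays of independently mutated monomer copies, scatters dispersed-element
#' copies, and fills the remainder with random background. Feature placement
#' is random but non-overlapping; the truth table records every feature
#' interval so each genome position maps to exactly one family (or
#' "background").
#'
#' @param spec A [genome_spec()].
#' @return A `sim_genome` list: `sequence` (single string), `features`
#'   (tibble: `start`, `end`, 1-based inclusive; `family`; `kind`), `spec`,
#'   and `monomers` (named list of the realised satellite monomer sequences).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  blocks <- list()   # list of (sequence, family, kind)
  monomers <- list()
  for (f in spec$satellite_families) {
    mono <- f$monomer %||% random_dna(f$length, f$gc)
    monomers[[f$name]] <- mono
    copies_per_locus <- diff(round(seq(0, f$copies_per_1C,
                                       length.out = f$locus_count + 1L)))
    for (nc in copies_per_locus) {
      if (nc == 0L) next
      arr <- vapply(seq_len(nc), function(i) {
        mutate_sequence(mono, f$divergence, f$indel_rate)
      }, character(1))
      blocks[[length(blocks) + 1L]] <-
        list(seq = paste(arr, collapse = ""), family = f$name, kind = "satellite")
    }
  }
  for (f in spec$dispersed_families) {
    elem <- random_dna(f$element_length, f$gc)
    monomers[[f$name]] <- elem
    for (i in seq_len(f$copies)) {
      blocks[[length(blocks) + 1L]] <-
        list(seq = mutate_sequence(elem, f$divergence, 0), family = f$name,
             kind = "dispersed")
    }
  }

  block_len <- vapply(blocks, function(b) nchar(b$seq), numeric(1))
  bg_total <- spec$genome_size_bp - sum(block_len)
  if (bg_total < 0) {
    stop("capacity error: realised repeat footprint exceeds genome size ",
         "(indels inflated the arrays); reduce copies or indel_rate")
  }
  nb <- length(blocks)
  if (nb > 0) blocks <- blocks[sample.int(nb)]
  # split background into nb + 1 gaps (some may be empty)
  if (nb > 0) {
    cuts <- sort(sample.int(bg_total + 1L, nb, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, bg_total))
  } else {
    gaps <- bg_total
  }
  pieces <- character(0); fam <- character(0); kind <- character(0)
  for (i in seq_along(gaps)) {
    if (gaps[i] > 0) {
      pieces <- c(pieces, random_dna(gaps[i], spec$background_gc))
      fam <- c(fam, "background"); kind <- c(kind, "background")
    }
    if (i <= nb) {
      pieces <- c(pieces, blocks[[i]]$seq)
      fam <- c(fam, blocks[[i]]$family); kind <- c(kind, blocks[[i]]$kind)
    }
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  features <- tibble::tibble(start = ends - lens + 1L, end = ends,
                             family = fam, kind = kind)
  structure(list(sequence = paste(pieces, collapse = ""),
                 features = features, spec = spec, monomers = monomers),
            class = "sim_genome")
}

#' Shear a genome into 454-like single-end reads
#'
#' Reads are drawn with uniform start positions and normal lengths (truncated
#' at 50 bp and at the genome end is avoided by requiring reads to lie fully
#' inside the genome), on a random strand, until the target base count
#' `coverage_fraction * genome length` is reached. Per-base substitution
#' errors and optional homopolymer length errors are then applied. Each read
#' carries a truth label: the family owning the majority of its footprint.
#'
#' @param genome A `sim_genome` from [build_genome()] (or a plain string, in
#'   which case all truth labels are `NA`).
#' @param coverage_fraction Target fraction of the genome covered by read
#'   bases (e.g. 0.022).
#' @param read_length_mean,read_length_sd Normal read-length model in bp.
#' @param substitution_error Per-base substitution error rate.
#' @param homopolymer_indel_error Per-homopolymer probability of a +/-1
#'   length error (454-style; default 0 = off).
#' @param seed Integer seed.
#' @return A `read_set` tibble: `id`, `sequence`, `length`, `true_family`,
#'   `strand`, `start`; attributes `total_reads`, `total_bases`, `provenance`.
#' @export
shear_reads <- function(genome, coverage_fraction = 0.022,
                        read_length_mean = 350, read_length_sd = 50,
                        substitution_error = 0, homopolymer_indel_error = 0,
                        seed = 1L) {
  stopifnot(coverage_fraction > 0, read_length_mean >= 50)
  gseq <- if (inherits(genome, "sim_genome")) genome$sequence else toupper(genome)
  feats <- if (inherits(genome, "sim_genome")) genome$features else NULL
  glen <- nchar(gseq)
  if (glen == 0) stop("genome is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  target <- coverage_fraction * glen
  n_guess <- max(1L, ceiling(target / read_length_mean * 1.2))
  lens <- integer(0); starts <- integer(0)
  repeat {
    l <- round(stats::rnorm(n_guess, read_length_mean, read_length_sd))
    l <- pmax(50L, pmin(as.integer(l), glen))
    s <- as.integer(floor(stats::runif(n_guess, 1, glen - l + 2)))
    lens <- c(lens, l); starts <- c(starts, s)
    cum <- cumsum(as.numeric(lens))
    if (cum[length(cum)] >= target) {
      # stop at the first read crossing the target: total bases within one read
      nkeep <- which(cum >= target)[1]
      lens <- lens[seq_len(nkeep)]; starts <- starts[seq_len(nkeep)]
      break
    }
  }
  n <- length(lens)
  if (n < 10) warning("coverage so low that only ", n, " reads were produced")

  raw <- substring(gseq, starts, starts + lens - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  raw[strand == "-"] <- revcomp(raw[strand == "-"])
  if (substitution_error > 0 || homopolymer_indel_error > 0) {
    raw <- vapply(raw, function(s) {
      s <- mutate_sequence(s, substitution_error, 0)
      if (homopolymer_indel_error > 0) s <- homopolymer_errors(s, homopolymer_indel_error)
      s
    }, character(1), USE.NAMES = FALSE)
  }
  true_family <- if (!is.null(feats)) {
    majority_family(feats, starts, starts + lens - 1L)
  } else {
    rep(NA_character_, n)
  }
  out <- tibble::tibble(
    id = sprintf("read%06d", seq_len(n)),
    sequence = raw,
    length = nchar(raw),
    true_family = true_family,
    strand = strand,
    start = starts
  )
  as_read_set(out, provenance = if (inherits(genome, "sim_genome")) genome$spec else "string")
}

# majority-footprint truth label per read interval
majority_family <- function(features, start, end) {
  fs <- features$start; fe <- features$end; fam <- features$family
  vapply(seq_along(start), function(i) {
    ov <- pmin(fe, end[i]) - pmax(fs, start[i]) + 1L
    hit <- ov > 0
    if (!any(hit)) return("background")
    tot <- tapply(ov[hit], fam[hit], sum)
    names(tot)[which.max(tot)]
  }, character(1))
}

# 454-style homopolymer length errors: each maximal run of length >= 2 gains
# or loses one base with the given probability
homopolymer_errors <- function(s, p) {
  r <- rle(seq_chars(s))
  idx <- which(r$lengths >= 2)
  hit <- idx[stats::runif(length(idx)) < p]
  for (i in hit) {
    r$lengths[i] <- r$lengths[i] + sample(c(-1L, 1L), 1L)
  }
  paste(rep(r$values, r$lengths), collapse = "")
}

# stamp read_set class + attributes onto a tibble of reads
as_read_set <- function(tbl, provenance = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(tbl)))
  if (anyDuplicated(tbl$id)) stop("read ids must be unique")
  if (!"length" %in% names(tbl)) tbl$length <- nchar(tbl$sequence)
  attr(tbl, "total_reads") <- nrow(tbl)
  attr(tbl, "total_bases") <- sum(tbl$length)
  attr(tbl, "provenance") <- provenance
  class(tbl) <- unique(c("read_set", class(tbl)))
  tbl
}

#' Quality-filter a read set
#'
#' Retains reads with length >= `min_length` and an N fraction <=
#' `max_n_fraction`. The criteria are configurable defaults (length 100 bp,
#' 2% N) since read-level quality filters vary between instruments.
#'
#' @param reads A `read_set` tibble.
#' @param min_length Minimum retained read length in bp.
#' @param max_n_fraction Maximum tolerated fraction of N bases.
#' @return A filtered `read_set` with updated counts.
#' @export
quality_filter <- function(reads, min_length = 100, max_n_fraction = 0.02) {
  stopifnot(is.data.frame(reads))
  n_frac <- stringr::str_count(reads$sequence, "N") / nchar(reads$sequence)
  keep <- nchar(reads$sequence) >= min_length & n_frac <= max_n_fraction
  out <- dplyr::filter(reads, keep)
  if (nrow(out) == 0) stop("quality filter removed every read")
  as_read_set(out, provenance = attr(reads, "provenance"))
}

#' Simulate a slot-blot signal table
#'
#' Emulates quantitative hybridisation of a labelled monomer probe against a
#' dilution series of genomic DNA and a dilution series of the unlabelled
#' monomer standard. The standard's signal is `gain * amount`; a genomic
#' sample's signal is `gain * amount * true_proportion` (only the satellite
#' fraction hybridises). Multiplicative log-normal noise with the given
#' coefficient of variation is applied to every signal; the mean multiplier
#' is 1 so the estimator is calibrated.
#'
#' @param true_proportion Satellite mass fraction of the genomic DNA (0-1).
#' @param genomic_amounts_ng Genomic DNA loadings (default 2, 20, 100 ng).
#' @param standard_amounts_ng Standard (pure monomer) loadings.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param gain Arbitrary positive detector gain (cancels in calibration).
#' @param seed Integer seed.
#' @return Tibble with columns `role` ("standard"/"sample"), `amount_ng`,
#'   `signal`.
#' @export
simulate_slot_blot <- function(true_proportion,
                               genomic_amounts_ng = c(2, 20, 100),
                               standard_amounts_ng = c(0.1, 0.5, 1, 5, 10),
                               noise_cv = 0, gain = 1, seed = 1L) {
  stopifnot(true_proportion >= 0, true_proportion <= 1,
            all(genomic_amounts_ng > 0), all(standard_amounts_ng > 0),
            noise_cv >= 0, noise_cv < 1, gain > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  tbl <- tibble::tibble(
    role = c(rep("standard", length(standard_amounts_ng)),
             rep("sample", length(genomic_amounts_ng))),
    amount_ng = c(standard_amounts_ng, genomic_amounts_ng),
    signal = c(gain * standard_amounts_ng,
               gain * genomic_amounts_ng * true_proportion)
  )
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    tbl$signal <- tbl$signal *
      stats::rlnorm(nrow(tbl), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  tbl
}
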