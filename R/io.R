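# Sequence file IO and pipeline configuration.

#' Read sequences from FASTA or FASTQ into a read set
#'
#' Ids are preserved (first whitespace-delimited token of the header),
#' sequences are upper-cased and U is normalised to T. A malformed FASTA
#' record is reported by record number.
#'
#' @param path Input file.
#' @param format "auto" (by extension), "fasta" or "fastq".
#' @return A `read_set` tibble (see [shear_reads()]); empty with a warning
#'   for an empty file.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else "fasta"
  }
  if (file.size(path) == 0 ||
      (format == "fasta" && length(readLines(path, n = 1)) == 0)) {
    warning("empty input file: ", path)
    return(as_read_set(tibble::tibble(id = character(0), sequence = character(0),
                                      length = integer(0)),
                       provenance = path))
  }
  if (format == "fasta") validate_fasta(path)
  # parse as raw strings first so that U survives until normalisation
  set <- Biostrings::readBStringSet(path, format = format)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  out <- tibble::tibble(id = unname(ids), sequence = unname(toupper(seqs)))
  as_read_set(out, provenance = path)
}

# cheap structural FASTA validation that can name the offending record
validate_fasta <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], ">")) {
    stop("malformed FASTA record 1 in ", path, ": file must start with '>'")
  }
  rec <- cumsum(startsWith(lines, ">"))
  seq_lines <- lines[!startsWith(lines, ">")]
  seq_rec <- rec[!startsWith(lines, ">")]
  bad <- grepl("[^ACGTUNacgtun[:space:]-]", seq_lines)
  if (any(bad)) {
    stop("malformed FASTA record ", seq_rec[which(bad)[1]], " in ", path,
         ": unexpected characters in sequence")
  }
  hdr_rec <- seq_len(max(rec))
  has_seq <- hdr_rec %in% seq_rec[nzchar(gsub("\\s", "", seq_lines))]
  if (!all(has_seq)) {
    stop("malformed FASTA record ", hdr_rec[!has_seq][1], " in ", path,
         ": header without sequence")
  }
  invisible(TRUE)
}

#' Write a read set (or any id/sequence table) to FASTA
#'
#' @param reads Data frame with `id` and `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  set <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the thresholds every stage uses, with validation. Defaults:
#' consensus k-mer length 25 bp; cluster edges need >= 90% identity over
#' >= 55% of the shorter read (seeded with shared 12-mers); clusters are
#' reported above 0.01% genome proportion (strict); a satellite call needs
#' >= 80% of cluster reads mapping back to the circular consensus; 1 pg =
#' 978 Mbp.
#'
#' @param k Consensus k-mer length (>= 11).
#' @param min_identity_pct Edge identity threshold.
#' @param min_overlap_fraction Edge overlap threshold (of the shorter read).
#' @param min_cluster_proportion_pct Cluster reporting cut.
#' @param satellite_mapping_fraction Satellite-call mapping threshold.
#' @param mbp_per_pg C-value conversion constant.
#' @param seed_k Seeding k-mer length for candidate pairs.
#' @param min_length,max_n_fraction Quality-filter settings.
#' @param min_cluster_size Classification size floor.
#' @param seed Pipeline seed.
#' @return A validated `pipeline_config` list with a `hash` field
#'   (stable digest of all settings).
#' @export
pipeline_config <- function(k = 25, min_identity_pct = 90,
                            min_overlap_fraction = 0.55,
                            min_cluster_proportion_pct = 0.01,
                            satellite_mapping_fraction = 0.80,
                            mbp_per_pg = 978, seed_k = 12,
                            min_length = 100, max_n_fraction = 0.02,
                            min_cluster_size = 10, seed = 1L) {
  if (!(min_identity_pct > 0 && min_identity_pct <= 100)) {
    stop("min_identity_pct must be in (0, 100]")
  }
  if (!(min_overlap_fraction > 0 && min_overlap_fraction <= 1)) {
    stop("min_overlap_fraction must be in (0, 1]")
  }
  if (!(min_cluster_proportion_pct >= 0 && min_cluster_proportion_pct <= 100)) {
    stop("min_cluster_proportion_pct must be in [0, 100]")
  }
  if (!(satellite_mapping_fraction > 0 && satellite_mapping_fraction <= 1)) {
    stop("satellite_mapping_fraction must be in (0, 1]")
  }
  if (k < 11) stop("k must be >= 11")
  if (mbp_per_pg <= 0) stop("mbp_per_pg must be positive")
  cfg <- list(k = as.integer(k), min_identity_pct = min_identity_pct,
              min_overlap_fraction = min_overlap_fraction,
              min_cluster_proportion_pct = min_cluster_proportion_pct,
              satellite_mapping_fraction = satellite_mapping_fraction,
              mbp_per_pg = mbp_per_pg, seed_k = as.integer(seed_k),
              min_length = min_length, max_n_fraction = max_n_fraction,
              min_cluster_size = as.integer(min_cluster_size),
              seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Chains quality filtering, edge finding, clustering, the proportion cut,
#' satellite classification, consensus reconstruction, motif annotation and
#' abundance estimation, and (optionally) writes the result tables plus a run
#' manifest recording settings, the config hash and stage timings, so a rerun
#' with the same config and input reproduces every output byte for byte.
#'
#' @param reads A `read_set` tibble or a FASTA/FASTQ path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for TSV reports (created if needed);
#'   `NULL` to skip writing.
#' @param genome_pg Optional 1C genome size in pg, enabling copy-number
#'   output.
#' @return A `pipeline_result` list: `reads` (filtered), `edges`, `clusters`
#'   (classified), `monomers`, `motifs`, `abundance`, `manifest`.
#' @export
run_pipeline <- function(reads, config = pipeline_config(), out_dir = NULL,
                         genome_pg = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  manifest <- list(config = unclass(config), stages = character(0),
                   timings_sec = numeric(0))
  stage <- function(name, expr) {
    ts <- Sys.time()
    message("[", name, "] ...")
    res <- tryCatch(force(expr),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    manifest$timings_sec <<- c(manifest$timings_sec,
                               as.numeric(difftime(Sys.time(), ts, units = "secs")))
    res
  }

  if (is.character(reads)) reads <- stage("read", read_reads(reads))
  filtered <- stage("filter", quality_filter(reads, config$min_length,
                                             config$max_n_fraction))
  edges <- stage("cluster", find_edges(filtered, config$min_identity_pct,
                                       config$min_overlap_fraction,
                                       seed_k = config$seed_k))
  clusters <- cluster_graph(edges, filtered)
  top <- top_clusters(clusters, config$min_cluster_proportion_pct)
  classified <- stage("detect", classify_clusters(
    top, filtered, k = config$k, min_identity_pct = config$min_identity_pct,
    satellite_mapping_fraction = config$satellite_mapping_fraction,
    min_size = config$min_cluster_size))
  monomers <- stage("consensus", {
    m <- attr(classified, "monomers")
    m[classified$classification == "satellite"]
  })
  motifs <- stage("annotate", lapply(monomers, scan_motifs))
  abundance <- stage("quantify", {
    rows <- lapply(which(classified$classification == "satellite"), function(i) {
      prop <- classified$proportion_pct[i]
      tibble::tibble(
        cluster_id = classified$cluster_id[i],
        method = "ngs",
        proportion_pct = prop,
        monomer_bp = classified$monomer_length[i],
        copies_per_1C = if (!is.null(genome_pg)) {
          copies_from_proportion(prop, genome_pg,
                                 classified$monomer_length[i],
                                 config$mbp_per_pg)
        } else NA_real_,
        genome_pg = genome_pg %||% NA_real_,
        denominator = "quality-filtered reads"
      )
    })
    dplyr::bind_rows(rows)
  })

  manifest$n_input_reads <- nrow(reads)
  manifest$n_filtered_reads <- nrow(filtered)
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <- as.character(utils::packageVersion("satkit"))
  manifest$total_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  result <- structure(list(reads = filtered, edges = edges,
                           clusters = classified, monomers = monomers,
                           motifs = motifs, abundance = abundance,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, config)
  result
}

# write the pipeline's tables with the config hash stamped on each
write_pipeline_outputs <- function(result, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("# config_hash: ", config$hash)
  wr <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  cl <- result$clusters
  wr(dplyr::select(tibble::as_tibble(cl), -dplyr::any_of("read_ids")),
     "clusters.tsv")
  wr(tibble::tibble(
    cluster_id = rep(cl$cluster_id, lengths(cl$read_ids)),
    read_id = unlist(cl$read_ids)
  ), "cluster_members.tsv")
  wr(result$edges, "edges.tsv")
  if (nrow(result$abundance) > 0) wr(result$abundance, "abundance.tsv")
  if (length(result$monomers) > 0) {
    write_reads(tibble::tibble(id = names(result$monomers),
                               sequence = vapply(result$monomers, `[[`,
                                                 character(1), "sequence")),
                file.path(out_dir, "monomers.fasta"))
  }
  man <- result$manifest
  writeLines(c(
    paste0("config_hash\t", config$hash),
    paste0("stages\t", paste(man$stages, collapse = ",")),
    paste0("n_input_reads\t", man$n_input_reads),
    paste0("n_filtered_reads\t", man$n_filtered_reads),
    paste0("package_version\t", man$package_version),
    paste0("seed\t", config$seed)
  ), file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$reads), " filtered reads, ",
      nrow(x$clusters), " reported cluster(s), ",
      sum(x$clusters$classification == "satellite"), " satellite(s)\n", sep = "")
  invisible(x)
}
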