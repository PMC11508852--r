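#' End-to-end pipeline configuration
#'
#' The input directory holds one subfolder per sample barcode, each
#' containing FASTQ files; sample labels are taken from the subfolder
#' names. The flags mirror the command-line interface: `identity_t`
#' (`--id`), `min_mean_q` (`--q`, 0 disables the quality filter),
#' `sintax_cutoff` (`--sintax`, overriding both dual-threshold cutoffs when
#' set) and `lulu` (`--skip-lulu` inverted).
#'
#' @param input_dir Directory of per-sample subfolders with FASTQ files.
#' @param reference Path to a SINTAX-formatted reference FASTA (required
#'   for the SH approach and for OTU taxonomy assignment).
#' @param output_dir Directory for result files (created if missing).
#' @param approach `"sh"` or `"otu"`.
#' @param identity_t Clustering identity threshold (OTU approach).
#' @param min_mean_q Minimum probability-domain mean Phred; 0 disables.
#' @param sintax_singleton,sintax_multiton Dual classifiability cutoffs.
#' @param sintax_cutoff Optional single cutoff overriding both.
#' @param lulu Run LULU-style curation after OTU clustering.
#' @param min_match LULU match-list minimum percent identity.
#' @param seed Master RNG seed, recorded in all outputs.
#' @param primers A [primer_pair]; stored as its fields.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, reference = NULL, output_dir = NULL,
                            approach = c("sh", "otu"), identity_t = 0.98,
                            min_mean_q = 0, sintax_singleton = 0.95,
                            sintax_multiton = 0.8, sintax_cutoff = NULL,
                            lulu = TRUE, min_match = 84, seed = 1L,
                            primers = primer_pair()) {
  approach <- match.arg(approach)
  if (!dir.exists(input_dir)) {
    stop(sprintf("pipeline_config: input directory '%s' does not exist",
                 input_dir))
  }
  if (!is.null(sintax_cutoff)) {
    sintax_singleton <- sintax_cutoff
    sintax_multiton <- sintax_cutoff
  }
  stopifnot(identity_t > 0.5, identity_t <= 1, min_mean_q >= 0,
            sintax_singleton >= sintax_multiton)
  if (approach == "sh" && is.null(reference)) {
    stop("pipeline_config: the SH approach requires a reference database")
  }
  if (!is.null(reference) && !file.exists(reference)) {
    stop(sprintf("pipeline_config: reference '%s' does not exist", reference))
  }
  structure(list(input_dir = input_dir, reference = reference,
                 output_dir = output_dir, approach = approach,
                 identity_t = identity_t, min_mean_q = min_mean_q,
                 sintax_singleton = sintax_singleton,
                 sintax_multiton = sintax_multiton, lulu = lulu,
                 min_match = min_match, seed = as.integer(seed),
                 forward_primer = primers$forward,
                 reverse_primer = primers$reverse,
                 max_mismatch = primers$max_mismatch),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' The round trip is lossless: `read_config(write_config(cfg))` equals
#' `cfg`.
#'
#' @param config A [pipeline_config].
#' @param path YAML file path.
#' @return The config (reading) or `path` invisibly (writing).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$seed <- as.integer(raw$seed)
  raw$max_mismatch <- as.integer(raw$max_mismatch)
  for (f in c("identity_t", "min_mean_q", "sintax_singleton",
              "sintax_multiton", "min_match")) {
    raw[[f]] <- as.numeric(raw[[f]])
  }
  structure(raw, class = "pipeline_config")
}

.read_sample_dirs <- function(input_dir) {
  dirs <- list.dirs(input_dir, recursive = FALSE)
  parts <- list()
  skipped <- character(0)
  for (d in dirs) {
    fq <- list.files(d, pattern = "\\.(fastq|fq)$", full.names = TRUE)
    if (length(fq) == 0L) {
      warning(sprintf("run_pipeline: sample folder '%s' holds no FASTQ; skipped",
                      basename(d)))
      skipped <- c(skipped, basename(d))
      next
    }
    rs <- lapply(fq, read_fastq, sample = basename(d))
    parts[[basename(d)]] <- do.call(c, rs)
  }
  if (length(parts) == 0L) stop("run_pipeline: no sample folders with FASTQ files")
  do.call(c, unname(parts))
}

#' Run the full metabarcoding pipeline
#'
#' Stages, in order: primer reorientation/trimming, mean-Phred quality
#' filter, dereplication into zOTUs, de novo chimera removal, then either
#' the SH approach (classification, dual-threshold classifiability filter,
#' SH aggregation) or the OTU approach (greedy clustering, centroid
#' classification, match list, optional LULU curation). Per-stage read
#' attrition is logged per sample, and for every sample the final table
#' column sum plus logged attrition equals the input read count.
#'
#' @param config A [pipeline_config].
#' @param classify_p Optional [classify_params]; cutoffs and seed from the
#'   config override its fields.
#' @return Invisibly, a list: `table` (the final [unit_table]),
#'   `taxonomy` (classification data.frame), `attrition` (per-sample,
#'   per-stage read counts), `read_log` (per-read stage/action/reason),
#'   `match_list`, `lulu_log`, `zotus`, `config`. When
#'   `config$output_dir` is set, tables, FASTA, logs and the config are
#'   written there.
#' @export
run_pipeline <- function(config, classify_p = classify_params()) {
  stopifnot(inherits(config, "pipeline_config"))
  primers <- primer_pair(config$forward_primer, config$reverse_primer,
                         config$max_mismatch)
  classify_p$singleton_cutoff <- config$sintax_singleton
  classify_p$multiton_cutoff <- config$sintax_multiton
  classify_p$seed <- config$seed
  reads <- .read_sample_dirs(config$input_dir)
  samples <- sort(unique(reads$sample))
  count_by <- function(r) {
    v <- table(factor(r$sample, levels = samples))
    as.integer(v)
  }
  attrition <- data.frame(sample = samples, input = count_by(reads))

  tr <- trim_and_orient(reads, primers)
  attrition$rejected_primers <- attrition$input - count_by(tr$reads)
  read_log <- data.frame(read_id = tr$log$read_id, stage = "trim_orient",
                         action = tr$log$action, reason = tr$log$reason,
                         stringsAsFactors = FALSE)
  reads <- tr$reads

  if (config$min_mean_q > 0) {
    keep <- read_mean_phred(reads) >= config$min_mean_q
    qfiltered <- reads[which(keep)]
    read_log <- rbind(read_log, data.frame(
      read_id = reads$id, stage = "quality_filter",
      action = ifelse(keep, "kept", "rejected"),
      reason = ifelse(keep, "", "below_min_mean_q"),
      stringsAsFactors = FALSE))
  } else {
    qfiltered <- reads
  }
  attrition$low_quality <- count_by(reads) - count_by(qfiltered)

  col_counts <- function(mat) {
    v <- stats::setNames(rep(0L, length(samples)), samples)
    if (!is.null(mat) && nrow(mat) > 0L) {
      cs <- colSums(mat)
      v[names(cs)] <- as.integer(cs)
    }
    as.integer(v)
  }

  z <- dereplicate(qfiltered)
  flags <- detect_chimeras(z)
  attrition$chimeric <- col_counts(unclass(z$table)[flags, , drop = FALSE])
  z <- zotu_subset(z, !flags)

  db <- if (!is.null(config$reference)) {
    build_kmer_index(load_sintax_db(config$reference), classify_p$k)
  } else NULL

  match_list <- NULL
  lulu_log <- NULL
  if (config$approach == "sh") {
    cls <- classify_zotus(z$seq, db, classify_p)
    keep <- apply_confidence_filter(z$size, cls$conf_species, classify_p)
    attrition$unclassified <- col_counts(unclass(z$table)[!keep, ,
                                                          drop = FALSE])
    kept <- zotu_subset(z, keep)
    final <- aggregate_sh(kept$table, cls$species[keep])
    taxonomy <- data.frame(unit = z$label, cls, kept = keep,
                           stringsAsFactors = FALSE)
  } else {
    cl <- greedy_cluster(z, cluster_params(config$identity_t))
    tab <- cl$table
    taxonomy <- NULL
    if (!is.null(db)) {
      cents <- cl$centroids[rownames(tab)]
      cls <- classify_zotus(unname(cents), db, classify_p)
      otu_sizes <- rowSums(tab)
      keep <- apply_confidence_filter(otu_sizes, cls$conf_species,
                                      classify_p)
      attrition$unclassified <- col_counts(unclass(tab)[!keep, ,
                                                        drop = FALSE])
      taxonomy <- data.frame(unit = rownames(tab), cls, kept = keep,
                             stringsAsFactors = FALSE)
      tab <- unit_table(unclass(tab)[keep, , drop = FALSE], kind = "OTU")
      cl$centroids <- cl$centroids[rownames(tab)]
    } else {
      attrition$unclassified <- 0L
    }
    if (config$lulu && nrow(tab) >= 2L) {
      match_list <- build_match_list(cl$centroids[rownames(tab)],
                                     config$min_match)
      cur <- lulu_curate(tab, match_list)
      tab <- cur$table
      lulu_log <- cur$log
    }
    final <- tab
  }

  attrition$final <- col_counts(unclass(final))

  centroids_final <- if (config$approach == "otu") {
    cl$centroids[rownames(final)]
  } else NULL
  out <- list(table = final, taxonomy = taxonomy, attrition = attrition,
              match_list = match_list, lulu_log = lulu_log, zotus = z,
              centroids = centroids_final, read_log = read_log,
              config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_unit_table(final, file.path(od, "unit_table.tsv"))
    utils::write.table(attrition, file.path(od, "attrition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(read_log, file.path(od, "read_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(taxonomy)) {
      utils::write.table(taxonomy, file.path(od, "taxonomy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(match_list)) {
      utils::write.table(match_list, file.path(od, "match_list.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    fa <- file.path(od, if (config$approach == "sh") "zotus.fasta"
                    else "centroids.fasta")
    if (config$approach == "sh") {
      writeLines(paste0(">", z$label, ";size=", z$size, "\n", z$seq), fa)
    } else {
      writeLines(paste0(">", names(centroids_final), "\n",
                        unname(centroids_final)), fa)
    }
    write_config(config, file.path(od, "config.yaml"))
  }
  invisible(out)
}
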