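#' Run the full covariance-detection pipeline on an aligned FASTA file
#'
#' Wires all stages: read and validate the alignment, discard sequences
#' diverging from the consensus, select informative sites, detect and
#' confirm independent covariant pairs, harvest tandem patterns, and — when
#' labels are supplied — cluster and evaluate. Writes `pairs.tsv`,
#' `patterns.tsv`, `clusters.tsv` (with labels), `report.txt` and
#' `run_log.txt` (effective parameters and discarded records) into
#' `out_dir`. The pipeline is deterministic: identical inputs and
#' parameters give byte-identical outputs.
#'
#' @param msa Path to an aligned FASTA file, or a [alignment()] object.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param labels Optional named character vector (or path to a two-column
#'   TSV) mapping sequence ids to class labels.
#' @param alphabet Alignment alphabet, `"AA"` or `"NT"`.
#' @param min_consensus_frac Consensus-identity floor for sequence
#'   filtering, default 1/3.
#' @param min_count Minimum sequence count per residue type / element,
#'   default 5.
#' @param purity_threshold Pair purity threshold, default 0.7.
#' @param degree_threshold Association-degree threshold, default 0.7.
#' @param min_pattern_size Minimum pattern size, default 3.
#' @param min_match Cluster-membership match fraction, default 0.45.
#' @return (Invisibly) list with `alignment`, `discarded`, `sites`,
#'   `pairs`, `patterns`, and, when labels are given, `clusters`,
#'   `pattern_classes` and `evaluation`.
#' @export
run_pipeline <- function(msa, out_dir = NULL, labels = NULL,
                         alphabet = c("AA", "NT"),
                         min_consensus_frac = 1 / 3, min_count = 5L,
                         purity_threshold = 0.7, degree_threshold = 0.7,
                         min_pattern_size = 3L, min_match = 0.45) {
  alphabet <- match.arg(alphabet)
  aln <- if (inherits(msa, "cov_alignment")) msa else
    read_fasta_alignment(msa, alphabet = alphabet)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  cons <- consensus_sequence(aln)
  filt <- filter_sequences(aln, cons, min_fraction = min_consensus_frac)
  aln <- filt$alignment
  sites <- informative_sites(aln, min_count = min_count)
  pairs <- detect_pairs(aln, sites, purity_threshold = purity_threshold,
                        min_count = min_count)
  idx <- build_element_index(aln, sites)
  patterns <- harvest_patterns(pairs, idx,
                               degree_threshold = degree_threshold,
                               min_size = min_pattern_size)
  out <- list(alignment = aln, discarded = filt$discarded, sites = sites,
              pairs = pairs, patterns = patterns)
  if (!is.null(labels) && length(patterns) > 0L) {
    clusters <- assign_clusters(aln, patterns, min_match = min_match)
    p2c <- map_patterns_to_classes(clusters, labels)
    out$clusters <- clusters
    out$pattern_classes <- p2c
    out$evaluation <- evaluate_clusters(clusters, labels, p2c)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(df, file) utils::write.table(
      df, file.path(out_dir, file), sep = "\t", quote = FALSE,
      row.names = FALSE)
    tsv(pairs, "pairs.tsv")
    tsv(patterns_table(patterns), "patterns.tsv")
    log_lines <- c(
      sprintf("records: %d kept, %d discarded", aln$n, length(filt$discarded)),
      sprintf("informative sites: %d of %d", length(sites), aln$L),
      sprintf("parameters: min_consensus_frac=%g min_count=%d %s",
              min_consensus_frac, min_count,
              sprintf("purity_threshold=%g degree_threshold=%g min_pattern_size=%d min_match=%g",
                      purity_threshold, degree_threshold, min_pattern_size,
                      min_match)),
      if (length(filt$discarded))
        paste("discarded:", paste(filt$discarded, collapse = ","))
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    report <- c(sprintf("%d confirmed pairs at %d site pairs",
                        sum(pairs$confirmed),
                        length(unique(paste(pairs$site_a, pairs$site_b)[pairs$confirmed]))),
                sprintf("%d covariant patterns", length(patterns)),
                vapply(patterns, format_pattern, character(1L)))
    if (!is.null(out$clusters)) {
      mem <- out$clusters$memberships
      cl_df <- data.frame(pattern_id = mem$pattern_id,
                          class = unname(out$pattern_classes[as.character(mem$pattern_id)]),
                          sequence_id = mem$sequence_id,
                          match_fraction = mem$match_fraction)
      tsv(cl_df, "clusters.tsv")
      ev <- out$evaluation
      mac <- attr(ev, "macro")
      report <- c(report, "", "evaluation:",
                  utils::capture.output(print.data.frame(ev, row.names = FALSE,
                                                         digits = 5)),
                  sprintf("macro: Sen %.5f Spe %.5f Acc %.5f",
                          mac["Sen"], mac["Spe"], mac["Acc"]))
    }
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  invisible(out)
}
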