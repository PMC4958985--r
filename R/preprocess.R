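#' Discard sequences diverging too far from the consensus
#'
#' Data-initialization filter for illegal or unrelated records: a sequence is
#' kept only if strictly more than `min_fraction` of its positions match the
#' consensus. Gap-vs-gap positions count as matches. The consensus is taken
#' as given and is not recomputed after filtering (single pass).
#'
#' @param aln A [alignment()] object.
#' @param cons A [consensus_sequence()] of `aln` (or any consensus of the
#'   same length).
#' @param min_fraction Required consensus-identity fraction, in (0, 1];
#'   default 1/3. The comparison is strict (`matches > min_fraction * L`).
#' @return List with `alignment` (kept records, original order) and
#'   `discarded` (character vector of removed ids).
#' @export
filter_sequences <- function(aln, cons, min_fraction = 1 / 3) {
  stopifnot(inherits(aln, "cov_alignment"), inherits(cons, "cov_consensus"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be a single value in (0, 1]")
  }
  if (cons$L != aln$L) stop("consensus length does not match alignment")
  m <- alignment_matrix(aln)
  cvec <- cons$residue
  matches <- rowSums(m == matrix(cvec, nrow = aln$n, ncol = aln$L, byrow = TRUE))
  keep <- matches > min_fraction * aln$L
  if (!any(keep)) stop("no sequence passed the consensus filter")
  list(alignment = subset_alignment(aln, which(keep)),
       discarded = aln$ids[!keep])
}

#' Informative sites of an alignment
#'
#' A site is informative when at least `min_types` distinct non-gap residues
#' each occur in at least `min_count` sequences there. Only informative sites
#' yield site-residue elements downstream; strictly conserved columns and
#' columns whose minor residues are too rare carry no detectable covariance.
#'
#' @param aln A [alignment()] object.
#' @param min_types Minimum number of residue types per site (>= 2).
#' @param min_count Minimum number of sequences carrying each counted
#'   residue type; default 5.
#' @return Sorted integer vector of 1-based site indices.
#' @export
informative_sites <- function(aln, min_types = 2L, min_count = 5L) {
  stopifnot(inherits(aln, "cov_alignment"))
  if (min_types < 2L) stop("min_types must be at least 2")
  if (min_count < 1L) stop("min_count must be at least 1")
  m <- alignment_matrix(aln)
  keep <- vapply(seq_len(aln$L), function(j) {
    col <- m[, j]
    tab <- table(col[col != aln$gap_char])
    sum(tab >= min_count) >= min_types
  }, logical(1L))
  which(keep)
}
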