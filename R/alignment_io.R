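#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-length sequence records. Sites
#' (columns) are addressed by 1-based index throughout the package, following
#' the convention that reported sites refer to the order of the aligned data.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence ids). All sequences must have the same number of characters.
#' @param alphabet `"AA"` (amino acid, default) or `"NT"` (nucleotide). The
#'   tag is informational; characters outside the alphabet are preserved.
#' @param gap_char Single gap character, default `"-"`.
#'
#' @return An object of class `cov_alignment`: a list with `ids`, `seqs`
#'   (named, upper-cased), `n` (record count), `L` (aligned length),
#'   `alphabet` and `gap_char`.
#' @export
#' @examples
#' aln <- alignment(c(a = "AT", b = "AT"))
#' aln$L
alignment <- function(seqs, alphabet = c("AA", "NT"), gap_char = "-") {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0L) stop("alignment has no records")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every record needs a sequence id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (nchar(gap_char) != 1L) stop("gap_char must be a single character")
  seqs <- toupper(as.character(seqs))
  widths <- nchar(seqs)
  L <- widths[1L]
  if (any(widths != L)) {
    bad <- which(widths != L)[1L]
    stop("not an alignment: record '", ids[bad], "' has length ", widths[bad],
         ", expected ", L)
  }
  names(seqs) <- ids
  structure(
    list(ids = ids, seqs = seqs, n = length(seqs), L = L,
         alphabet = alphabet, gap_char = gap_char),
    class = "cov_alignment"
  )
}

#' @export
print.cov_alignment <- function(x, ...) {
  cat("cov_alignment: ", x$n, " sequences x ", x$L, " aligned sites (",
      x$alphabet, ", gap '", x$gap_char, "')\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file and validates it as an alignment: all
#' records must have the same length and unique ids. Characters are
#' upper-cased; anything else (including ambiguity codes) is preserved
#' verbatim.
#'
#' @param path Path to an aligned FASTA file.
#' @inheritParams alignment
#' @return A [alignment()] object.
#' @export
read_fasta_alignment <- function(path, alphabet = c("AA", "NT"),
                                 gap_char = "-") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  # FASTA descriptions: id is the first whitespace-delimited token
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, "", 1L)
  alignment(seqs, alphabet = alphabet, gap_char = gap_char)
}

#' Write an alignment to FASTA
#'
#' @param aln A [alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cov_alignment"))
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Alignment as a character matrix
#'
#' @param aln A [alignment()] object.
#' @return `n x L` character matrix, rownames = sequence ids.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "cov_alignment"))
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = aln$n, ncol = aln$L, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Consensus sequence of an alignment
#'
#' Per column, the most frequent non-gap residue; ties are broken by the
#' lexicographically smallest residue so the result is deterministic and
#' independent of record order. An all-gap column yields the gap character.
#'
#' @param aln A [alignment()] object.
#' @return A list of class `cov_consensus` with `seq` (length-L string),
#'   `residue` (character vector) and `count` (majority counts; 0 for
#'   all-gap columns).
#' @export
consensus_sequence <- function(aln) {
  stopifnot(inherits(aln, "cov_alignment"))
  m <- alignment_matrix(aln)
  res <- character(aln$L)
  cnt <- integer(aln$L)
  for (j in seq_len(aln$L)) {
    col <- m[, j]
    col <- col[col != aln$gap_char]
    if (length(col) == 0L) {
      res[j] <- aln$gap_char
      cnt[j] <- 0L
    } else {
      tab <- table(col)
      top <- tab[tab == max(tab)]
      res[j] <- sort(names(top))[1L]
      cnt[j] <- as.integer(max(tab))
    }
  }
  structure(list(seq = paste(res, collapse = ""), residue = res, count = cnt,
                 L = aln$L, gap_char = aln$gap_char),
            class = "cov_consensus")
}

#' @export
print.cov_consensus <- function(x, ...) {
  cat("cov_consensus of length", x$L, "\n")
  invisible(x)
}

#' Read a sequence label file
#'
#' Two-column tab-separated file: sequence id, class label. Lines starting
#' with `#` are comments.
#'
#' @param path Path to the label file.
#' @return Named character vector (names = sequence ids, values = labels).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("label file needs two tab-separated columns")
  if (anyDuplicated(df[[1L]])) {
    stop("duplicate sequence id in label file: ",
         df[[1L]][duplicated(df[[1L]])][1L])
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a label file
#' @param labels Named character vector (names = ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# subset records of an alignment by id or index, keeping metadata
subset_alignment <- function(aln, keep) {
  alignment(aln$seqs[keep], alphabet = aln$alphabet, gap_char = aln$gap_char)
}
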