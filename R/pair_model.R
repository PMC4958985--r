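#' @name pair_model
#' @title Independent covariant pair model
#'
#' @description A site-residue element is one residue at one aligned site,
#' written `"12-A"` (residue A at site 12). Two elements at distinct sites
#' form a covariant pair when their occurrence sets across the sequences
#' co-occur with high purity. Purity is the co-occurrence statistic
#' \deqn{P = 2 n_{ab} / (n_a + n_b)}
#' where \eqn{n_a, n_b} are the element occurrence counts and \eqn{n_{ab}}
#' the number of sequences carrying both; it is 0 when the elements never
#' co-occur and 1 when their occurrence sets are identical. Because an
#' observable covariance requires a residue-pair transformation, a site pair
#' is confirmed only when at least two distinct element pairs reach the
#' threshold; lone qualifying pairs are flagged as noise.
NULL

element_key <- function(site, residue) paste0(site, "-", residue)

# the purity statistic, kept in one place so an alternative form can be
# swapped in; equals the Sorensen-Dice coefficient of the occurrence sets
dice_purity <- function(n_a, n_b, n_ab) 2 * n_ab / (n_a + n_b)

#' Index site-residue elements of an alignment
#'
#' Tallies, for each informative site, which sequences carry each non-gap
#' residue. Gap positions contribute no element.
#'
#' @param aln A [alignment()] object.
#' @param sites Integer vector of 1-based site indices (typically from
#'   [informative_sites()]).
#' @return An object of class `cov_element_index`: list with `occ` (named
#'   list, element key -> sorted integer vector of record indices), `n`
#'   (named integer vector of counts) and `elements` (data.frame with
#'   `key`, `site`, `residue`, `n`).
#' @export
build_element_index <- function(aln, sites) {
  stopifnot(inherits(aln, "cov_alignment"))
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) && (min(sites) < 1L || max(sites) > aln$L)) {
    stop("sites must lie in 1..L")
  }
  m <- alignment_matrix(aln)
  occ <- list()
  rows <- list()
  for (s in sites) {
    col <- m[, s]
    for (r in sort(unique(col[col != aln$gap_char]))) {
      k <- element_key(s, r)
      occ[[k]] <- which(unname(col) == r)
      rows[[k]] <- data.frame(key = k, site = s, residue = r,
                              n = length(occ[[k]]), stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), site = integer(), residue = character(),
               n = integer(), stringsAsFactors = FALSE)
  rownames(elements) <- NULL
  structure(list(occ = occ, n = vapply(occ, length, integer(1L)),
                 elements = elements, n_seq = aln$n),
            class = "cov_element_index")
}

#' Purity of a coupled element pair
#'
#' @param idx A [build_element_index()] object.
#' @param a,b Element keys such as `"12-A"`, at distinct sites.
#' @return Purity in \[0, 1\]; symmetric in `a` and `b`.
#' @export
#' @examples
#' aln <- alignment(c(s1 = "AT", s2 = "AT", s3 = "GC"))
#' idx <- build_element_index(aln, 1:2)
#' purity(idx, "1-A", "2-T")
purity <- function(idx, a, b) {
  stopifnot(inherits(idx, "cov_element_index"))
  for (k in c(a, b)) {
    if (is.null(idx$occ[[k]])) stop("element not in index: ", k)
  }
  sa <- idx$occ[[a]]
  sb <- idx$occ[[b]]
  site_a <- as.integer(sub("-.*$", "", a))
  site_b <- as.integer(sub("-.*$", "", b))
  if (site_a == site_b) stop("elements must be at distinct sites")
  dice_purity(length(sa), length(sb), length(intersect(sa, sb)))
}

#' Detect independent covariant pairs
#'
#' Scores every pair of elements at distinct informative sites and keeps
#' those with purity at or above the threshold (inclusive) and both element
#' counts at least `min_count`. Site pairs reached by at least two distinct
#' qualifying element pairs are marked `confirmed`; the rest are noise.
#'
#' The rational purity range is `2/3 < P <= 1`; the default threshold 0.7 is
#' an intermediate correlation value within it. Thresholds outside the
#' rational range are allowed for exploratory scans but emit a warning.
#'
#' @param aln A [alignment()] object.
#' @param sites Informative site indices; defaults to
#'   [informative_sites()] with `min_count` as its residue-count floor.
#' @param purity_threshold Minimum purity, default 0.7.
#' @param min_count Minimum occurrence count per element, default 5.
#' @return data.frame with columns `site_a`, `residue_a`, `site_b`,
#'   `residue_b`, `n_a`, `n_b`, `n_ab`, `purity`, `confirmed`, sorted by
#'   (site_a, site_b, residue_a, residue_b) with `site_a < site_b`.
#' @export
detect_pairs <- function(aln, sites = informative_sites(aln, min_count = min_count),
                         purity_threshold = 0.7, min_count = 5L) {
  stopifnot(inherits(aln, "cov_alignment"))
  if (!is.numeric(purity_threshold) || purity_threshold <= 0 ||
      purity_threshold > 1) {
    stop("purity_threshold must be in (0, 1]")
  }
  if (purity_threshold <= 2 / 3) {
    warning("purity_threshold ", purity_threshold,
            " is outside the rational range 2/3 < P <= 1")
  }
  empty <- data.frame(site_a = integer(), residue_a = character(),
                      site_b = integer(), residue_b = character(),
                      n_a = integer(), n_b = integer(), n_ab = integer(),
                      purity = numeric(), confirmed = logical(),
                      stringsAsFactors = FALSE)
  if (length(unique(sites)) < 2L) {
    message("fewer than 2 informative sites; no pairs to score")
    return(empty)
  }
  idx <- build_element_index(aln, sites)
  el <- idx$elements[idx$elements$n >= min_count, , drop = FALSE]
  if (length(unique(el$site)) < 2L) {
    message("fewer than 2 sites carry elements above min_count")
    return(empty)
  }
  el <- el[order(el$site, el$residue), , drop = FALSE]
  out <- vector("list", 64L)
  nout <- 0L
  ne <- nrow(el)
  for (i in seq_len(ne - 1L)) {
    occ_i <- idx$occ[[el$key[i]]]
    for (j in (i + 1L):ne) {
      if (el$site[j] == el$site[i]) next
      n_ab <- length(intersect(occ_i, idx$occ[[el$key[j]]]))
      p <- dice_purity(el$n[i], el$n[j], n_ab)
      if (p >= purity_threshold) {
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- data.frame(
          site_a = el$site[i], residue_a = el$residue[i],
          site_b = el$site[j], residue_b = el$residue[j],
          n_a = el$n[i], n_b = el$n[j], n_ab = n_ab, purity = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nout == 0L) return(empty)
  pairs <- do.call(rbind, out[seq_len(nout)])
  pairs <- pairs[order(pairs$site_a, pairs$site_b, pairs$residue_a,
                       pairs$residue_b), , drop = FALSE]
  rownames(pairs) <- NULL
  sp <- paste(pairs$site_a, pairs$site_b)
  pairs$confirmed <- stats::ave(seq_along(sp), sp, FUN = length) >= 2L
  pairs
}

#' Confirm covariance between two sites
#'
#' A covariance event transforms one residue pair into another, so at least
#' two element pairs must reach the purity threshold between the two sites
#' simultaneously; a single qualifying pair is noise.
#'
#' @param pairs Output of [detect_pairs()].
#' @param x,y Site indices (order irrelevant).
#' @return `TRUE` if the site pair is confirmed.
#' @export
confirm_site_covariance <- function(pairs, x, y) {
  lo <- min(x, y); hi <- max(x, y)
  sum(pairs$site_a == lo & pairs$site_b == hi) >= 2L
}

#' Confirmed pairs only
#' @param pairs Output of [detect_pairs()].
#' @return The confirmed subset.
#' @export
confirmed_pairs <- function(pairs) {
  pairs[pairs$confirmed, , drop = FALSE]
}
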