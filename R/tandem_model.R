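#' @name tandem_model
#' @title Correlated tandem model
#'
#' @description Confirmed independent pairs that share a common site-residue
#' element are joined into groups (connected components of the element
#' graph). Each group is transformed into a symmetric purity matrix over its
#' elements; the association degree of an element is the mean purity of its
#' row (diagonal excluded), and `d_m` denotes the smallest degree in the
#' current matrix. While `d_m` falls below the degree threshold the
#' corresponding element is removed and the degrees are recalculated; the
#' survivors (at least three, one per site) form a covariant pattern such as
#' `(1-A 6-T 7-V)`. Patterns that are subsets of other patterns are dropped
#' from the final report.
NULL

#' Group confirmed pairs by shared elements
#'
#' Builds the element graph (nodes = site-residue elements, edges =
#' confirmed pairs) and returns its connected components, numbered by their
#' smallest (site, residue) member.
#'
#' @param pairs Confirmed pairs (rows of [detect_pairs()] output with
#'   `confirmed = TRUE`; unconfirmed rows are ignored).
#' @return List of groups, each a list with `group_id`, `elements`
#'   (data.frame `key`, `site`, `residue`) and `pairs` (member pair rows).
#' @export
build_groups <- function(pairs) {
  pairs <- pairs[pairs$confirmed %in% TRUE, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  ka <- element_key(pairs$site_a, pairs$residue_a)
  kb <- element_key(pairs$site_b, pairs$residue_b)
  g <- igraph::graph_from_data_frame(data.frame(from = ka, to = kb),
                                     directed = FALSE)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  # element metadata from the pair table
  meta <- unique(data.frame(
    key = c(ka, kb),
    site = c(pairs$site_a, pairs$site_b),
    residue = c(pairs$residue_a, pairs$residue_b),
    stringsAsFactors = FALSE))
  groups <- lapply(member, function(keys) {
    el <- meta[meta$key %in% keys, , drop = FALSE]
    el <- el[order(el$site, el$residue), , drop = FALSE]
    rownames(el) <- NULL
    pr <- pairs[ka %in% keys & kb %in% keys, , drop = FALSE]
    list(elements = el, pairs = pr)
  })
  # deterministic numbering by smallest (site, residue) member
  first_site <- vapply(groups, function(g) g$elements$site[1L], integer(1L))
  first_res <- vapply(groups, function(g) g$elements$residue[1L], character(1L))
  ord <- order(first_site, first_res)
  groups <- groups[ord]
  for (i in seq_along(groups)) groups[[i]]$group_id <- i
  groups
}

#' Purity matrix of a pair group
#'
#' Every off-diagonal entry is the purity actually computed from the
#' alignment, including for element pairs that were not themselves detected
#' pairs; two elements at the same site have disjoint occurrence sets and
#' hence entry 0. The diagonal is `NA` and excluded from degree averages.
#'
#' @param group One group from [build_groups()] (or any list with an
#'   `elements` data.frame carrying `key` and `site`).
#' @param idx The [build_element_index()] of the alignment.
#' @return Symmetric numeric matrix with element keys as dimnames.
#' @export
purity_matrix <- function(group, idx) {
  keys <- group$elements$key
  n <- length(keys)
  m <- matrix(NA_real_, n, n, dimnames = list(keys, keys))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (group$elements$site[i] == group$elements$site[j]) {
        p <- 0
      } else {
        p <- purity(idx, keys[i], keys[j])
      }
      m[i, j] <- p
      m[j, i] <- p
    }
  }
  m
}

#' Association degrees of a purity matrix
#'
#' The degree of an element is the average purity of its row over the other
#' `n - 1` elements; `d_m` is the smallest degree in the matrix.
#'
#' @param m A [purity_matrix()].
#' @return List with `degree` (named numeric), `d_m` and `which_min`
#'   (keys of all elements attaining `d_m`).
#' @export
association_degrees <- function(m) {
  if (is.null(dim(m)) || nrow(m) < 2L) {
    stop("degree needs a matrix over at least 2 elements")
  }
  deg <- rowMeans(m, na.rm = TRUE)
  list(degree = deg, d_m = min(deg), which_min = names(deg)[deg == min(deg)])
}

# tie-break for removal: largest site, then lexicographically largest residue
pick_removal <- function(keys) {
  site <- as.integer(sub("-.*$", "", keys))
  res <- sub("^[0-9]+-", "", keys)
  ord <- order(site, res)        # ascending; remove the last
  keys[ord[length(ord)]]
}

#' Prune a group matrix by association degree
#'
#' Repeatedly removes the single element attaining the minimum degree `d_m`
#' while `d_m` is below the threshold, recomputing degrees after each
#' removal. Ties at the minimum are broken by removing the element with the
#' largest site, then the lexicographically largest residue. Once all
#' degrees are at or above the threshold, a surviving same-site duplicate
#' (a sequence cannot carry two residues at one site) is resolved by
#' removing the lower-degree one and continuing. Survivors are returned when
#' at least `min_size` remain.
#'
#' @param m A [purity_matrix()].
#' @param degree_threshold Minimum association degree, default 0.7
#'   (inclusive: an element at exactly the threshold survives).
#' @param min_size Minimum pattern size, default 3 (two surviving elements
#'   are just a pair, already reported by the pair model).
#' @return Character vector of surviving element keys, or `NULL` when fewer
#'   than `min_size` survive.
#' @export
prune_group <- function(m, degree_threshold = 0.7, min_size = 3L) {
  repeat {
    if (is.null(dim(m)) || nrow(m) < min_size) return(NULL)
    d <- association_degrees(m)
    if (d$d_m < degree_threshold) {
      drop <- pick_removal(d$which_min)
    } else {
      keys <- rownames(m)
      site <- as.integer(sub("-.*$", "", keys))
      dupsite <- unique(site[duplicated(site)])
      if (length(dupsite) == 0L) return(keys)
      cand <- keys[site == dupsite[1L]]
      cdeg <- d$degree[cand]
      worst <- cand[cdeg == min(cdeg)]
      drop <- pick_removal(worst)
    }
    keep <- setdiff(rownames(m), drop)
    m <- m[keep, keep, drop = FALSE]
  }
}

new_pattern <- function(elements, group_id, m) {
  elements <- elements[order(elements$site, elements$residue), , drop = FALSE]
  rownames(elements) <- NULL
  keys <- elements$key
  sub <- m[keys, keys, drop = FALSE]
  deg <- rowMeans(sub, na.rm = TRUE)
  structure(list(elements = elements, group_id = group_id,
                 min_purity = min(sub, na.rm = TRUE),
                 degrees = deg, size = nrow(elements)),
            class = "cov_pattern")
}

#' @export
print.cov_pattern <- function(x, ...) {
  cat(format_pattern(x), " [group ", x$group_id, ", min purity ",
      signif(x$min_purity, 4), "]\n", sep = "")
  invisible(x)
}

#' Format a covariant pattern
#'
#' @param p A `cov_pattern` (or a data.frame with `site` and `residue`).
#' @return The standard `"(1-A 6-T 7-V)"` representation, sites ascending.
#' @export
format_pattern <- function(p) {
  el <- if (inherits(p, "cov_pattern")) p$elements else p
  el <- el[order(el$site), , drop = FALSE]
  paste0("(", paste(paste0(el$site, "-", el$residue), collapse = " "), ")")
}

#' Drop subset and duplicate patterns
#'
#' A pattern whose element set is a proper subset of another pattern's is
#' redundant; exact duplicates collapse to one. Output is sorted by size
#' (descending) then first site (ascending).
#'
#' @param patterns List of `cov_pattern` objects.
#' @return Filtered, sorted list.
#' @export
remove_subset_patterns <- function(patterns) {
  if (length(patterns) <= 1L) return(patterns)
  sets <- lapply(patterns, function(p) p$elements$key)
  n <- length(sets)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[i]) next
      if (all(sets[[i]] %in% sets[[j]])) {
        if (length(sets[[i]]) < length(sets[[j]])) {
          drop[i] <- TRUE                     # proper subset
        } else if (i > j && !drop[j]) {
          drop[i] <- TRUE                     # duplicate: keep the first
        }
      }
    }
  }
  kept <- patterns[!drop]
  size <- vapply(kept, function(p) p$size, numeric(1L))
  first <- vapply(kept, function(p) min(p$elements$site), numeric(1L))
  str <- vapply(kept, format_pattern, character(1L))
  kept[order(-size, first, str)]
}

# split surviving elements into connected components of the member-pair graph
survivor_components <- function(keys, pairs) {
  ka <- element_key(pairs$site_a, pairs$residue_a)
  kb <- element_key(pairs$site_b, pairs$residue_b)
  sel <- ka %in% keys & kb %in% keys
  edges <- data.frame(from = ka[sel], to = kb[sel])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = keys))
  comp <- igraph::components(g)
  unname(split(names(comp$membership), comp$membership))
}

#' Harvest covariant patterns from confirmed pairs
#'
#' Runs the full tandem model: group confirmed pairs by shared elements,
#' build each group's purity matrix, prune by association degree, split any
#' survivor set that the removals disconnected (each part re-pruned against
#' the threshold), and drop subset/duplicate patterns.
#'
#' @param pairs Output of [detect_pairs()]; only confirmed rows are used.
#' @param idx The [build_element_index()] of the same alignment.
#' @param degree_threshold Minimum association degree, default 0.7.
#' @param min_size Minimum pattern size, default 3.
#' @return List of `cov_pattern` objects (possibly empty), subset-free,
#'   sorted by size descending then first site.
#' @export
harvest_patterns <- function(pairs, idx, degree_threshold = 0.7,
                             min_size = 3L) {
  groups <- build_groups(pairs)
  patterns <- list()
  for (grp in groups) {
    m <- purity_matrix(grp, idx)
    queue <- list(grp$elements$key)
    while (length(queue)) {
      keys <- queue[[1L]]
      queue <- queue[-1L]
      surv <- prune_group(m[keys, keys, drop = FALSE],
                          degree_threshold = degree_threshold,
                          min_size = min_size)
      if (is.null(surv)) next
      comps <- survivor_components(surv, grp$pairs)
      if (length(comps) > 1L) {
        # pruning disconnected the group: re-check each part separately
        queue <- c(queue, comps[lengths(comps) >= min_size])
      } else {
        el <- grp$elements[grp$elements$key %in% surv, , drop = FALSE]
        patterns <- c(patterns, list(new_pattern(el, grp$group_id, m)))
      }
    }
  }
  remove_subset_patterns(patterns)
}

#' Tabulate patterns for reporting
#'
#' @param patterns List of `cov_pattern` objects.
#' @return data.frame with `pattern_id`, `group_id`, `size`, `pattern`,
#'   `min_purity`, `degrees` (comma-separated, per element in site order).
#' @export
patterns_table <- function(patterns) {
  if (length(patterns) == 0L) {
    return(data.frame(pattern_id = integer(), group_id = integer(),
                      size = integer(), pattern = character(),
                      min_purity = numeric(), degrees = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    pattern_id = seq_along(patterns),
    group_id = vapply(patterns, function(p) p$group_id, integer(1L)),
    size = vapply(patterns, function(p) as.integer(p$size), integer(1L)),
    pattern = vapply(patterns, format_pattern, character(1L)),
    min_purity = vapply(patterns, function(p) p$min_purity, numeric(1L)),
    degrees = vapply(patterns, function(p)
      paste(signif(p$degrees[p$elements$key], 4), collapse = ","),
      character(1L)),
    stringsAsFactors = FALSE)
}
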