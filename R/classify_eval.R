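#' Fraction of pattern sites matched by a sequence
#'
#' A pattern site matches when the sequence carries exactly the pattern's
#' residue at that aligned position; a gap never matches.
#'
#' @param seq An aligned sequence (single character string).
#' @param pattern A `cov_pattern` (or data.frame with `site`, `residue`).
#' @return Matched fraction in \[0, 1\].
#' @export
match_fraction <- function(seq, pattern) {
  el <- if (inherits(pattern, "cov_pattern")) pattern$elements else pattern
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (max(el$site) > length(chars)) {
    stop("pattern site ", max(el$site), " beyond sequence length ",
         length(chars))
  }
  mean(chars[el$site] == el$residue)
}

#' Cluster sequences by covariant patterns
#'
#' Every pattern is the signature of one subpopulation; a loose fit
#' suffices for membership, so a sequence joins the cluster of every
#' pattern for which at least `min_match` of the pattern sites match
#' (inclusive threshold, default 45%). Clusters may overlap and a sequence
#' matching no pattern is reported as unassigned.
#'
#' @param aln A [alignment()] object.
#' @param patterns Non-empty list of `cov_pattern` objects.
#' @param min_match Minimum matched fraction of pattern sites, default 0.45.
#' @return Object of class `cov_clusters`: list with `memberships`
#'   (data.frame `pattern_id`, `sequence_id`, `match_fraction`),
#'   `unassigned` (ids), `n_patterns` and `min_match`.
#' @export
assign_clusters <- function(aln, patterns, min_match = 0.45) {
  stopifnot(inherits(aln, "cov_alignment"))
  if (length(patterns) == 0L) stop("patterns must be non-empty")
  if (min_match <= 0 || min_match > 1) stop("min_match must be in (0, 1]")
  m <- alignment_matrix(aln)
  rows <- vector("list", length(patterns))
  for (k in seq_along(patterns)) {
    el <- patterns[[k]]$elements
    if (max(el$site) > aln$L) stop("pattern site beyond alignment length")
    hit <- m[, el$site, drop = FALSE] ==
      matrix(el$residue, nrow = aln$n, ncol = nrow(el), byrow = TRUE)
    frac <- rowMeans(hit)
    sel <- which(frac >= min_match)
    rows[[k]] <- data.frame(pattern_id = rep.int(k, length(sel)),
                            sequence_id = aln$ids[sel],
                            match_fraction = frac[sel],
                            stringsAsFactors = FALSE)
  }
  memberships <- do.call(rbind, rows)
  rownames(memberships) <- NULL
  structure(list(memberships = memberships,
                 unassigned = setdiff(aln$ids, memberships$sequence_id),
                 n_patterns = length(patterns), min_match = min_match),
            class = "cov_clusters")
}

#' @export
print.cov_clusters <- function(x, ...) {
  cat("cov_clusters:", x$n_patterns, "patterns,",
      nrow(x$memberships), "memberships,",
      length(x$unassigned), "unassigned (min_match", x$min_match, ")\n")
  invisible(x)
}

#' Evaluate cluster assignments against class labels
#'
#' Membership in any cluster whose pattern maps to a class counts as a
#' positive call for that class. Per class, the confusion counts over all
#' sequences give Sen = TP/(TP+FN), Spe = TN/(TN+FP) and
#' Acc = (TP+TN)/(TP+TN+FP+FN); the macro row is the unweighted mean over
#' classes.
#'
#' @param assign A [assign_clusters()] result.
#' @param labels Named character vector, sequence id -> class label; every
#'   clustered sequence must be labeled.
#' @param pattern_to_class Named character vector, pattern id (as produced
#'   by `assign_clusters`, coerced to character) -> class label. Classes
#'   without any pattern simply receive no positive calls.
#' @return Object of class `cov_eval`: data.frame with one row per class
#'   (`class`, `TP`, `FP`, `FN`, `TN`, `Sen`, `Spe`, `Acc`) and a `macro`
#'   attribute (named numeric: Sen, Spe, Acc).
#' @export
evaluate_clusters <- function(assign, labels, pattern_to_class) {
  stopifnot(inherits(assign, "cov_clusters"))
  mem <- assign$memberships
  ids <- union(mem$sequence_id, assign$unassigned)
  if (!all(ids %in% names(labels))) {
    stop("unlabeled sequence: ", setdiff(ids, names(labels))[1L])
  }
  labels <- labels[ids]
  classes <- sort(unique(unname(labels)))
  if (!all(pattern_to_class %in% classes)) {
    stop("pattern mapped to unknown class: ",
         setdiff(pattern_to_class, classes)[1L])
  }
  N <- length(ids)
  rows <- lapply(classes, function(cl) {
    pats <- as.integer(names(pattern_to_class)[pattern_to_class == cl])
    called <- unique(mem$sequence_id[mem$pattern_id %in% pats])
    is_cl <- labels == cl
    if (!any(is_cl)) stop("empty positive class: ", cl)
    tp <- sum(ids[is_cl] %in% called)
    fp <- length(called) - tp
    fn <- sum(is_cl) - tp
    tn <- N - tp - fp - fn
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = tn,
               Sen = tp / (tp + fn), Spe = tn / (tn + fp),
               Acc = (tp + tn) / N, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "macro") <- c(Sen = mean(out$Sen), Spe = mean(out$Spe),
                          Acc = mean(out$Acc))
  class(out) <- c("cov_eval", "data.frame")
  out
}

#' @export
print.cov_eval <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 5)
  mac <- attr(x, "macro")
  cat(sprintf("macro: Sen %.5f  Spe %.5f  Acc %.5f\n",
              mac["Sen"], mac["Spe"], mac["Acc"]))
  invisible(x)
}

# majority class of each pattern's training cluster (tie: first class
# alphabetically); returns named character vector keyed by pattern id
map_patterns_to_classes <- function(assign, labels) {
  mem <- assign$memberships
  out <- character(0)
  for (pid in sort(unique(mem$pattern_id))) {
    cls <- labels[mem$sequence_id[mem$pattern_id == pid]]
    tab <- sort(table(cls), decreasing = TRUE)
    tab <- tab[tab == max(tab)]
    out[as.character(pid)] <- sort(names(tab))[1L]
  }
  out
}

# per-pattern accuracy as a one-pattern classifier for class cl
pattern_class_acc <- function(assign, labels, pid, cl) {
  mem <- assign$memberships
  called <- unique(mem$sequence_id[mem$pattern_id == pid])
  n <- length(labels)
  tp <- sum(labels[called] == cl)
  fp <- length(called) - tp
  fn <- sum(labels == cl) - tp
  (tp + (n - tp - fp - fn)) / n
}

#' Stratified k-fold cross-validation of pattern classification
#'
#' The members of each class are randomly divided into `k` subsets; the
#' like-numbered subsets across classes form each test set, and the rest
#' train. Per fold, covariant patterns are detected on the training
#' alignment, each pattern is attributed to the majority class of its
#' training cluster, the best pattern per class (highest training accuracy;
#' ties broken by larger pattern, then smaller first site) is retained, the
#' test portion is classified and evaluated, and the macro indexes are
#' averaged across folds.
#'
#' @param aln A [alignment()] object.
#' @param labels Named character vector, sequence id -> class.
#' @param k Number of folds, default 10; every class needs at least `k`
#'   members.
#' @param seed Integer seed controlling the fold partition.
#' @param purity_threshold,min_count Passed to [detect_pairs()].
#' @param degree_threshold,min_pattern_size Passed to [harvest_patterns()].
#' @param min_match Passed to [assign_clusters()].
#' @return Object of class `cov_cv`: list with `folds` (data.frame of
#'   per-fold macro Sen/Spe/Acc), `mean` and `sd` (named numeric), `k`,
#'   `seed` and `fold_assignment` (named integer vector).
#' @export
cross_validate <- function(aln, labels, k = 10L, seed = 1L,
                           purity_threshold = 0.7, min_count = 5L,
                           degree_threshold = 0.7, min_pattern_size = 3L,
                           min_match = 0.45) {
  stopifnot(inherits(aln, "cov_alignment"))
  if (!all(aln$ids %in% names(labels))) {
    stop("unlabeled sequence: ", setdiff(aln$ids, names(labels))[1L])
  }
  labels <- labels[aln$ids]
  names(labels) <- aln$ids
  sizes <- table(labels)
  if (any(sizes < k)) {
    stop("class smaller than k folds: ", names(sizes)[sizes < k][1L])
  }
  fold <- withr::with_seed(seed, {
    f <- integer(aln$n)
    for (cl in names(sizes)) {
      members <- which(labels == cl)
      f[members] <- sample(rep_len(seq_len(k), length(members)))
    }
    f
  })
  names(fold) <- aln$ids
  res <- vector("list", k)
  for (i in seq_len(k)) {
    train <- subset_alignment(aln, which(fold != i))
    test <- subset_alignment(aln, which(fold == i))
    pairs <- detect_pairs(train, purity_threshold = purity_threshold,
                          min_count = min_count)
    idx <- build_element_index(train, informative_sites(train,
                                                        min_count = min_count))
    patterns <- harvest_patterns(pairs, idx,
                                 degree_threshold = degree_threshold,
                                 min_size = min_pattern_size)
    if (length(patterns) == 0L) {
      res[[i]] <- data.frame(fold = i, Sen = 0, Spe = 1,
                             Acc = NA_real_, n_patterns = 0L)
      next
    }
    tr_assign <- assign_clusters(train, patterns, min_match = min_match)
    p2c <- map_patterns_to_classes(tr_assign, labels[train$ids])
    # best pattern per class on the training portion
    best <- character(0)
    for (cl in names(sizes)) {
      cand <- as.integer(names(p2c)[p2c == cl])
      if (length(cand) == 0L) next
      acc <- vapply(cand, pattern_class_acc, numeric(1L),
                    assign = tr_assign, labels = labels[train$ids], cl = cl)
      size <- vapply(patterns[cand], function(p) p$size, numeric(1L))
      first <- vapply(patterns[cand], function(p) min(p$elements$site),
                      numeric(1L))
      best[as.character(cand[order(-acc, -size, first)][1L])] <- cl
    }
    chosen <- as.integer(names(best))
    if (length(chosen) == 0L) {
      res[[i]] <- data.frame(fold = i, Sen = 0, Spe = 1,
                             Acc = NA_real_, n_patterns = length(patterns))
      next
    }
    te_assign <- assign_clusters(test, patterns[chosen],
                                 min_match = min_match)
    mapping <- stats::setNames(unname(best), seq_along(chosen))
    ev <- evaluate_clusters(te_assign, labels[test$ids], mapping)
    mac <- attr(ev, "macro")
    res[[i]] <- data.frame(fold = i, Sen = mac["Sen"], Spe = mac["Spe"],
                           Acc = mac["Acc"], n_patterns = length(patterns))
  }
  folds <- do.call(rbind, res)
  rownames(folds) <- NULL
  metrics <- c("Sen", "Spe", "Acc")
  structure(list(folds = folds,
                 mean = vapply(folds[metrics], mean, numeric(1L)),
                 sd = vapply(folds[metrics], stats::sd, numeric(1L)),
                 k = k, seed = seed, fold_assignment = fold),
            class = "cov_cv")
}

#' @export
print.cov_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  for (m in c("Sen", "Spe", "Acc")) {
    cat(sprintf("  macro %s: %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' Stratified subsample of a labeled alignment
#'
#' Draws `round(fraction * n)` members per class (at least one), for
#' different-scale tests.
#'
#' @param aln A [alignment()] object.
#' @param labels Named character vector, sequence id -> class.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return List with `alignment` and `labels` of the subsample.
#' @export
subsample_alignment <- function(aln, labels, fraction, seed = 1L) {
  stopifnot(inherits(aln, "cov_alignment"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  labels <- labels[aln$ids]
  keep <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(unname(labels))), function(cl) {
      members <- aln$ids[labels == cl]
      size <- max(1L, round(fraction * length(members)))
      sample(members, size)
    }), use.names = FALSE)
  })
  keep <- aln$ids[aln$ids %in% keep]   # original record order
  list(alignment = subset_alignment(aln, keep), labels = labels[keep])
}
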