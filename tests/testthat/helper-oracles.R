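# Independent brute-force oracles. These deliberately avoid the package's
# index/graph machinery: purities are counted from logical vectors over the
# raw character matrix, grouping is done by repeated set merging, and the
# pruning dynamics are re-simulated with plain loops.

oracle_char_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

# score every element pair at distinct sites by direct co-occurrence counting
oracle_detect_pairs <- function(aln, sites, threshold, min_count,
                                gap_char = "-") {
  m <- oracle_char_matrix(aln)
  res <- list()
  sites <- sort(sites)
  for (ii in seq_along(sites)) {
    for (jj in seq_along(sites)) {
      if (jj <= ii) next
      i <- sites[ii]; j <- sites[jj]
      for (r1 in sort(unique(m[m[, i] != gap_char, i]))) {
        for (r2 in sort(unique(m[m[, j] != gap_char, j]))) {
          a <- m[, i] == r1
          b <- m[, j] == r2
          na <- sum(a); nb <- sum(b); nab <- sum(a & b)
          p <- 2 * nab / (na + nb)
          if (na >= min_count && nb >= min_count && p >= threshold) {
            res[[length(res) + 1L]] <- data.frame(
              site_a = i, residue_a = r1, site_b = j, residue_b = r2,
              n_a = na, n_b = nb, n_ab = nab, purity = p,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(site_a = integer(), residue_a = character(),
                      site_b = integer(), residue_b = character(),
                      n_a = integer(), n_b = integer(), n_ab = integer(),
                      purity = numeric(), confirmed = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$site_a, out$site_b, out$residue_a, out$residue_b), ]
  rownames(out) <- NULL
  key <- paste(out$site_a, out$site_b)
  out$confirmed <- vapply(key, function(k) sum(key == k) >= 2L, logical(1L))
  out
}

oracle_purity_of <- function(aln, key1, key2, gap_char = "-") {
  m <- oracle_char_matrix(aln)
  parse <- function(k) {
    list(site = as.integer(sub("-.*$", "", k)), res = sub("^[0-9]+-", "", k))
  }
  e1 <- parse(key1); e2 <- parse(key2)
  if (e1$site == e2$site) return(0)
  a <- m[, e1$site] == e1$res
  b <- m[, e2$site] == e2$res
  2 * sum(a & b) / (sum(a) + sum(b))
}

# merge confirmed-pair element sets until a fixpoint: the groups
oracle_groups <- function(pairs) {
  pairs <- pairs[pairs$confirmed, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  sets <- lapply(seq_len(nrow(pairs)), function(r) {
    c(paste0(pairs$site_a[r], "-", pairs$residue_a[r]),
      paste0(pairs$site_b[r], "-", pairs$residue_b[r]))
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      if (is.null(sets[[i]])) next
      for (j in seq_along(sets)) {
        if (i == j || is.null(sets[[j]])) next
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sets <- Filter(Negate(is.null), sets)
  lapply(sets, function(s) {
    site <- as.integer(sub("-.*$", "", s))
    res <- sub("^[0-9]+-", "", s)
    sort(s[order(site, res)])
  })
}

# replay the degree-pruning dynamics with plain loops
oracle_prune <- function(aln, keys, pair_tab, threshold, min_size = 3L) {
  key_site <- function(k) as.integer(sub("-.*$", "", k))
  key_res <- function(k) sub("^[0-9]+-", "", k)
  pick <- function(cand) {
    ord <- order(key_site(cand), key_res(cand))
    cand[ord[length(ord)]]
  }
  repeat {
    if (length(keys) < min_size) return(NULL)
    deg <- vapply(keys, function(a) {
      mean(vapply(setdiff(keys, a), function(b)
        oracle_purity_of(aln, a, b), numeric(1L)))
    }, numeric(1L))
    if (min(deg) < threshold) {
      keys <- setdiff(keys, pick(names(deg)[deg == min(deg)]))
      next
    }
    sites <- key_site(keys)
    dup <- unique(sites[duplicated(sites)])
    if (length(dup)) {
      cand <- keys[sites == dup[1L]]
      cdeg <- deg[cand]
      keys <- setdiff(keys, pick(cand[cdeg == min(cdeg)]))
      next
    }
    return(keys)
  }
}

oracle_components_of <- function(keys, pairs) {
  ka <- paste0(pairs$site_a, "-", pairs$residue_a)
  kb <- paste0(pairs$site_b, "-", pairs$residue_b)
  sel <- ka %in% keys & kb %in% keys
  sets <- c(lapply(which(sel), function(r) c(ka[r], kb[r])),
            as.list(keys))
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      if (is.null(sets[[i]])) next
      for (j in seq_along(sets)) {
        if (i == j || is.null(sets[[j]])) next
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  Filter(Negate(is.null), sets)
}

# full tandem oracle: groups, pruning, disconnection splits, subset removal;
# returns a sorted character vector of formatted patterns
oracle_patterns <- function(aln, pairs, threshold, min_size = 3L) {
  groups <- oracle_groups(pairs)
  confirmed <- pairs[pairs$confirmed, , drop = FALSE]
  out <- list()
  for (keys in groups) {
    queue <- list(keys)
    while (length(queue)) {
      ks <- queue[[1L]]; queue <- queue[-1L]
      surv <- oracle_prune(aln, ks, confirmed, threshold, min_size)
      if (is.null(surv)) next
      comps <- oracle_components_of(surv, confirmed)
      if (length(comps) > 1L) {
        queue <- c(queue, comps[lengths(comps) >= min_size])
      } else {
        out[[length(out) + 1L]] <- sort(surv)
      }
    }
  }
  # drop duplicates and proper subsets
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i == j || !keep[i]) next
      if (all(out[[i]] %in% out[[j]]) &&
          (length(out[[i]]) < length(out[[j]]) || (i > j && keep[j]))) {
        keep[i] <- FALSE
      }
    }
  }
  fmt <- vapply(out[keep], function(s) {
    site <- as.integer(sub("-.*$", "", s))
    paste0("(", paste(s[order(site)], collapse = " "), ")")
  }, character(1L))
  sort(fmt)
}

# random small alignment for property tests
random_alignment <- function(n_seq, L, alphabet = c("A", "C", "G", "T"),
                             gap_prob = 0.05, block = TRUE) {
  m <- matrix(sample(alphabet, n_seq * L, replace = TRUE), n_seq, L)
  if (block && n_seq >= 4L && L >= 3L) {
    # correlated 3-site block so covariant pairs and patterns actually arise
    half <- seq_len(n_seq %/% 2L)
    m[half, 1:3] <- rep(alphabet[c(1L, 2L, 3L)], each = length(half))
    m[-half, 1:3] <- rep(alphabet[c(3L, 4L, 1L)],
                         each = n_seq - length(half))
  }
  if (gap_prob > 0) m[matrix(runif(n_seq * L) < gap_prob, n_seq, L)] <- "-"
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- sprintf("s%03d", seq_len(n_seq))
  alignment(seqs, alphabet = "NT")
}
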