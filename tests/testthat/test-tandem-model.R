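# small helper: fabricate a confirmed-pairs table from element key pairs
fake_pairs <- function(...) {
  rows <- lapply(list(...), function(kk) {
    site <- as.integer(sub("-.*$", "", kk))
    res <- sub("^[0-9]+-", "", kk)
    o <- order(site)
    data.frame(site_a = site[o[1]], residue_a = res[o[1]],
               site_b = site[o[2]], residue_b = res[o[2]],
               n_a = 1L, n_b = 1L, n_ab = 1L, purity = 1,
               confirmed = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("groups are the connected components of the element graph", {
  g1 <- build_groups(fake_pairs(c("1-A", "6-T"), c("6-T", "7-V")))
  expect_length(g1, 1L)
  expect_equal(g1[[1]]$elements$key, c("1-A", "6-T", "7-V"))
  expect_equal(g1[[1]]$group_id, 1L)

  g2 <- build_groups(fake_pairs(c("3-G", "4-C"), c("1-A", "2-T")))
  expect_length(g2, 2L)
  # numbered by smallest (site, residue) member
  expect_equal(g2[[1]]$elements$key[1], "1-A")
  expect_equal(g2[[2]]$elements$key[1], "3-G")

  expect_length(build_groups(fake_pairs(c("1-A", "2-T"))[0, ]), 0L)
})

test_that("group purity matrices hold data-derived purities, 0 at same site", {
  # 1-A pairs with 2-T; 1-G also pairs with 2-T is impossible (disjoint),
  # so couple 1-A and 1-G through shared partners at sites 2 and 3
  aln <- alignment(stats::setNames(
    c("ATT", "ATT", "ATT", "GTC", "GTC", "GTC"), sprintf("s%d", 1:6)))
  idx <- build_element_index(aln, 1:3)
  grp <- list(elements = data.frame(key = c("1-A", "1-G", "2-T"),
                                    site = c(1L, 1L, 2L),
                                    residue = c("A", "G", "T"),
                                    stringsAsFactors = FALSE))
  m <- purity_matrix(grp, idx)
  expect_identical(m["1-A", "1-G"], 0)           # same-site: disjoint sets
  expect_equal(m["1-A", "2-T"], 2 * 3 / (3 + 6)) # data-derived, not a member pair
  expect_true(all(is.na(diag(m))))
  expect_identical(m, t(m))

  # single-pair group: off-diagonal is that pair's purity
  grp2 <- list(elements = data.frame(key = c("1-A", "3-T"),
                                     site = c(1L, 3L), residue = c("A", "T"),
                                     stringsAsFactors = FALSE))
  m2 <- purity_matrix(grp2, idx)
  expect_equal(m2["1-A", "3-T"], 1)
})

test_that("association degrees are off-diagonal row means and d_m their min", {
  m <- matrix(NA_real_, 3, 3, dimnames = rep(list(c("1-A", "2-B", "3-C")), 2))
  m["1-A", "2-B"] <- m["2-B", "1-A"] <- 0.9
  m["1-A", "3-C"] <- m["3-C", "1-A"] <- 0.8
  m["2-B", "3-C"] <- m["3-C", "2-B"] <- 0.7
  d <- association_degrees(m)
  expect_equal(unname(d$degree), c(0.85, 0.80, 0.75))
  expect_equal(d$d_m, 0.75)
  expect_equal(d$which_min, "3-C")

  # constant matrix: every degree equals the constant
  mc <- matrix(0.6, 4, 4, dimnames = rep(list(paste0(1:4, "-A")), 2))
  diag(mc) <- NA
  dc <- association_degrees(mc)
  expect_true(all(dc$degree == 0.6))
  expect_equal(dc$d_m, 0.6)

  # permutation of rows/columns permutes degrees identically
  perm <- c(3, 1, 2)
  dp <- association_degrees(m[perm, perm])
  expect_equal(dp$degree, d$degree[perm])

  expect_error(association_degrees(m[1, 1, drop = FALSE]), "at least 2")
})

test_that("degree pruning removes weak elements one at a time", {
  keys <- c("1-A", "6-T", "7-V", "2-W")
  m <- matrix(NA_real_, 4, 4, dimnames = list(keys, keys))
  fill <- function(a, b, p) m[a, b] <<- m[b, a] <<- p
  fill("1-A", "6-T", 0.9); fill("1-A", "7-V", 0.8); fill("6-T", "7-V", 0.85)
  fill("2-W", "1-A", 0.3); fill("2-W", "6-T", 0.4); fill("2-W", "7-V", 0.2)
  # 2-W has the smallest association (0.3) and is removed first; the
  # remaining degrees all exceed 0.7, harvesting a 3-element pattern
  expect_equal(prune_group(m, 0.7), c("1-A", "6-T", "7-V"))

  # all associations strong: nothing is removed
  ms <- matrix(0.9, 4, 4, dimnames = list(keys, keys)); diag(ms) <- NA
  expect_equal(prune_group(ms, 0.7), keys)

  # uniformly weak: elements fall out until fewer than 3 remain -> none
  mw <- matrix(0.5, 3, 3,
               dimnames = rep(list(c("1-A", "6-T", "7-V")), 2))
  diag(mw) <- NA
  expect_null(prune_group(mw, 0.7))

  # exact-threshold degrees survive (termination is >=, not >)
  mt <- matrix(0.7, 3, 3, dimnames = rep(list(c("1-A", "6-T", "7-V")), 2))
  diag(mt) <- NA
  expect_equal(prune_group(mt, 0.7), c("1-A", "6-T", "7-V"))

  # tie at the minimum: the largest site (then largest residue) goes first
  m4 <- matrix(0.9, 4, 4, dimnames = list(keys, keys))
  m4["2-W", c("1-A", "6-T")] <- m4[c("1-A", "6-T"), "2-W"] <- 0.7
  m4["7-V", c("1-A", "6-T")] <- m4[c("1-A", "6-T"), "7-V"] <- 0.7
  m4["2-W", "7-V"] <- m4["7-V", "2-W"] <- 0.1   # deg(2-W) = deg(7-V) = 0.5
  diag(m4) <- NA
  surv <- prune_group(m4, 0.7)
  expect_equal(surv, c("1-A", "6-T", "2-W"))     # 7-V removed before 2-W
})

test_that("subset and duplicate patterns are dropped, larger first", {
  mk <- function(keys, gid = 1L) {
    el <- data.frame(key = keys,
                     site = as.integer(sub("-.*$", "", keys)),
                     residue = sub("^[0-9]+-", "", keys),
                     stringsAsFactors = FALSE)
    m <- matrix(0.9, length(keys), length(keys),
                dimnames = list(keys, keys))
    diag(m) <- NA
    covtandem:::new_pattern(el, gid, m)
  }
  full <- mk(c("1-A", "6-T", "7-V"))
  sub <- mk(c("1-A", "6-T"))
  out <- remove_subset_patterns(list(sub, full))
  expect_length(out, 1L)
  expect_equal(format_pattern(out[[1]]), "(1-A 6-T 7-V)")

  expect_length(remove_subset_patterns(list(full, mk(c("1-A", "6-T", "7-V")))),
                1L)

  other <- mk(c("1-A", "6-T", "8-K"))
  both <- remove_subset_patterns(list(other, full))
  expect_length(both, 2L)
  # pairwise subset relation verified directly
  expect_false(all(other$elements$key %in% full$elements$key))
})

test_that("patterns are rendered in the (site-residue ...) notation", {
  el <- data.frame(site = c(7L, 1L, 6L), residue = c("V", "A", "T"))
  expect_equal(format_pattern(el), "(1-A 6-T 7-V)")
  el2 <- data.frame(site = c(13L, 16L, 127L, 222L, 238L),
                    residue = c("R", "T", "R", "A", "H"))
  expect_equal(format_pattern(el2), "(13-R 16-T 127-R 222-A 238-H)")
  # ordering is by site regardless of insertion order
  expect_equal(format_pattern(el[c(2, 3, 1), ]), format_pattern(el))
})

test_that("harvested patterns match the brute-force dynamics oracle", {
  set.seed(37)
  tried <- 0
  for (rep in 1:40) {
    aln <- random_alignment(sample(10:30, 1), sample(4:8, 1), gap_prob = 0.03)
    sites <- informative_sites(aln, min_count = 1)
    if (length(sites) < 3) next
    pairs <- detect_pairs(aln, sites, purity_threshold = 0.7, min_count = 1)
    idx <- build_element_index(aln, sites)
    got <- sort(vapply(harvest_patterns(pairs, idx, 0.7), format_pattern,
                       character(1)))
    want <- oracle_patterns(aln, pairs, 0.7)
    expect_equal(got, want)
    tried <- tried + 1
  }
  expect_gte(tried, 20)
})

test_that("reported patterns are subset-free, site-unique, above threshold", {
  set.seed(41)
  n_checked <- 0
  for (rep in 1:10) {
    aln <- random_alignment(sample(12:30, 1), sample(5:9, 1))
    sites <- informative_sites(aln, min_count = 1)
    if (length(sites) < 3) next
    pairs <- detect_pairs(aln, sites, purity_threshold = 0.7, min_count = 1)
    idx <- build_element_index(aln, sites)
    pats <- harvest_patterns(pairs, idx, 0.7)
    sets <- lapply(pats, function(p) p$elements$key)
    for (i in seq_along(pats)) {
      expect_gte(pats[[i]]$size, 3)
      expect_false(anyDuplicated(pats[[i]]$elements$site) > 0)
      # post-hoc: every element's degree in its own matrix >= threshold
      m <- purity_matrix(pats[[i]], idx)
      expect_true(all(association_degrees(m)$degree >= 0.7))
      for (j in seq_along(pats)) {
        if (i != j) expect_false(all(sets[[i]] %in% sets[[j]]))
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 5)
})

test_that("a planted pattern is recovered exactly from a clean alignment", {
  # three classes: with only two, a class's planted tuple and the other
  # class's consensus complement ride on the same carriers and merge into
  # one (correct) larger signature, so standalone recovery needs a third
  # subpopulation to break the complementarity
  pat <- data.frame(site = c(5L, 12L, 20L), residue = c("W", "Y", "F"))
  cfg <- simulation_config(class_sizes = c(120L, 120L, 120L), L = 30L,
                           noise_rate = 0, carrier_purity = 0.95,
                           patterns = list(pat, data.frame(
                             site = c(2L, 9L, 25L, 28L),
                             residue = c("K", "R", "D", "E")),
                             data.frame(site = c(7L, 15L, 22L),
                                        residue = c("L", "M", "P"))),
                           consensus = paste(rep("G", 30), collapse = ""),
                           seed = 5L)
  sim <- generate_alignment(cfg)
  aln <- sim$alignment
  sites <- informative_sites(aln)
  pairs <- detect_pairs(aln, sites)
  idx <- build_element_index(aln, sites)
  found <- vapply(harvest_patterns(pairs, idx), format_pattern, character(1))
  expect_true(format_pattern(pat) %in% found)
  expect_true(format_pattern(sim$truth$patterns$B) %in% found)
})
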