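test_that("standard lists combine pathways from cleanly related pairs only", {
  cs <- list(s1 = pathway_callset("s1", c("P1", "P2")),
             s2 = pathway_callset("s2", "P2"),
             s3 = pathway_callset("s3", "P3"),
             s4 = pathway_callset("s4", "P2"))
  pr <- data.frame(sample_a = c("s1", "s3"), sample_b = c("s2", "s4"),
                   related = c(TRUE, TRUE))
  lst <- build_standard_list(cs, pr, "sp", 5e6)
  expect_identical(lst$map_ids, c("P1", "P2", "P3"))
  expect_identical(lst$depth, 5e6)

  # samples of an unrelated pair are excluded entirely
  cs2 <- list(s1 = pathway_callset("s1", "P1"), s2 = pathway_callset("s2", "P1"),
              s3 = pathway_callset("s3", "P9"), s4 = pathway_callset("s4", "P9"))
  pr2 <- data.frame(sample_a = c("s1", "s3"), sample_b = c("s2", "s4"),
                    related = c(TRUE, FALSE))
  expect_identical(build_standard_list(cs2, pr2, "sp", 5e6)$map_ids, "P1")

  pr3 <- data.frame(sample_a = "s1", sample_b = "s2", related = FALSE)
  expect_error(build_standard_list(cs2[1:2], pr3, "sp", 5e6), "no related pairs")
  expect_error(build_standard_list(cs2, pr3, "sp", 5e6), "without a relatedness label")
})

test_that("PKS profiles project call sets onto the list order", {
  lst <- standard_pathway_list("sp", 5e6, c("P1", "P2"))
  expect_identical(make_pks_profile(pathway_callset("s", "P1"), lst)$vector,
                   c(P1 = 1L, P2 = 0L))
  expect_identical(make_pks_profile(pathway_callset("s", character(0)), lst)$vector,
                   c(P1 = 0L, P2 = 0L))
  expect_identical(make_pks_profile(pathway_callset("s", c("P1", "P2", "P3")), lst)$vector,
                   c(P1 = 1L, P2 = 1L)) |> suppressMessages()
  expect_message(make_pks_profile(pathway_callset("s", "P9"), lst), "outside")
})

test_that("pairwise differences count discordant pathways with signs", {
  lst <- toy_list(2)
  a <- toy_profile(c(1L, 0L), "a", 1, lst)
  b <- toy_profile(c(0L, 1L), "b", 2, lst)
  expect_identical(pks_difference(a, a)$n_diff, 0L)
  d <- pks_difference(a, b)
  expect_identical(d$n_diff, 2L)
  expect_identical(unname(d$delta), c(-1L, 1L))  # one loss, one gain

  other <- toy_profile(c(0L, 1L, 0L), "c", 3)
  expect_error(pks_difference(a, other), "different standard")

  # random profiles of length 23 vs an element-wise counting oracle
  set.seed(8)
  l23 <- toy_list(23)
  for (i in 1:100) {
    va <- sample(0:1, 23, TRUE); vb <- sample(0:1, 23, TRUE)
    d <- pks_difference(toy_profile(va, "a", 1, l23), toy_profile(vb, "b", 2, l23))
    n <- 0L; for (j in 1:23) if (va[j] != vb[j]) n <- n + 1L
    expect_identical(d$n_diff, n)
  }
})

test_that("Hamming distance satisfies the metric axioms", {
  set.seed(12)
  l <- toy_list(23)
  for (i in 1:200) {
    va <- sample(0:1, 23, TRUE); vb <- sample(0:1, 23, TRUE); vc <- sample(0:1, 23, TRUE)
    a <- toy_profile(va, "a", 1, l); b <- toy_profile(vb, "b", 2, l)
    cc <- toy_profile(vc, "c", 3, l)
    dab <- pks_difference(a, b)$n_diff
    expect_identical(dab, pks_difference(b, a)$n_diff)          # symmetry
    expect_identical(pks_difference(a, a)$n_diff, 0L)           # identity
    expect_lte(dab, pks_difference(a, cc)$n_diff + pks_difference(cc, b)$n_diff)
  }
})

test_that("pair summaries use half-away-from-zero percentage rounding", {
  s <- summarize_related_pairs(diffs_with_counts(c(0, 0, 3, 5)))
  expect_identical(s$n_zero, 2L)
  expect_identical(s$pct_zero, 50.0)
  expect_identical(s$n_nonzero, 2L)

  # rounding convention itself
  expect_identical(round_half_up(18.15, 1), 18.2)
  expect_identical(round_half_up(-0.25, 1), -0.3)
  expect_identical(round_half_up(100 * 13 / 35, 1), 37.1)

  expect_error(summarize_related_pairs(list()), "at least one")
})

test_that("shared-pattern groups collect identical nonzero deltas only", {
  lst <- toy_list(4)
  ref <- toy_profile(rep(0L, 4), "ref", 1, lst)
  mk <- function(v, id) pks_difference(ref, toy_profile(v, id, 2, lst))
  diffs <- list(mk(c(1L, 0L, 0L, 0L), "x1"), mk(c(1L, 0L, 0L, 0L), "x2"),
                mk(c(0L, 1L, 1L, 0L), "y1"),
                mk(rep(0L, 4), "z1"), mk(rep(0L, 4), "z2"))
  s <- summarize_related_pairs(diffs)
  expect_length(s$shared_pattern_groups, 1)   # zero pairs are not a "pattern"
  expect_setequal(s$shared_pattern_groups[[1]], c("ref|x1", "ref|x2"))
  expect_identical(s$n_zero, 2L)
  # percentage conservation under rounding
  expect_lt(abs(s$pct_zero + s$pct_nonzero - 100), 0.1 + 1e-9)
})

test_that("cluster detection recovers patterns, reappearances and resolution", {
  lst <- toy_list(4)
  mk <- function(v, i, d) toy_profile(v, sprintf("s%d", i), d, lst)
  A <- c(1L, 0L, 1L, 0L); B <- c(0L, 0L, 0L, 1L)
  C <- c(1L, 1L, 0L, 0L); D <- c(0L, 1L, 1L, 1L)

  # all distinct: unique and resolved
  cr <- find_clusters(list(mk(A, 1, 1), mk(B, 2, 2), mk(C, 3, 3)))
  expect_identical(cr$classification, "unique")
  expect_length(cr$clusters, 0)
  expect_identical(cr$cluster_membership_count, 0L)
  expect_true(cr$resolved)

  # extinction and reappearance: A,B,C,D,A,A,A at days 2,5,6,7,14,21,28
  days <- c(2L, 5L, 6L, 7L, 14L, 21L, 28L)
  pats <- list(A, B, C, D, A, A, A)
  cr2 <- find_clusters(Map(mk, pats, seq_along(days), days))
  expect_identical(cr2$classification, "shared")
  expect_length(cr2$clusters, 1)
  expect_identical(cr2$clusters[[1]]$days, c(2L, 14L, 21L, 28L))
  expect_identical(cr2$cluster_membership_count, 4L)
  expect_identical(cr2$reappearance_events, 1L)
  expect_false(cr2$resolved)

  # trailing unique pattern resolves the series
  cr3 <- find_clusters(list(mk(A, 1, 1), mk(A, 2, 2), mk(B, 3, 3)))
  expect_identical(cr3$clusters[[1]]$days, c(1L, 2L))
  expect_true(cr3$resolved)

  expect_error(find_clusters(list(mk(A, 1, 1))), "at least 2")
  expect_error(find_clusters(list(mk(A, 1, 2), mk(B, 2, 2))), "strictly increasing")
})

test_that("cluster reports are invariant to consistent pathway permutation", {
  set.seed(3)
  lst <- toy_list(6)
  perm <- sample(6)
  plst <- standard_pathway_list("sp", 5e6, lst$map_ids)  # same ids, same order
  for (i in 1:20) {
    vecs <- lapply(1:5, function(j) sample(0:1, 6, TRUE))
    vecs[[4]] <- vecs[[2]]  # force one cluster
    days <- c(1L, 3L, 5L, 8L, 13L)
    s1 <- Map(function(v, d, j) toy_profile(v, sprintf("s%d", j), d, lst),
              vecs, days, 1:5)
    s2 <- Map(function(v, d, j) toy_profile(v[perm], sprintf("s%d", j), d, plst),
              vecs, days, 1:5)
    c1 <- find_clusters(s1); c2 <- find_clusters(s2)
    expect_identical(c1$classification, c2$classification)
    expect_identical(c1$cluster_membership_count, c2$cluster_membership_count)
    expect_identical(c1$reappearance_events, c2$reappearance_events)
    expect_identical(c1$resolved, c2$resolved)
    expect_identical(lapply(c1$clusters, `[[`, "days"),
                     lapply(c2$clusters, `[[`, "days"))
  }
})
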