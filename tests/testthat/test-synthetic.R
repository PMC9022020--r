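test_that("generated pathway DBs honour overlap and determinism", {
  db0 <- generate_pathway_db(6, 200, overlap_frac = 0, seed = 4)
  all_ecs <- unlist(db0, use.names = FALSE)
  expect_identical(anyDuplicated(all_ecs), 0L)  # overlap 0 -> pairwise disjoint

  db1 <- generate_pathway_db(1, 50, overlap_frac = 0.5, seed = 4)
  expect_length(db1, 1)

  expect_identical(generate_pathway_db(6, 200, 0.4, seed = 9),
                   generate_pathway_db(6, 200, 0.4, seed = 9))
  expect_false(identical(generate_pathway_db(6, 200, 0.4, seed = 9),
                         generate_pathway_db(6, 200, 0.4, seed = 10)))
  expect_error(generate_pathway_db(100, 10, 0, seed = 1), "too small")

  # shared sub-pool produces overlap when requested
  dbo <- generate_pathway_db(8, 300, overlap_frac = 0.6, seed = 2)
  ov <- combn(8, 2, function(ij) length(intersect(dbo[[ij[1]]], dbo[[ij[2]]])))
  expect_gt(mean(ov), 0)
})

test_that("strain pairs share exactly the planted fraction of calls", {
  p1 <- generate_strain_pair(10000, 40, shared_frac = 1, seed = 6)
  expect_identical(p1$a$calls, p1$b$calls)
  expect_equal(compute_wss(p1$a, p1$b)$score, 100)

  p0 <- generate_strain_pair(10000, 40, shared_frac = 0, seed = 6,
                             separate_windows = TRUE)
  expect_equal(compute_wss(p0$a, p0$b)$score, 0)

  ph <- generate_strain_pair(50000, 60, shared_frac = 0.5, seed = 6)
  ka <- paste(ph$a$calls$pos, ph$a$calls$alt)
  kb <- paste(ph$b$calls$pos, ph$b$calls$alt)
  expect_identical(length(intersect(ka, kb)), 30L)  # floor(0.5 * 60)
  expect_identical(nrow(ph$a$calls), 60L)
  expect_identical(nrow(ph$b$calls), 60L)
  # emitted instance agrees with the brute-force window oracle
  expect_equal(compute_wss(ph$a, ph$b)$score, oracle_wss(ph$a, ph$b, 1000),
               tolerance = 1e-12)

  expect_identical(generate_strain_pair(10000, 40, 0.3, seed = 1),
                   generate_strain_pair(10000, 40, 0.3, seed = 1))
})

test_that("longitudinal series realize their cluster spec exactly", {
  days <- c(2L, 5L, 6L, 7L, 14L, 21L, 28L)
  g <- generate_longitudinal_series(days, 8, list(c(2, 14, 21, 28)), seed = 7)
  cr <- find_clusters(g$profiles)
  expect_identical(cr$classification, "shared")
  expect_identical(cr$clusters[[1]]$days, c(2L, 14L, 21L, 28L))
  expect_identical(cr$cluster_membership_count, 4L)
  expect_identical(cr$reappearance_events, 1L)
  expect_false(cr$resolved)
  expect_identical(g$truth$classification, "shared")
  expect_identical(g$truth$reappearance_events, 1L)
  expect_false(g$truth$resolved)

  # empty spec: all patterns unique
  g0 <- generate_longitudinal_series(days, 8, list(), seed = 7)
  cr0 <- find_clusters(g0$profiles)
  expect_identical(cr0$classification, "unique")
  expect_true(cr0$resolved)

  # two interleaved clusters both recovered
  g2 <- generate_longitudinal_series(days, 8,
                                     list(c(2, 6, 21), c(5, 14, 28)), seed = 7)
  cr2 <- find_clusters(g2$profiles)
  expect_length(cr2$clusters, 2)
  expect_identical(lapply(cr2$clusters, `[[`, "days"),
                   list(c(2L, 6L, 21L), c(5L, 14L, 28L)))
  expect_identical(cr2$reappearance_events, 4L)

  expect_error(generate_longitudinal_series(days, 2, list(), seed = 1),
               "patterns")
  expect_error(generate_longitudinal_series(days, 8, list(c(2, 3)), seed = 1),
               "not in days")
  expect_error(generate_longitudinal_series(days, 8, list(c(2, 5), c(5, 7)),
                                            seed = 1), "disjoint")
  expect_error(generate_longitudinal_series(days, 8, list(c(2, 2)), seed = 1))
})

test_that("pair labels are recovered perfectly at well-separated similarity", {
  rel <- vapply(1:15, function(i) {
    p <- generate_strain_pair(50000, 100, 0.9, seed = 100 + i)
    compute_wss(p$a, p$b)$score
  }, 0)
  unrel <- vapply(1:15, function(i) {
    p <- generate_strain_pair(50000, 100, 0.1, seed = 200 + i)
    compute_wss(p$a, p$b)$score
  }, 0)
  model <- calibrate_cutoff(rel[1:8], unrel[1:8], "synthetic_sp")
  held_r <- rel[9:15]; held_u <- unrel[9:15]
  expect_true(all(held_r > model$cutoff))
  expect_true(all(held_u <= model$cutoff))
})

test_that("simulated cohorts land on disk with consistent ground truth", {
  dir <- withr::local_tempdir()
  cfg <- simulate_cohort(dir,
                         list(I1 = list(days = c(0L, 3L, 7L), cluster_spec = list()),
                              I2 = list(days = c(0L, 3L, 7L, 10L),
                                        cluster_spec = list(c(0L, 7L)))),
                         seed = 21, list_length = 10)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  st <- read.delim(file.path(dir, "samples.tsv"))
  expect_identical(nrow(st), 7L)
  expect_true(all(file.exists(file.path(dir, st$vcf))))
  expect_true(all(file.exists(file.path(dir, st$gff))))
  expect_true(all(file.exists(file.path(dir, st$fastq))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$I2$classification, "shared")
  expect_identical(unlist(truth$I2$cluster_days[[1]]), c(0L, 7L))
})
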