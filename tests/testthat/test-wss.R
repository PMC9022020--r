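write_vcf_lines <- function(lines, ext = ".vcf") {
  fp <- tempfile(fileext = ext)
  writeLines(lines, fp)
  fp
}

vcf_header <- c("##fileformat=VCFv4.2",
                "##contig=<ID=sp,length=3000>",
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

test_that("VCF loading keeps SNVs and skips indels/multi-allelics", {
  fp <- write_vcf_lines(c(vcf_header,
                          "sp\t100\t.\tA\tT\t.\tPASS\t.",
                          "sp\t200\t.\tAT\tA\t.\tPASS\t.",     # indel
                          "sp\t300\t.\tG\tC,A\t.\t.\t.",        # multi-allelic
                          "sp\t400\t.\tG\tC\t.\tq10\t.",        # soft-filtered
                          "sp\t500\t.\tC\tG\t.\t.\t."))
  prof <- suppressMessages(load_snv_profile(fp, "sp"))
  expect_identical(prof$calls$pos, c(100L, 500L))
  expect_identical(prof$calls$alt, c("T", "G"))
  expect_identical(attr(prof, "n_skipped"), 3L)
  expect_identical(prof$genome_length, 3000)

  empty <- load_snv_profile(write_vcf_lines(vcf_header), "sp")
  expect_identical(nrow(empty$calls), 0L)

  dup <- write_vcf_lines(c(vcf_header,
                           "sp\t100\t.\tA\tT\t.\tPASS\t.",
                           "sp\t100\t.\tA\tG\t.\tPASS\t."))
  expect_error(load_snv_profile(dup, "sp"), "conflicting calls at position 100")

  bad <- write_vcf_lines(c(vcf_header, "sp\t100\tbroken"))
  expect_error(load_snv_profile(bad, "sp"), "line 4")
})

test_that("SNV VCF writing round-trips through the reader", {
  prof <- snv_profile("sp", 3000,
                      data.frame(pos = c(10, 1500, 2999), alt = c("T", "G", "A")))
  fp <- tempfile(fileext = ".vcf")
  write_snv_vcf(prof, fp)
  back <- load_snv_profile(fp, "sp")
  expect_identical(back$calls, prof$calls)
  expect_identical(back$genome_length, prof$genome_length)
})

test_that("WSS matches hand-computed per-window Jaccard", {
  a <- snv_profile("sp", 3000, data.frame(pos = c(100, 1500), alt = c("T", "G")))
  b <- snv_profile("sp", 3000, data.frame(pos = c(100, 2500), alt = c("T", "A")))
  res <- compute_wss(a, b)
  expect_equal(res$score, 100 / 3, tolerance = 1e-12)
  expect_identical(res$n_windows_used, 3L)
  expect_true(is.na(res$related))

  # identical non-empty profiles score 100; fully disjoint windows score 0
  expect_equal(compute_wss(a, a)$score, 100)
  d1 <- snv_profile("sp", 3000, data.frame(pos = 50, alt = "T"))
  d2 <- snv_profile("sp", 3000, data.frame(pos = 1050, alt = "T"))
  expect_equal(compute_wss(d1, d2)$score, 0)

  # same position, different alt: different call
  e1 <- snv_profile("sp", 3000, data.frame(pos = 100, alt = "T"))
  e2 <- snv_profile("sp", 3000, data.frame(pos = 100, alt = "G"))
  expect_equal(compute_wss(e1, e2)$score, 0)

  expect_error(compute_wss(snv_profile("sp", 3000, NULL),
                           snv_profile("sp", 3000, NULL)),
               "no informative windows")
  expect_error(compute_wss(a, snv_profile("other", 3000, NULL)), "species")
})

test_that("WSS is symmetric, window-local and monotone under shared calls", {
  set.seed(11)
  for (i in 1:50) {
    glen <- sample(3:10, 1) * 1000
    a <- rand_snv_profile(glen, sample(1:30, 1))
    b <- rand_snv_profile(glen, sample(1:30, 1))
    expect_equal(compute_wss(a, b)$score, compute_wss(b, a)$score)
    expect_equal(compute_wss(a, b)$score, oracle_wss(a, b, 1000),
                 tolerance = 1e-12)

    # adding one shared call to both never decreases the score
    free <- setdiff(seq_len(glen), c(a$calls$pos, b$calls$pos))
    pos <- sample(free, 1)
    a2 <- snv_profile("sp", glen, rbind(a$calls, data.frame(pos = pos, alt = "A")))
    b2 <- snv_profile("sp", glen, rbind(b$calls, data.frame(pos = pos, alt = "A")))
    expect_gte(compute_wss(a2, b2)$score, compute_wss(a, b)$score - 1e-9)
  }
})

test_that("cutoff calibration maximizes Youden's J over score midpoints", {
  m <- calibrate_cutoff(c(90, 95), c(40, 50), "sp")
  expect_equal(m$cutoff, 70)
  expect_identical(m$calibration_n, c(n_related = 2L, n_unrelated = 2L))

  # perfectly separated singletons: midpoint
  expect_equal(calibrate_cutoff(80, 20, "sp")$cutoff, 50)

  # overlapping distributions: deterministic under the largest-tie rule
  r <- c(50, 60, 70); u <- c(55, 65, 75)
  m1 <- calibrate_cutoff(r, u, "sp")
  expect_identical(m1$cutoff, calibrate_cutoff(r, u, "sp")$cutoff)
  j <- function(ct) mean(r > ct) + mean(u <= ct) - 1
  cand <- sort(unique(c(r, u)))
  cand <- (cand[-1] + cand[-length(cand)]) / 2
  expect_equal(j(m1$cutoff), max(vapply(cand, j, 0)))
  expect_lt(j(m1$cutoff), 1)

  expect_error(calibrate_cutoff(numeric(0), 1, "sp"), "non-empty")
  expect_error(calibrate_cutoff(c(5, 5), c(5, 5), "sp"), "identical")
})

test_that("relatedness uses a strict greater-than rule", {
  m <- cutoff_model("sp", 70)
  res <- function(s) structure(list(score = s, n_windows_used = 1L,
                                    related = NA, species_id = "sp"),
                               class = "wss_result")
  expect_identical(classify_pair(res(72), m), "related")
  expect_identical(classify_pair(res(70), m), "unrelated")  # ties are unrelated
  expect_identical(classify_pair(res(40), m), "unrelated")
  expect_error(classify_pair(res(40), cutoff_model("other", 70)), "species")
})

test_that("cutoff tables round-trip as TSV", {
  fp <- tempfile(fileext = ".tsv")
  write_cutoff_table(list(calibrate_cutoff(c(90, 95), c(40, 50), "spA"),
                          cutoff_model("spB", 83.2, 10L, 12L)), fp)
  back <- read_cutoff_table(fp)
  expect_named(back, c("spA", "spB"))
  expect_equal(back$spA$cutoff, 70)
  expect_equal(back$spB$cutoff, 83.2)
  expect_identical(back$spB$calibration_n, c(n_related = 10L, n_unrelated = 12L))
})
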