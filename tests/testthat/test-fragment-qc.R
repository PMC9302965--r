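frag <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end, length = end - start)
}

test_that("fragment lengths classify into the nucleosomal classes with explicit gaps", {
  cases <- c(`100` = "sub", `146` = "sub", `147` = "other", `150` = "other",
             `179` = "other", `180` = "mono", `200` = "mono", `247` = "mono",
             `248` = "other", `314` = "other", `315` = "di", `400` = "di",
             `473` = "di", `474` = "other", `600` = "other")
  got <- classify_fragment_length(as.integer(names(cases)))
  expect_equal(as.character(got), unname(cases))
  expect_error(classify_fragment_length(0), ">= 1")
  expect_error(size_class_scheme(mono_hi = 400), "sub_max")
})

test_that("size distribution reports partitioning proportions", {
  sd1 <- size_distribution(tibble::tibble(length = c(100, 100, 200, 400)))
  expect_equal(sd1$proportions$proportion, c(0.5, 0.25, 0.25, 0))
  expect_equal(sum(sd1$proportions$n), 4L)

  expect_equal(size_distribution(tibble::tibble(length = rep(200, 5)))$proportions$proportion,
               c(0, 1, 0, 0))
  expect_equal(size_distribution(tibble::tibble(length = 150))$proportions$proportion,
               c(0, 0, 0, 1))
  expect_error(size_distribution(tibble::tibble(length = numeric(0))), "at least one")

  # partition property on random lengths
  withr::with_seed(5, {
    lens <- sample(30:600, 500, replace = TRUE)
    p <- size_distribution(tibble::tibble(length = lens))$proportions$proportion
    expect_equal(sum(p), 1, tolerance = 1e-12)
  })
})

test_that("FROT counts fragments intersecting TSS windows by >= 1 bp", {
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 1500, strand = "+")
  expect_equal(frot(frag("chr1", 900, 1000), tss), 1)
  expect_equal(frot(frag("chr1", 5000, 5100), tss), 0)
  expect_equal(frot(frag(c("chr1", "chr1"), c(900, 5000), c(1000, 5100)), tss), 0.5)
  expect_warning(res <- frot(frag("chr1", 0, 100), tss[0, ]), "empty TSS")
  expect_equal(res, 0)
})

test_that("adding a TSS record never decreases FROT", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- 50
      st <- sample(0:99000, n)
      fr <- frag("chr1", st, st + sample(50:400, n, replace = TRUE))
      tss <- tibble::tibble(gene_id = paste0("g", 1:5), chrom = "chr1",
                            pos = sample(0:99000, 5), strand = "+")
      base <- frot(fr, tss)
      more <- dplyr::bind_rows(tss, tibble::tibble(gene_id = "gx", chrom = "chr1",
                                                   pos = sample(0:99000, 1), strand = "+"))
      expect_gte(frot(fr, more), base)
    }
  })
})

test_that("TSS profile is strand-oriented mean coverage over 2*window/bin bins", {
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 5000, strand = "+")
  empty <- tss_profile(frag("chr1", 1, 2)[0, ], tss)
  expect_equal(nrow(empty), 200L)
  expect_true(all(empty$coverage == 0))

  # one fragment exactly on the 10 bp bin right of the TSS
  prof <- tss_profile(frag("chr1", 5000, 5010), tss)
  expect_equal(sum(prof$coverage > 0), 1L)
  expect_equal(prof$bin_start[prof$coverage > 0], 0)

  # same fragment, minus strand: mirrored into the upstream-left half
  tss_m <- dplyr::mutate(tss, strand = "-")
  prof_m <- tss_profile(frag("chr1", 5000, 5010), tss_m)
  expect_equal(prof_m$bin_start[prof_m$coverage > 0], -10)

  expect_error(tss_profile(frag("chr1", 0, 10), tss, window = 1000, bin = 13),
               "divisible")
})

test_that("fragments centred on a TSS maximise the central profile bins", {
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 50000, strand = "+")
  withr::with_seed(7, {
    centers <- round(rnorm(2000, 50000, 80))
    fr <- frag("chr1", centers - 50, centers + 50)
  })
  prof <- tss_profile(fr, tss)
  central <- abs(prof$bin_start) <= 50
  expect_gt(min(prof$coverage[central]), max(prof$coverage[abs(prof$bin_start) > 500]))
})

test_that("FRiP partitions fragments with proximal peaks checked first", {
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", pos = 1000, strand = "+")
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(800, 50000), end = c(1301, 50501))
  frs <- frag("chr1", c(900, 50100, 8000, 9000), c(1000, 50200, 8100, 9100))
  res <- frip(frs, peaks, tss)
  expect_equal(res$fraction, c(0.25, 0.25, 0.5))
  expect_equal(sum(res$fraction), 1)
  expect_equal(sum(res$n), 4L)

  # a fragment under both a proximal and a distal peak counts as tss_peaks
  both <- tibble::tibble(chrom = "chr1", start = c(800, 2500), end = c(1301, 3001))
  one <- frag("chr1", 1250, 2600)  # spans the proximal and the distal peak
  res2 <- frip(one, both, tss)
  expect_equal(res2$fraction[res2$category == "tss_peaks"], 1)

  expect_error(frip(one, peaks[0, ], tss), "non-empty")
})

test_that("in-peak counting uses the 1 bp rule and rejects overlapping peaks", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(1000, 5000), end = c(1501, 5501))
  frs <- frag("chr1", c(1100, 1200, 1300, 999, 4000), c(1200, 1300, 1400, 1001, 4100))
  res <- count_in_peaks(frs, peaks)
  expect_equal(res$count, c(4L, 0L))  # boundary fragment (1 bp inside) counts

  expect_equal(count_in_peaks(frs[0, ], peaks)$count, c(0L, 0L))

  overlapping <- tibble::tibble(chrom = "chr1", start = c(0, 400), end = c(501, 901))
  expect_error(count_in_peaks(frs, overlapping), "ambiguous")
})

test_that("subsampling is an exact, seeded uniform subset", {
  fr <- frag("chr1", seq(0, 9900, by = 100), seq(50, 9950, by = 100))
  expect_equal(subsample_fragments(fr, nrow(fr), seed = 1), fr)
  expect_equal(nrow(subsample_fragments(fr, 0, seed = 1)), 0L)
  expect_identical(subsample_fragments(fr, 10, seed = 3),
                   subsample_fragments(fr, 10, seed = 3))
  expect_error(subsample_fragments(fr, nrow(fr) + 1, seed = 1), "exceeds")
})

test_that("subsampling preserves size-class proportions in expectation", {
  cfg <- tiny_config(depth = 20000)
  fr <- simulate_fragments(cfg, 1)
  full <- size_distribution(fr)$proportions$proportion
  n_sub <- 2000
  props <- sapply(1:100, function(s) {
    size_distribution(subsample_fragments(fr, n_sub, seed = s))$proportions$proportion
  })
  se_mean <- sqrt(full * (1 - full) / n_sub / 100)
  expect_true(all(abs(rowMeans(props) - full) <= 3 * pmax(se_mean, 1e-12)))
})

test_that("qc_report bundles the metrics and glance flattens them", {
  cfg <- tiny_config()
  truth <- sim_truth(cfg)
  anno <- simulate_annotation(cfg, truth)
  fr <- simulate_fragments(cfg, 1, truth)
  pk <- simulate_peak_calls(fr, cfg, 1)
  qc <- qc_report(fr, pk, anno$tss)
  expect_s3_class(qc, "atac_qc")
  expect_equal(sum(qc$class_proportions$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(qc$frip$fraction), 1, tolerance = 1e-9)
  expect_true(all(qc$frip$fraction >= 0 & qc$frip$fraction <= 1))
  g <- glance(qc)
  expect_equal(g$n_fragments, cfg$depth)
  expect_equal(g$frot, qc$frot)
})
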