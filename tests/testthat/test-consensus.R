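chrom_sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))

test_that("summit extension produces 501 bp windows and drops boundary peaks", {
  pk <- tibble::tibble(chrom = "chr1", start = 9900L, end = 10100L,
                       summit = 10000L, score = 5)
  fixed <- to_fixed_width(pk, chrom_sizes)
  expect_equal(fixed$start, 9750L)
  expect_equal(fixed$end, 10251L)
  expect_equal(fixed$end - fixed$start, 501L)

  near_edge <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L,
                              summit = 100L, score = 5)
  expect_message(dropped <- to_fixed_width(near_edge, chrom_sizes), "dropped 1")
  expect_equal(nrow(dropped), 0L)

  expect_equal(nrow(to_fixed_width(pk[0, ], chrom_sizes)), 0L)
  expect_error(to_fixed_width(dplyr::mutate(pk, summit = NA), chrom_sizes), "summit")
})

test_that("blacklist filtering removes peaks on >= 1 bp intersection", {
  pk <- tibble::tibble(chrom = "chr1", start = c(1000L, 2000L, 3000L),
                       end = c(1501L, 2501L, 3501L), score = 1)
  bl <- tibble::tibble(chrom = "chr1", start = c(1100L, 2500L), end = c(1200L, 2600L))
  kept <- filter_blacklist(pk, bl)
  expect_equal(kept$start, 3000L)  # full containment and 1 bp overlap both removed
  expect_equal(filter_blacklist(pk, bl[0, ]), pk)
})

test_that("iterative removal keeps greedy-by-score survivors", {
  abc <- tibble::tibble(chrom = "chr1", start = c(0L, 250L, 600L),
                        end = c(501L, 751L, 1101L), score = c(10, 20, 5))
  expect_equal(iterative_removal(abc)$score, 20)

  abc2 <- tibble::tibble(chrom = "chr1", start = c(0L, 400L, 800L),
                         end = c(501L, 901L, 1301L), score = c(30, 25, 20))
  expect_equal(iterative_removal(abc2)$score, c(30, 20))

  disjoint <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                             end = c(501L, 1501L), score = c(1, 2))
  expect_equal(iterative_removal(disjoint), disjoint)
})

test_that("iterative removal matches the naive oracle and is idempotent", {
  for (seed in 1:200) {
    inst <- random_peak_instance(n = sample(1:12, 1), seed = seed)
    got <- iterative_removal(inst)
    expect_equal(as.data.frame(got), as.data.frame(oracle_iterative_removal(inst)),
                 info = paste("seed", seed))
    expect_equal(iterative_removal(got), got)
    # survivors are pairwise non-overlapping
    if (nrow(got) > 1) {
      by_chrom <- split(got, got$chrom)
      for (g in by_chrom) {
        if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
  }
})

test_that("SPM normalization rescales scores to sum to one million", {
  expect_equal(spm_normalize(10), 1e6)
  expect_equal(spm_normalize(c(10, 10)), c(5e5, 5e5))
  expect_equal(spm_normalize(c(10, 30, 60)), c(1e5, 3e5, 6e5))
  expect_error(spm_normalize(c(0, 0)), "> 0")
  expect_error(spm_normalize(c(-1, 2)), ">= 0")

  withr::with_seed(2, {
    for (i in 1:20) {
      v <- runif(sample(1:50, 1), 0, 100)
      expect_equal(sum(spm_normalize(v)), 1e6, tolerance = 1e-9)
    }
  })

  # tibble form normalizes within each sample
  pk <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L, 0L),
                       end = c(501L, 1501L, 501L),
                       score = c(10, 30, 5),
                       sample_id = c("s1", "s1", "s2"))
  out <- spm_normalize(pk)
  expect_equal(out$spm, c(2.5e5, 7.5e5, 1e6))
})

test_that("replicate consensus applies the SPM >= 3 in >= 2 samples rule", {
  params <- consensus_params()

  # same locus in 2 of 3 samples, spm {5, 4}: retained with support 2
  samples <- list(
    peak_row("chr1", 1000, spm = 5, "s1"),
    peak_row("chr1", 1000, spm = 4, "s2"),
    peak_row("chr1", 50000, spm = 6, "s3")
  )
  cons <- replicate_consensus(samples, params)
  locus <- cons[cons$start == 1000, ]
  expect_equal(nrow(locus), 1L)
  expect_equal(locus$spm, 5)
  expect_equal(locus$support, 2L)

  # spm {5, 2.9}: only one qualifying sample, dropped
  weak <- list(
    peak_row("chr1", 1000, spm = 5, "s1"),
    peak_row("chr1", 1000, spm = 2.9, "s2")
  )
  expect_equal(nrow(replicate_consensus(weak, params)), 0L)

  # one sample with spm 50: support 1 < 2, dropped
  lone <- list(
    peak_row("chr1", 1000, spm = 50, "s1"),
    peak_row("chr1", 99000, spm = 50, "s2")
  )
  expect_equal(nrow(replicate_consensus(lone, params)), 0L)

  expect_error(replicate_consensus(list(peak_row("chr1", 0, 5, "s1")), params),
               "min_samples")
})

test_that("support requires >= 50% of the fixed width, not just any overlap", {
  params <- consensus_params()
  # offset 251 => intersection 250 bp < 251 required: no support from s2
  shifted <- list(
    peak_row("chr1", 1000, spm = 5, "s1"),
    peak_row("chr1", 1251, spm = 4, "s2")
  )
  expect_equal(nrow(replicate_consensus(shifted, params)), 0L)
  # offset 250 => intersection 251 bp: supported
  touching <- list(
    peak_row("chr1", 1000, spm = 5, "s1"),
    peak_row("chr1", 1250, spm = 4, "s2")
  )
  expect_equal(replicate_consensus(touching, params)$support, 2L)
})

test_that("replicate consensus is invariant to sample order", {
  cfg <- tiny_config(n_replicates = 3, conditions = "esc",
                     platforms = list(p = c(sub = .5, mono = .3, di = .15, other = .05)))
  truth <- sim_truth(cfg)
  pk <- lapply(1:3, function(i) {
    p <- simulate_peak_calls(simulate_fragments(cfg, i, truth), cfg, i)
    p <- suppressMessages(to_fixed_width(p, cfg$genome))
    spm_normalize(iterative_removal(p))
  })
  a <- replicate_consensus(pk)
  b <- replicate_consensus(pk[c(3, 1, 2)])
  cols <- c("chrom", "start", "end", "spm", "support")
  expect_equal(as.data.frame(a[cols]), as.data.frame(b[cols]))
})

test_that("merging consensus sets re-normalizes, removes overlaps, and records provenance", {
  one <- function(start, spm, extra = NULL) {
    p <- peak_row("chr1", start, spm, "x")
    if (!is.null(extra)) p <- dplyr::bind_rows(p, peak_row("chr1", 90000, extra, "x"))
    p
  }
  # identical single-peak sets: one survivor contributed by both
  m <- merge_consensus_sets(list(a = one(1000, 7), b = one(1000, 7)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$sources[[1]], c("a", "b"))

  # disjoint single-peak sets: two survivors, one source each
  m2 <- merge_consensus_sets(list(a = one(1000, 7), b = one(50000, 7)))
  expect_equal(nrow(m2), 2L)
  expect_equal(lengths(m2$sources), c(1L, 1L))

  # same locus, different re-normalized spm: higher instance survives, both contribute
  m3 <- merge_consensus_sets(list(a = one(1000, 9, extra = 1),
                                  b = one(1000, 6, extra = 4)))
  at_locus <- m3[m3$start == 1000, ]
  expect_equal(at_locus$set_label, "a")  # 9/10 of a's mass > 6/10 of b's
  expect_equal(at_locus$spm, 9e5)
  expect_equal(at_locus$sources[[1]], c("a", "b"))

  # re-normalization: each set's spm sums to 1e6 again after rescaling
  expect_equal(sum(spm_normalize(c(42, 13))), 1e6, tolerance = 1e-9)

  expect_error(merge_consensus_sets(list(a = one(0, 1)[0, ], b = one(0, 1))),
               "empty")
  expect_error(merge_consensus_sets(list(a = one(0, 1))), "at least 2")
})

test_that("build_consensus chains the stages and reports per-stage counts", {
  cfg <- tiny_config(n_replicates = 3, conditions = "esc",
                     platforms = list(p = c(sub = .5, mono = .3, di = .15, other = .05)))
  truth <- sim_truth(cfg)
  pk <- lapply(1:3, function(i) simulate_peak_calls(simulate_fragments(cfg, i, truth), cfg, i))
  names(pk) <- paste0("s", 1:3)
  cons <- suppressMessages(build_consensus(pk, cfg$genome, truth$blacklist))
  expect_s3_class(cons, "atac_consensus")
  expect_true(all(cons$end - cons$start == 501L))
  expect_true(all(cons$support >= 2L))
  expect_true(all(cons$spm >= 3))
  stage <- attr(cons, "stage_counts")
  expect_equal(nrow(stage), 3L)
  # counts never increase through the filtering stages
  expect_true(all(stage$n_fixed_width <= stage$n_called))
  expect_true(all(stage$n_blacklisted <= stage$n_fixed_width))
  expect_true(all(stage$n_after_removal <= stage$n_blacklisted))
  g <- glance(cons)
  expect_equal(g$n_peaks, nrow(cons))
})
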