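#' Configuration of the synthetic ATAC-seq experiment
#'
#' Describes a down-scaled multi-replicate, multi-platform chromatin
#' accessibility study: a small genome, planted accessible regions (some
#' shared between the two cell states, some state-specific), per-platform
#' insert-size mixtures, and a planted transcription-factor truth for the
#' motif-expression integration. All randomness flows from the single `seed`;
#' any sample is regenerable independently.
#'
#' Platform defaults encode the observed direction of the platform bias: the
#' BGI-like mixture carries 1.3x the sub-nucleosomal weight of the
#' Illumina-like mixture, which in turn carries 2.6x the di-nucleosomal
#' weight.
#'
#' @param genome Tibble with `chrom` and `length` (bp).
#' @param n_regions Number of planted accessible regions.
#' @param region_width Width of each planted region (bp).
#' @param n_replicates Biological replicates per condition and platform.
#' @param conditions Two cell-state labels.
#' @param platforms Named list of insert-size mixture weights, each a named
#'   numeric vector over `sub`, `mono`, `di`, `other` summing to 1.
#' @param depth Fragments per sample.
#' @param frip_target Probability that a fragment originates from a planted
#'   region.
#' @param noise_peak_rate Expected spurious low-score peaks per Mb.
#' @param background_rate Poisson background rate (fragment midpoints per bp)
#'   used by the window scorer; default derived as
#'   `(1 - frip_target) * depth / genome length`.
#' @param prop_shared Fraction of planted regions accessible in both
#'   conditions (the remainder split evenly between condition-specific sets).
#' @param intensity_sd Standard deviation (log scale) of the lognormal
#'   per-region accessibility intensity. Region strength heterogeneity is what
#'   places some regions near the reproducibility threshold, so that a small
#'   fraction of peaks is recovered by one replicate group but not another —
#'   the structure the shared/specific comparison quantifies.
#' @param prop_proximal Fraction of planted regions given a TSS (making them
#'   promoter-proximal).
#' @param n_master_tfs,n_decoy_tfs,n_background_genes Gene counts for the
#'   expression simulation.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param seed Root seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome = tibble(chrom = c("chr1", "chr2"),
                                       length = c(5e6, 5e6)),
                       n_regions = 400,
                       region_width = 400,
                       n_replicates = 3,
                       conditions = c("esc", "mef"),
                       platforms = list(
                         illumina = c(sub = 0.45, mono = 0.33, di = 0.13, other = 0.09),
                         bgi = c(sub = 0.585, mono = 0.315, di = 0.05, other = 0.05)
                       ),
                       depth = 50000,
                       frip_target = 0.6,
                       noise_peak_rate = 2,
                       background_rate = NULL,
                       prop_shared = 0.6,
                       prop_proximal = 0.3,
                       intensity_sd = 0.5,
                       n_master_tfs = 5,
                       n_decoy_tfs = 10,
                       n_background_genes = 200,
                       dispersion = 0.1,
                       seed = 1) {
  for (w in platforms) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9 ||
        !setequal(names(w), SIZE_CLASSES)) {
      abort("sim_config: each platform needs non-negative sub/mono/di/other weights summing to 1")
    }
  }
  if (frip_target <= 0 || frip_target >= 1) {
    abort("sim_config: frip_target must be in (0, 1)")
  }
  if (depth < 1) abort("sim_config: depth must be >= 1")
  cfg <- list(
    genome = genome, n_regions = n_regions, region_width = region_width,
    n_replicates = n_replicates, conditions = conditions,
    platforms = platforms, depth = depth, frip_target = frip_target,
    noise_peak_rate = noise_peak_rate,
    background_rate = background_rate %||%
      ((1 - frip_target) * depth / sum(genome$length)),
    prop_shared = prop_shared, prop_proximal = prop_proximal,
    intensity_sd = intensity_sd,
    n_master_tfs = n_master_tfs, n_decoy_tfs = n_decoy_tfs,
    n_background_genes = n_background_genes, dispersion = dispersion,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Sample sheet of a synthetic experiment
#'
#' @param config A [sim_config()].
#' @return A tibble with `sample_index`, `sample_id`, `condition`, `platform`,
#'   `replicate`.
#' @export
sim_samples <- function(config) {
  grid <- expand.grid(
    replicate = seq_len(config$n_replicates),
    platform = names(config$platforms),
    condition = config$conditions,
    stringsAsFactors = FALSE
  )
  tibble(
    sample_index = seq_len(nrow(grid)),
    sample_id = paste(grid$condition, grid$platform, grid$replicate, sep = "_"),
    condition = grid$condition,
    platform = grid$platform,
    replicate = grid$replicate
  )
}

# Deterministic sub-seed for a namespaced stage of the simulation.
sub_seed <- function(seed, stage, index = 0L) {
  offset <- c(truth = 11, fragments = 101, peaks = 211,
              annotation = 307, expression = 401, noise = 503)[[stage]]
  # double arithmetic: exact well past 2^31, avoids integer overflow
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 + offset +
                7919 * as.numeric(index)) %% 2147483647)
}

#' Planted ground truth of a synthetic experiment
#'
#' Plants non-overlapping accessible regions on the genome (each shared or
#' condition-specific), a blacklist of decoy regions, and the TF truth used by
#' the expression simulation.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with `regions` (tibble: `region_id`,
#'   `chrom`, `start`, `end`, `center`, `access` — `"shared"` or a condition
#'   label — and `intensity`, the region's relative accessibility weight),
#'   `blacklist`, and `tf_truth`.
#' @export
sim_truth <- function(config) {
  with_seed(sub_seed(config$seed, "truth"), {
    g <- config$genome
    rw <- config$region_width
    # candidate centers on a 2.5 kb grid, >= 2 kb from chromosome ends,
    # guaranteeing pairwise non-overlap and separation
    cand <- map_dfr(seq_len(nrow(g)), function(i) {
      centers <- seq(2000 + rw, g$length[i] - 2000 - rw, by = 2500)
      tibble(chrom = g$chrom[i], center = centers)
    })
    total_needed <- config$n_regions + 5L  # + blacklist decoys
    if (total_needed > nrow(cand)) {
      abort("sim_truth: genome too small for the requested number of regions")
    }
    picked <- cand[sort(sample.int(nrow(cand), total_needed)), , drop = FALSE]
    shuffle <- sample.int(total_needed)
    region_rows <- picked[shuffle[seq_len(config$n_regions)], , drop = FALSE]
    bl_rows <- picked[shuffle[(config$n_regions + 1L):total_needed], , drop = FALSE]

    n <- config$n_regions
    n_shared <- round(config$prop_shared * n)
    n_spec <- n - n_shared
    n_a <- n_spec %/% 2L
    access <- c(rep("shared", n_shared),
                rep(config$conditions[1], n_a),
                rep(config$conditions[length(config$conditions)], n_spec - n_a))
    if (length(config$conditions) == 1L) access <- rep("shared", n)
    access <- sample(access)

    regions <- region_rows |>
      mutate(
        region_id = paste0("region_", row_number()),
        start = as.integer(.data$center - rw %/% 2L),
        end = as.integer(.data$center + rw %/% 2L),
        access = access,
        intensity = stats::rlnorm(dplyr::n(), 0, config$intensity_sd)
      ) |>
      select("region_id", "chrom", "start", "end", "center", "access",
             "intensity") |>
      arrange(.data$chrom, .data$start)

    blacklist <- bl_rows |>
      mutate(start = as.integer(.data$center - 500L),
             end = as.integer(.data$center + 500L)) |>
      select("chrom", "start", "end") |>
      arrange(.data$chrom, .data$start)

    tf_truth <- tibble(
      tf_gene = c(paste0("MasterTF", seq_len(config$n_master_tfs)),
                  paste0("DecoyTF", seq_len(config$n_decoy_tfs))),
      role = c(rep("master", config$n_master_tfs),
               rep(c("decoy_low", "decoy_flat"),
                   length.out = config$n_decoy_tfs)),
    ) |>
      mutate(
        mean_target = dplyr::case_when(
          .data$role == "master" ~ 500,
          .data$role == "decoy_low" ~ 2,
          TRUE ~ 50
        ),
        mean_background = dplyr::case_when(
          .data$role == "master" ~ 1,
          .data$role == "decoy_low" ~ 2,
          TRUE ~ 50
        )
      )

    structure(list(regions = regions, blacklist = blacklist, tf_truth = tf_truth),
              class = "sim_truth")
  })
}

#' Simulate the fragments of one library
#'
#' Each fragment is placed near a planted accessible region of the sample's
#' condition with probability `frip_target` (centre Gaussian around the region
#' centre, sd = region width / 4) and uniformly on the genome otherwise. Its
#' length is drawn from the sample platform's size-class mixture: uniform on
#' 30-146 bp for the sub-nucleosomal class, truncated Gaussian(200, 20) on
#' 180-247 bp for mono-nucleosomal, truncated Gaussian(400, 30) on 315-473 bp
#' for di-nucleosomal, and uniform over the gap ranges otherwise.
#'
#' @param config A [sim_config()].
#' @param sample_index Row of [sim_samples()] to generate.
#' @param truth Optional pre-computed [sim_truth()] (recomputed from the
#'   config otherwise).
#' @return A fragment tibble (`chrom`, `start`, `end`, `length`) with the
#'   sample sheet row and the truth attached as attributes `sample` and
#'   `truth`.
#' @export
simulate_fragments <- function(config, sample_index, truth = NULL) {
  truth <- truth %||% sim_truth(config)
  samples <- sim_samples(config)
  if (sample_index < 1L || sample_index > nrow(samples)) {
    abort(sprintf("simulate_fragments: sample_index must be in 1..%d", nrow(samples)))
  }
  smp <- samples[sample_index, ]
  weights <- config$platforms[[smp$platform]][SIZE_CLASSES]
  acc <- truth$regions |>
    filter(.data$access %in% c("shared", smp$condition))
  g <- config$genome
  n <- config$depth

  frags <- with_seed(sub_seed(config$seed, "fragments", sample_index), {
    is_signal <- runif(n) < config$frip_target
    n_sig <- sum(is_signal)

    chrom <- character(n)
    center <- numeric(n)
    if (n_sig > 0L) {
      ridx <- sample.int(nrow(acc), n_sig, replace = TRUE, prob = acc$intensity)
      chrom[is_signal] <- acc$chrom[ridx]
      center[is_signal] <- round(rnorm(n_sig, acc$center[ridx], config$region_width / 4))
    }
    n_bg <- n - n_sig
    if (n_bg > 0L) {
      cidx <- sample.int(nrow(g), n_bg, replace = TRUE, prob = g$length)
      chrom[!is_signal] <- g$chrom[cidx]
      center[!is_signal] <- floor(runif(n_bg, 0, g$length[cidx]))
    }

    cls <- sample(SIZE_CLASSES, n, replace = TRUE, prob = weights)
    len <- integer(n)
    len[cls == "sub"] <- sample(30:146, sum(cls == "sub"), replace = TRUE)
    len[cls == "mono"] <- rtrunc_norm_int(sum(cls == "mono"), 200, 20, 180, 247)
    len[cls == "di"] <- rtrunc_norm_int(sum(cls == "di"), 400, 30, 315, 473)
    gap <- c(147:179, 248:314, 474:600)
    len[cls == "other"] <- sample(gap, sum(cls == "other"), replace = TRUE)

    chrom_len <- setNames(g$length, g$chrom)[chrom]
    half <- len %/% 2L
    center <- pmin(pmax(center, half), chrom_len - (len - half))
    tibble(
      chrom = chrom,
      start = as.integer(center - half),
      end = as.integer(center - half + len),
      length = len
    ) |>
      arrange(.data$chrom, .data$start)
  })
  attr(frags, "sample") <- smp
  attr(frags, "truth") <- truth
  frags
}

# Integer draws from a Gaussian truncated to [lo, hi] by rejection.
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  out <- round(rnorm(n, mean, sd))
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  as.integer(out)
}

#' Poisson-tail score of a window fragment count
#'
#' The window scorer used by [simulate_peak_calls()]: the score of a window
#' containing `k` fragment midpoints is `-log10 P(X >= k)` with
#' `X ~ Poisson(lambda)`; a window with `k = 0` scores 0.
#'
#' @param k Fragment midpoint count(s).
#' @param lambda Poisson mean (background rate times window width).
#' @return Score vector (>= 0).
#' @export
poisson_window_score <- function(k, lambda) {
  ifelse(k <= 0, 0, -ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10))
}

#' Simulate peak calls from a fragment set
#'
#' A deliberately simple windowed scorer standing in for an upstream peak
#' caller: 501 bp windows stepped by 100 bp are scored by the Poisson tail
#' probability of their fragment-midpoint count ([poisson_window_score()]);
#' windows scoring above 2 become candidate peaks with the summit at the
#' window's coverage maximum. Low-score noise peaks are injected at
#' `noise_peak_rate` per Mb with scores uniform on (2, 4]. Adjacent windows
#' overlap by construction, so downstream iterative removal is always
#' exercised.
#'
#' @param fragments A fragment tibble from [simulate_fragments()].
#' @param config A [sim_config()].
#' @param sample_index Index used for the sample label and the noise-peak
#'   seed.
#' @return A narrowPeak-shaped peak tibble (see [read_narrowpeak()]).
#' @export
simulate_peak_calls <- function(fragments, config, sample_index = 1L) {
  width <- 501L
  step <- 100L
  lambda <- config$background_rate * width
  sample_id <- sim_samples(config)$sample_id[sample_index]
  g <- config$genome

  calls <- map_dfr(seq_len(nrow(g)), function(ci) {
    chrom <- g$chrom[ci]
    clen <- g$length[ci]
    frags <- filter(fragments, .data$chrom == !!chrom)
    if (nrow(frags) == 0L) return(tibble())
    ws <- seq(0L, clen - width, by = step)
    mid <- (frags$start + frags$end) %/% 2L
    k <- GenomicRanges::countOverlaps(
      IRanges::IRanges(ws + 1L, ws + width),
      IRanges::IRanges(mid + 1L, mid + 1L)
    )
    score <- poisson_window_score(k, lambda)
    keep <- score > 2
    if (!any(keep)) return(tibble())
    ws <- ws[keep]
    cov <- IRanges::coverage(IRanges::IRanges(frags$start + 1L, frags$end), width = clen)
    summit1 <- IRanges::viewWhichMaxs(IRanges::Views(cov, ws + 1L, ws + width))
    tibble(
      chrom = chrom, start = ws, end = ws + width,
      signal = as.numeric(k[keep]), score = score[keep],
      summit = as.integer(summit1 - 1L)
    )
  })

  noise <- with_seed(sub_seed(config$seed, "noise", sample_index), {
    n_noise <- stats::rpois(1, config$noise_peak_rate * sum(g$length) / 1e6)
    if (n_noise == 0L) {
      tibble()
    } else {
      cidx <- sample.int(nrow(g), n_noise, replace = TRUE, prob = g$length)
      st <- floor(runif(n_noise, 0, g$length[cidx] - width))
      tibble(
        chrom = g$chrom[cidx], start = as.integer(st), end = as.integer(st + width),
        signal = 0, score = runif(n_noise, 2, 4),
        summit = as.integer(st + width %/% 2L)
      )
    }
  })

  out <- bind_rows(calls, noise) |>
    arrange(.data$chrom, .data$start) |>
    mutate(
      name = paste0(sample_id, "_pk", row_number()),
      display_score = pmin(1000, round(10 * .data$score)),
      strand = ".",
      qvalue = -1,
      sample_id = sample_id
    ) |>
    relocate("chrom", "start", "end", "name", "display_score", "strand",
             "signal", "score", "qvalue", "summit", "sample_id")
  out
}

#' Simulate the TSS and genomic-feature annotation
#'
#' Places a TSS at the centre of a fraction of the planted regions (making
#' those regions promoter-proximal) plus random extra TSS, and tiles a simple
#' gene model downstream of each TSS: promoter (+/- 1 kb around the TSS), then
#' 5'UTR, exon, intron, exon, 3'UTR blocks, strand-oriented and
#' non-overlapping within a gene.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-computed [sim_truth()].
#' @param n_extra_tss Number of additional TSS at random positions.
#' @return A list with `tss` (tibble: `gene_id`, `chrom`, `pos`, `strand`),
#'   `features` (tibble: `chrom`, `start`, `end`, `label`) and `blacklist`.
#' @export
simulate_annotation <- function(config, truth = NULL, n_extra_tss = 100) {
  truth <- truth %||% sim_truth(config)
  g <- config$genome
  with_seed(sub_seed(config$seed, "annotation"), {
    n_prox <- round(config$prop_proximal * nrow(truth$regions))
    prox <- truth$regions[sample.int(nrow(truth$regions), n_prox), , drop = FALSE]
    cidx <- sample.int(nrow(g), n_extra_tss, replace = TRUE, prob = g$length)
    extra_pos <- floor(runif(n_extra_tss, 5000, g$length[cidx] - 5000))
    tss <- tibble(
      gene_id = c(prox$region_id, paste0("gene_", seq_len(n_extra_tss))),
      chrom = c(prox$chrom, g$chrom[cidx]),
      pos = as.integer(c(prox$center, extra_pos)),
      strand = sample(c("+", "-"), n_prox + n_extra_tss, replace = TRUE)
    ) |>
      arrange(.data$chrom, .data$pos)

    blocks <- c(utr5 = 200L, exon = 300L, intron = 1000L, exon = 300L, utr3 = 300L)
    chrom_len <- setNames(g$length, g$chrom)
    features <- map_dfr(seq_len(nrow(tss)), function(i) {
      pos <- tss$pos[i]
      chrom <- tss$chrom[i]
      rows <- list(tibble(chrom = chrom,
                          start = max(0L, pos - 1000L),
                          end = min(chrom_len[[chrom]], pos + 1001L),
                          label = "promoter"))
      cursor <- pos + 1001L
      dir <- if (tss$strand[i] == "+") 1L else -1L
      if (dir < 0L) cursor <- pos - 1000L
      for (j in seq_along(blocks)) {
        w <- blocks[[j]]
        if (dir > 0L) {
          s <- cursor; e <- cursor + w; cursor <- e
        } else {
          e <- cursor; s <- cursor - w; cursor <- s
        }
        if (s >= 0L && e <= chrom_len[[chrom]]) {
          rows[[length(rows) + 1L]] <- tibble(chrom = chrom, start = as.integer(s),
                                              end = as.integer(e),
                                              label = names(blocks)[j])
        }
      }
      bind_rows(rows)
    }) |>
      arrange(.data$chrom, .data$start)

    list(tss = tss, features = features, blacklist = truth$blacklist)
  })
}

#' Simulate expression counts and a motif-enrichment table
#'
#' Negative-binomial expression counts per replicate for planted master TFs
#' (high mean in the target condition, near zero in the background), decoy TFs
#' (enriched motifs but low or flat expression) and background genes; plus a
#' motif table listing planted and decoy motifs with ascending FDR in
#' planted-first order (including redundant second motifs for some TFs).
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-computed [sim_truth()].
#' @return A list with `expression` (gene-by-sample count tibble), `motifs`
#'   (tibble: `motif_id`, `tf_gene`, `p_value`, `fdr`), and `conditions`
#'   (named vector mapping expression sample columns to conditions; the first
#'   configured condition is the integration target).
#' @export
simulate_expression <- function(config, truth = NULL) {
  truth <- truth %||% sim_truth(config)
  tf <- truth$tf_truth
  target <- config$conditions[1]
  background <- config$conditions[length(config$conditions)]
  with_seed(sub_seed(config$seed, "expression"), {
    bg_means <- exp(rnorm(config$n_background_genes, log(5000), 0.6))
    genes <- tibble(
      gene_id = c(tf$tf_gene, paste0("bg_gene_", seq_len(config$n_background_genes))),
      mean_target = c(tf$mean_target, bg_means),
      mean_background = c(tf$mean_background, bg_means)
    )
    size <- 1 / config$dispersion
    samples <- c(paste0(target, "_r", seq_len(config$n_replicates)),
                 paste0(background, "_r", seq_len(config$n_replicates)))
    conds <- setNames(rep(c(target, background), each = config$n_replicates), samples)
    expr <- genes["gene_id"]
    for (s in samples) {
      mu <- if (conds[[s]] == target) genes$mean_target else genes$mean_background
      expr[[s]] <- rnbinom(nrow(genes), mu = mu, size = size)
    }

    masters <- tf$tf_gene[tf$role == "master"]
    decoys <- tf$tf_gene[tf$role != "master"]
    primary <- tibble(
      tf_gene = c(masters, decoys),
      motif_id = paste0("motif_", c(masters, decoys)),
      fdr = c(10^-seq(16, 16 - length(masters) + 1),
              10^-seq(10, 2, length.out = length(decoys)))
    )
    redundant <- tibble(
      tf_gene = masters[seq_len(min(2L, length(masters)))],
      motif_id = paste0("motif_alt_", masters[seq_len(min(2L, length(masters)))]),
      fdr = 1e-4
    )
    motifs <- bind_rows(primary, redundant) |>
      mutate(p_value = .data$fdr / 2) |>
      arrange(.data$fdr, .data$motif_id) |>
      select("motif_id", "tf_gene", "p_value", "fdr")

    list(expression = as_tibble(expr), motifs = motifs, conditions = conds)
  })
}

#' Generate a complete synthetic experiment
#'
#' Runs every generator with a single root seed: truth, annotation, per-sample
#' fragments and peak calls, expression and motifs.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `samples`, `truth`, `tss`, `features`,
#'   `blacklist`, `fragments` (named list of tibbles), `peaks` (named list of
#'   narrowPeak-shaped tibbles), `expression`, `motifs`, `conditions`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  truth <- sim_truth(config)
  samples <- sim_samples(config)
  anno <- simulate_annotation(config, truth)
  fragments <- list()
  peaks <- list()
  for (i in samples$sample_index) {
    fr <- simulate_fragments(config, i, truth)
    fragments[[samples$sample_id[i]]] <- fr
    peaks[[samples$sample_id[i]]] <- simulate_peak_calls(fr, config, i)
  }
  ex <- simulate_expression(config, truth)
  list(
    config = config, samples = samples, truth = truth,
    tss = anno$tss, features = anno$features, blacklist = anno$blacklist,
    fragments = fragments, peaks = peaks,
    expression = ex$expression, motifs = ex$motifs, conditions = ex$conditions
  )
}

#' Write a synthetic experiment to disk
#'
#' Emits per-sample fragment BEDs and narrowPeak files plus TSS, feature,
#' blacklist, expression, motif and truth tables in the formats the readers in
#' this package consume.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(sim$fragments)) {
    fr <- sim$fragments[[sid]]
    writeLines(paste(fr$chrom, fr$start, fr$end, sep = "\t"),
               file.path(dir, paste0(sid, ".fragments.bed")))
    write_narrowpeak(sim$peaks[[sid]], file.path(dir, paste0(sid, ".narrowPeak")))
  }
  readr::write_tsv(sim$tss, file.path(dir, "tss.tsv"))
  readr::write_tsv(sim$features, file.path(dir, "features.tsv"))
  writeLines(paste(sim$blacklist$chrom, sim$blacklist$start, sim$blacklist$end, sep = "\t"),
             file.path(dir, "blacklist.bed"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$motifs, file.path(dir, "motifs.tsv"))
  readr::write_tsv(sim$truth$regions, file.path(dir, "truth_regions.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$config$genome, file.path(dir, "chrom_sizes.tsv"))
  invisible(dir)
}
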