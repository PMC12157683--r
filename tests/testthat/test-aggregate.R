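## Construct a toy locus: `n_reads` reads covering [0, len) on one
## chromosome, the first `n_fires` carrying a FIRE element [fs, fe).
toy_track <- function(n_reads, n_fires, ep, fs = 100L, fe = 300L,
                      len = 1000L, config = peak_config()) {
  ids <- sprintf("r%02d", seq_len(n_reads))
  ft <- fibers(fiber_id = ids, chrom = "chrT", ref_start = 0L,
               ref_end = len, haplotype = "UNK")
  msps <- data.table::data.table(
    fiber_id = ids[seq_len(n_fires)], start = fs, end = fe,
    ep = rep_len(ep, n_fires), is_fire = TRUE)
  fire_score_track(ft, msps, c(chrT = len), config)
}

test_that("the aggregate score evaluates the per-base formula exactly", {
  ## R = 10, C = 5, every EP = 0.99: S = -(50/10) * 5 * log10(0.01) = 50
  tr <- toy_track(10L, 5L, 0.99)
  expect_equal(tr$chroms$chrT$S[200], 50)

  ## saturation: all 10 reads carry FIRE elements at the EP cap -> exactly 100
  tr2 <- toy_track(10L, 10L, 0.99)
  expect_equal(tr2$chroms$chrT$S[200], 100)

  ## estimated precision above the cap is thresholded at 0.99
  tr3 <- toy_track(10L, 10L, 0.995)
  expect_equal(tr3$chroms$chrT$S[200], 100)

  ## fewer than four FIRE elements: sentinel -1
  tr4 <- toy_track(10L, 3L, 0.99)
  expect_equal(tr4$chroms$chrT$S[200], -1)
  ## outside every read there is nothing to score
  expect_equal(tr$chroms$chrT$S[1000], -1)
})

test_that("scores stay within the documented bounds", {
  set.seed(21)
  for (i in 1:20) {
    tr <- toy_track(sample(5:30, 1), sample(4:30, 1),
                    runif(1, 0.5, 1), len = 500L, fe = 400L)
    S <- tr$chroms$chrT$S
    expect_true(all(S == -1 | (S >= 0 & S <= 100)))
  }
})

test_that("coverage reliability uses the Poisson band around the median", {
  ## 30 uniform reads plus a 50-read pile on one interval
  ft1 <- fibers(fiber_id = sprintf("u%02d", 1:30), chrom = "chrT",
                ref_start = 0L, ref_end = 10000L)
  mask1 <- coverage_mask(ft1, c(chrT = 10000L))
  expect_true(all(mask1$chroms$chrT$reliable))

  ft2 <- fibers(fiber_id = c(sprintf("u%02d", 1:30), sprintf("p%02d", 1:50)),
                chrom = "chrT",
                ref_start = c(rep(0L, 30), rep(2000L, 50)),
                ref_end = c(rep(10000L, 30), rep(3000L, 50)))
  mask2 <- coverage_mask(ft2, c(chrT = 10000L))
  med <- mask2$median
  expect_equal(med, 30)
  ## |80 - 30| = 50 > 5 * sqrt(30) ~ 27.4
  expect_false(mask2$chroms$chrT$reliable[2500])
  ## a base at coverage 30 stays reliable
  expect_true(mask2$chroms$chrT$reliable[5000])
  expect_error(coverage_mask(ft2[0], c(chrT = 10000L)), "empty")
})

test_that("read shuffling preserves structure and respects the mask", {
  set.seed(33)
  n <- 150L
  lens <- sample(500:2000, n, replace = TRUE)
  starts <- sample(0:80000, n, replace = TRUE)
  ft <- fibers(fiber_id = sprintf("r%03d", 1:n), chrom = "chrT",
               ref_start = starts, ref_end = starts + lens,
               m6a = lapply(lens, function(L) sort(sample(0:(L - 1), 20))))
  cs <- c(chrT = 100000L)
  mask <- coverage_mask(ft, cs)
  sh1 <- shuffle_fibers(ft, cs, mask, seed = 9)
  sh2 <- shuffle_fibers(ft, cs, mask, seed = 9)
  expect_identical(sh1$ref_start, sh2$ref_start)       # seeded determinism
  expect_identical(sh1$ref_end - sh1$ref_start, lens)  # lengths kept
  expect_identical(sh1$m6a, ft$m6a)                    # internal structure

  ## mean coverage is conserved (read mass moves, it does not change)
  cov_of <- function(x) mean(fireseq:::interval_cover(x$ref_start,
                                                      x$ref_end, 100000L))
  expect_equal(cov_of(sh1), cov_of(ft), tolerance = 1e-12)

  ## reads starting on unreliable bases stay; others avoid unreliable bases
  rel <- mask$chroms$chrT$reliable
  if (any(!rel)) {
    frozen <- which(!rel[ft$ref_start + 1L])
    expect_identical(sh1$ref_start[frozen], ft$ref_start[frozen])
  }
})

test_that("reads pinned in unreliable territory are not moved", {
  ## a deliberate coverage spike makes its reads unreliable at origin
  ft <- fibers(fiber_id = c(sprintf("u%02d", 1:20), sprintf("p%02d", 1:60)),
               chrom = "chrT",
               ref_start = c(rep(0L, 20), rep(40000L, 60)),
               ref_end = c(rep(20000L, 20), rep(41000L, 60)))
  cs <- c(chrT = 100000L)
  mask <- coverage_mask(ft, cs)
  expect_false(all(mask$chroms$chrT$reliable))
  sh <- shuffle_fibers(ft, cs, mask, seed = 2)
  pinned <- startsWith(ft$fiber_id, "p")
  expect_identical(sh$ref_start[pinned], ft$ref_start[pinned])
  ## relocated reads never land on unreliable bases
  moved <- which(!pinned)
  rel <- mask$chroms$chrT$reliable
  for (i in moved) {
    span <- (sh$ref_start[i] + 1L):sh$ref_end[i]
    expect_true(all(rel[span]))
  }
})

test_that("the FDR table is the clamped, monotone null/observed ratio", {
  mk <- function(S) {
    structure(list(chroms = list(chrT = list(S = S)),
                   chrom_sizes = c(chrT = length(S))),
              class = "fire_track")
  }
  obs <- mk(c(rep(10, 100), rep(-1, 50)))
  nul <- mk(c(rep(10, 5), rep(-1, 145)))
  tab <- fdr_table(obs, nul)
  expect_equal(tab[threshold == 10, fdr], 0.05)  # 5 / 100

  ## no null bases above the top score
  tab2 <- fdr_table(mk(c(rep(5, 10), rep(9, 10))), mk(rep(5, 20)))
  expect_equal(tab2[threshold == 9, fdr], 0)
  ## clamped at 1 when the null dominates
  tab3 <- fdr_table(mk(rep(2, 10)), mk(rep(3, 50)))
  expect_equal(tab3[threshold == 2, fdr], 1)
  ## monotone non-increasing in score
  set.seed(5)
  tab4 <- fdr_table(mk(runif(500, 0, 50)), mk(runif(500, 0, 30)))
  expect_true(all(diff(tab4$fdr) <= 0))
  ## sentinel scores map to FDR 1
  expect_equal(fdr_lookup(tab4, -1), 1)
})

test_that("peak bounds are the medians of the supporting elements", {
  ## three FIRE elements with staggered bounds on ten covering reads
  ids <- sprintf("r%02d", 1:10)
  ft <- fibers(fiber_id = ids, chrom = "chrT", ref_start = 0L,
               ref_end = 1000L)
  msps <- data.table::data.table(
    fiber_id = ids[1:3], start = c(100L, 102L, 104L),
    end = c(300L, 310L, 320L), ep = 0.99, is_fire = TRUE)
  config <- peak_config(min_elements = 3L)
  tr <- fire_score_track(ft, msps, c(chrT = 1000L), config)
  tab <- fdr_table(tr, structure(list(
    chroms = list(chrT = list(S = rep(-1, 1000))),
    chrom_sizes = c(chrT = 1000L)), class = "fire_track"))
  pk <- call_peaks(tr, tab, config)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 102L)
  expect_equal(pk$end, 310L)
  expect_true(pk$start <= pk$summit && pk$summit < pk$end)
  expect_equal(pk$n_reads, 10L)
  expect_equal(pk$n_fires, 3L)
  expect_equal(pk$actuation, 0.3)
})

test_that("summit actuation counts reads carrying overlapping elements", {
  ids <- sprintf("r%02d", 1:10)
  ft <- fibers(fiber_id = ids, chrom = "chrT", ref_start = 0L,
               ref_end = 1000L)
  msps <- data.table::data.table(
    fiber_id = ids[1:5], start = 200L, end = 400L, ep = 0.99, is_fire = TRUE)
  tr <- fire_score_track(ft, msps, c(chrT = 1000L))
  tab <- fdr_table(tr, structure(list(
    chroms = list(chrT = list(S = rep(-1, 1000))),
    chrom_sizes = c(chrT = 1000L)), class = "fire_track"))
  pk <- call_peaks(tr, tab)
  expect_equal(pk$actuation, 0.5)
})

test_that("adjacent maxima sharing support merge into the higher summit", {
  ## two C = 4 plateaus separated by a C = 3 dip, sharing 3 of 4 elements
  ids <- sprintf("r%02d", 1:12)
  ft <- fibers(fiber_id = ids, chrom = "chrT", ref_start = 0L,
               ref_end = 2000L)
  msps <- data.table::data.table(
    fiber_id = ids[1:5],
    start = c(105L, 100L, 110L, 120L, 600L),
    end = c(905L, 900L, 910L, 500L, 920L),
    ep = 0.99, is_fire = TRUE)
  config <- peak_config(min_elements = 3L)
  tr <- fire_score_track(ft, msps, c(chrT = 2000L), config)
  expect_equal(max(tr$chroms$chrT$C), 4L)
  tab <- fdr_table(tr, structure(list(
    chroms = list(chrT = list(S = rep(-1, 2000))),
    chrom_sizes = c(chrT = 2000L)), class = "fire_track"))
  pk <- call_peaks(tr, tab, config)
  ## the two maxima share 3 elements, 75% of the smaller support: merged
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$n_fires, 4L)
})

test_that("wide peaks merge sub-FDR runs across sub-nucleosome gaps", {
  S <- rep(-1, 3000)
  S[101:200] <- 20; S[301:400] <- 20   # gap of 100 < 147
  S[1001:1100] <- 20                   # gap of 600 from the previous run
  track <- structure(list(chroms = list(chrT = list(S = S)),
                          chrom_sizes = c(chrT = 3000L)),
                     class = "fire_track")
  tab <- data.table::data.table(threshold = 20, n_obs = 300L, n_null = 0L,
                                fdr = 0)
  wp <- call_wide_peaks(data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0)),
    track, tab, peak_config())
  expect_equal(nrow(wp), 2L)
  expect_equal(wp$start, c(100L, 1000L))
  expect_equal(wp$end, c(400L, 1100L))

  ## with no sub-FDR bases the wide peaks equal the narrow peaks
  track0 <- structure(list(chroms = list(chrT = list(S = rep(-1, 3000))),
                           chrom_sizes = c(chrT = 3000L)),
                      class = "fire_track")
  narrow <- data.table::data.table(chrom = "chrT", start = 10L, end = 50L)
  wp0 <- call_wide_peaks(narrow, track0, tab, peak_config())
  expect_equal(wp0, narrow)
})

test_that("gap of one nucleosome or more keeps wide peaks apart", {
  S <- rep(-1, 1000)
  S[101:200] <- 20; S[348:400] <- 20   # gap exactly 147
  track <- structure(list(chroms = list(chrT = list(S = S)),
                          chrom_sizes = c(chrT = 1000L)),
                     class = "fire_track")
  tab <- data.table::data.table(threshold = 20, n_obs = 100L, n_null = 0L,
                                fdr = 0)
  wp <- call_wide_peaks(data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0)),
    track, tab, peak_config())
  expect_equal(nrow(wp), 2L)
})
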