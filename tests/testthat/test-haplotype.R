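test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  ## every 2x2 table with both row sums and both column sums <= 12
  for (a in 0:12) for (b in 0:(12 - a)) for (cc in 0:12) {
    for (d in 0:(12 - cc)) {
      if (a + cc > 12 || b + d > 12) next
      if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
      got <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      want <- oracle_fisher(a, b, cc, d)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the textbook step-up procedure", {
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- stats::p.adjust(p, method = "BH")
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    expect_true(all(q >= p))
  }
})

test_that("haplotype selectivity testing counts, tests and corrects", {
  ## complete separation: all 10 H1 reads actuated, none of 10 H2 reads
  fx <- mk_hsca_fixture(reads = 10L, p1 = 1, p2 = 0, seed = 1)
  h <- hsca_test(fx$peaks, fx$ft, fx$fires)
  expect_true(h$tested)
  expect_equal(h$reads_h1, 10L)
  expect_equal(h$fires_h1, 10L)
  expect_equal(h$fires_h2, 0L)
  expect_equal(h$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(h$diff_actuation, 1)
  expect_equal(h$q, h$p)

  ## identical actuation on both haplotypes: p = 1
  fx2 <- mk_hsca_fixture(reads = 10L, p1 = 1, p2 = 1, seed = 2)
  h2 <- hsca_test(fx2$peaks, fx2$ft, fx2$fires)
  expect_equal(h2$p, 1)

  ## nine reads on one haplotype: not tested
  fx3 <- mk_hsca_fixture(reads = 10L, p1 = 0.5, p2 = 0.5, seed = 3)
  drop_one <- fx3$ft[fx3$ft$fiber_id != "p1_H2_r01", ]
  data.table::setattr(drop_one, "class", class(fx3$ft))
  h3 <- hsca_test(fx3$peaks, drop_one, fx3$fires[fiber_id != "p1_H2_r01"])
  expect_false(h3$tested)
  expect_true(is.na(h3$p))
})

test_that("unphased reads never enter the haplotype counts", {
  fx <- mk_hsca_fixture(reads = 12L, p1 = 1, p2 = 1, seed = 4)
  ft <- data.table::copy(fx$ft)
  ft[fiber_id == "p1_H1_r01", haplotype := "UNK"]
  data.table::setattr(ft, "class", class(fx$ft))
  fires <- fireseq:::project_fires(
    ft, data.table::data.table(fiber_id = ft$fiber_id, start = 500L,
                               end = 2500L, ep = 0.97, is_fire = TRUE))
  h <- hsca_test(fx$peaks, ft, fires)
  expect_equal(h$reads_h1, 11L)
  expect_equal(h$reads_h2, 12L)
})

test_that("the haplotype null is calibrated and planted effects are found", {
  ## null: equal actuation, >= 20 seeds; fraction of q <= 0.05 stays <= 5%
  n_sig <- 0L; n_tot <- 0L
  for (s in 1:20) {
    fx <- mk_hsca_fixture(reads = 20L, p1 = 0.4, p2 = 0.4, n_peaks = 12L,
                          seed = 100 + s)
    h <- hsca_test(fx$peaks, fx$ft, fx$fires)
    n_sig <- n_sig + sum(h$q <= 0.05, na.rm = TRUE)
    n_tot <- n_tot + sum(h$tested)
  }
  expect_lte(n_sig / n_tot, 0.05)

  ## power: 0.8 vs 0.2 at 15 reads per haplotype, detected >= 80% of runs
  hits <- 0L; tot <- 0L
  for (s in 1:25) {
    fx <- mk_hsca_fixture(reads = 15L, p1 = 0.8, p2 = 0.2, n_peaks = 4L,
                          seed = 200 + s)
    h <- hsca_test(fx$peaks, fx$ft, fx$fires)
    hits <- hits + sum(h$q <= 0.05, na.rm = TRUE)
    tot <- tot + sum(h$tested)
  }
  expect_gte(hits / tot, 0.8)
})

test_that("window enrichment slides 100-peak windows per chromosome", {
  ## 200 peaks; the first 100 hold all the significant ones
  set.seed(31)
  peaks <- data.table::data.table(
    peak_id = sprintf("peak_%05d", 1:200), chrom = "chrT",
    start = seq(0L, by = 1000L, length.out = 200),
    end = seq(200L, by = 1000L, length.out = 200))
  hsca <- data.table::data.table(
    peak_id = peaks$peak_id, chrom = "chrT",
    p = c(rep(1e-6, 30), rep(0.9, 170)),
    q = c(rep(1e-4, 30), rep(0.95, 170)), tested = TRUE)
  we <- window_enrichment(peaks, hsca, window = 100L, slide = 10L)
  expect_equal(nrow(we), 11L)           # (200 - 100)/10 + 1
  expect_equal(we$n_peaks, rep(100L, 11))
  ## the first window concentrates every hit: smallest p of all windows
  expect_equal(which.min(we$p), 1L)
  expect_true(all(diff(we$n_sig) <= 0))
  ## with slide = window the windows are disjoint: floor(N/100) of them
  we2 <- window_enrichment(peaks, hsca, window = 100L, slide = 100L)
  expect_equal(nrow(we2), 2L)
  expect_warning(window_enrichment(peaks[1:50], hsca[1:50]), "fewer than")

  ## a window whose rate equals the genome-wide rate is not enriched
  hsca_u <- data.table::copy(hsca)
  hsca_u[, p := rep(c(1e-6, rep(0.9, 9)), 20)]
  hsca_u[, q := rep(c(1e-4, rep(0.95, 9)), 20)]
  we3 <- window_enrichment(peaks, hsca_u, window = 100L, slide = 100L)
  expect_equal(we3$n_sig, c(10L, 10L))
  expect_equal(we3$p, c(1, 1))
})

test_that("cosine similarity behaves on closed-form cases", {
  expect_equal(fireseq:::cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fireseq:::cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(fireseq:::cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_true(is.na(fireseq:::cosine_sim(c(0, 0), c(1, 1))))
})

test_that("windowed haplotype similarity labels intra- and inter-sample pairs", {
  set.seed(41)
  act <- matrix(runif(150 * 4), ncol = 4,
                dimnames = list(NULL, c("A.H1", "A.H2", "B.H1", "B.H2")))
  act[, 2] <- act[, 1] + rnorm(150, 0, 0.01)   # A's haplotypes nearly equal
  sim <- haplotype_similarity(act, sample_ids = c("A", "A", "B", "B"),
                              window = 100L, slide = 10L)
  expect_equal(length(unique(sim$win_id)), 6L)
  expect_equal(nrow(sim), 6L * 6L)
  expect_setequal(unique(sim$pair), c("intra", "inter"))
  aa <- sim[hap1 == "A.H1" & hap2 == "A.H2"]
  expect_true(all(aa$pair == "intra"))
  expect_true(all(aa$similarity > 0.99))
})

test_that("permutation enrichment is seeded and handles degenerate input", {
  cs <- c(chrT = 100000L)
  q <- data.table::data.table(chrom = "chrT",
                              start = c(1000L, 50000L), end = c(2000L, 51000L))
  ## annotation covering the whole genome: observed = null = 100%, p = 1
  whole <- data.table::data.table(chrom = "chrT", start = 0L, end = 100000L)
  res <- permutation_enrichment(q, whole, cs, n = 200L, seed = 1)
  expect_equal(res$observed, 100)
  expect_equal(res$p, 1)

  expect_warning(
    res0 <- permutation_enrichment(q, whole[0], cs, n = 10L, seed = 1),
    "empty annotation")
  expect_equal(res0$p, 1)

  ## a tight annotation around the queries: no null draw matches, p at floor
  ann <- data.table::data.table(chrom = "chrT",
                                start = c(1400L, 50400L), end = c(1600L, 50600L))
  r1 <- permutation_enrichment(q, ann, cs, n = 400L, seed = 7)
  r2 <- permutation_enrichment(q, ann, cs, n = 400L, seed = 7)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$observed, 100)
  expect_gte(r1$p, 1 / 401)
})

test_that("parent-of-origin consistency requires direction agreement", {
  mk <- function(q, d) data.table::data.table(site = "s1", q = q, diff = d)
  ## maternal skew in 11 of 13 samples, two untested
  tabs <- c(lapply(1:11, function(i) mk(0.01, 0.3)),
            lapply(1:2, function(i) mk(NA_real_, NA_real_)))
  poe <- consistent_poe(tabs, min_samples = 10L)
  expect_equal(nrow(poe), 1L)
  expect_equal(poe$direction, "maternal")
  expect_equal(poe$n_sig, 11L)

  ## direction conflict: 6 maternal vs 5 paternal
  tabs2 <- c(lapply(1:6, function(i) mk(0.01, 0.3)),
             lapply(1:5, function(i) mk(0.01, -0.3)))
  expect_equal(nrow(consistent_poe(tabs2, min_samples = 10L)), 0L)

  ## significant in only 9 samples
  tabs3 <- lapply(1:9, function(i) mk(0.01, 0.3))
  expect_equal(nrow(consistent_poe(tabs3, min_samples = 10L)), 0L)

  expect_error(consistent_poe(list(data.table::data.table(q = 1))),
               "orient haplotypes")
})

test_that("CpG methylation differences are percentages with a call floor", {
  mkf <- function(id, hap, meth) {
    mk_fiber(integer(0), len = 2000L, id = id, hap = hap,
             cpg_pos = seq(100L, 1000L, by = 100L),
             cpg_meth = rep(meth, 10L))
  }
  ft <- mk_fibers(mkf("a", "H1", 1L), mkf("b", "H2", 0L))
  peaks <- data.table::data.table(peak_id = "peak_00001", chrom = "chrT",
                                  start = 0L, end = 1500L)
  d <- cpg_hap_difference(ft, peaks)
  expect_equal(d$diff, 100)

  ## 8/10 methylated on H1 vs 2/10 on H2: +60 points
  f1 <- mk_fiber(integer(0), len = 2000L, id = "c", hap = "H1",
                 cpg_pos = seq(100L, 1000L, by = 100L),
                 cpg_meth = c(rep(1L, 8), rep(0L, 2)))
  f2 <- mk_fiber(integer(0), len = 2000L, id = "d", hap = "H2",
                 cpg_pos = seq(100L, 1000L, by = 100L),
                 cpg_meth = c(rep(1L, 2), rep(0L, 8)))
  d2 <- cpg_hap_difference(mk_fibers(f1, f2), peaks)
  expect_equal(d2$diff, 60)

  ## no CpG data: missing
  d3 <- cpg_hap_difference(mk_fibers(mk_fiber(integer(0), len = 2000L,
                                              id = "e", hap = "H1")), peaks)
  expect_true(is.na(d3$diff))

  ## fewer than five calls on one haplotype: missing
  f4 <- mk_fiber(integer(0), len = 2000L, id = "f", hap = "H2",
                 cpg_pos = c(100L, 200L), cpg_meth = c(1L, 0L))
  d4 <- cpg_hap_difference(mk_fibers(f1, f4), peaks)
  expect_true(is.na(d4$diff))
  expect_equal(d4$pct_meth_h1, 80)
})
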