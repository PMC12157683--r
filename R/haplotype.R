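#' Test peaks for haplotype-selective chromatin accessibility
#'
#' For every peak with at least `min_reads` haplotype-phased Fiber-seq reads
#' on both haplotypes at the summit, the difference in percent actuation
#' (fraction of reads carrying an overlapping FIRE element) between the two
#' haplotypes is tested with a two-sided Fisher's exact test on the 2x2
#' table `(fires_H1, reads_H1 - fires_H1; fires_H2, reads_H2 - fires_H2)`,
#' followed by Benjamini-Hochberg correction across all tested peaks.
#' Unphased (`UNK`) reads are excluded from the counts.
#'
#' @param peaks peaks from [call_peaks()].
#' @param ft a `fire_fibers` table.
#' @param fires reference-projected FIRE elements with a `haplotype` column
#'   (the `fires` component of a [fire_score_track()]).
#' @param min_reads minimum phased reads per haplotype (default 10).
#' @return `data.table` per peak: per-haplotype read and FIRE counts,
#'   actuations, `diff_actuation` (H1 - H2), `tested`, `p` and `q`.
#' @export
hsca_test <- function(peaks, ft, fires, min_reads = 10L) {
  if (!nrow(peaks))
    return(data.table(peak_id = character(0), chrom = character(0),
                      summit = integer(0), reads_h1 = integer(0),
                      reads_h2 = integer(0), fires_h1 = integer(0),
                      fires_h2 = integer(0), actuation_h1 = numeric(0),
                      actuation_h2 = numeric(0), diff_actuation = numeric(0),
                      tested = logical(0), p = numeric(0), q = numeric(0)))
  cnt <- function(tab, hap) {
    sub <- tab[haplotype == hap]
    overlap_count(peaks[, .(chrom, start = summit, end = summit + 1L)],
                  sub[, .(chrom, start, end)])
  }
  reads <- ft[, .(chrom, start = ref_start, end = ref_end, haplotype)]
  res <- peaks[, .(peak_id, chrom, summit)]
  res[, reads_h1 := cnt(reads, "H1")]
  res[, reads_h2 := cnt(reads, "H2")]
  res[, fires_h1 := cnt(fires, "H1")]
  res[, fires_h2 := cnt(fires, "H2")]
  res[, actuation_h1 := fifelse(reads_h1 > 0L, fires_h1 / reads_h1, NA_real_)]
  res[, actuation_h2 := fifelse(reads_h2 > 0L, fires_h2 / reads_h2, NA_real_)]
  res[, diff_actuation := actuation_h1 - actuation_h2]
  res[, tested := reads_h1 >= min_reads & reads_h2 >= min_reads]
  res[, p := NA_real_]
  ti <- which(res$tested)
  for (i in ti) {
    m <- matrix(c(res$fires_h1[i], res$reads_h1[i] - res$fires_h1[i],
                  res$fires_h2[i], res$reads_h2[i] - res$fires_h2[i]),
                nrow = 2L, byrow = TRUE)
    res$p[i] <- fisher.test(m)$p.value
  }
  res[, q := NA_real_]
  res$q[ti] <- p.adjust(res$p[ti], method = "BH")
  res[]
}

#' Windows enriched in haplotype-selective peaks
#'
#' Slides windows of `window` consecutive peaks (genomic order, per
#' chromosome, step `slide`; a terminal remainder shorter than `window` is
#' dropped) and Fisher-tests the count of nominally significant
#' haplotype-selective peaks in the window against the haplotype-selective
#' count in the rest of the genome (the window itself excluded), with BH
#' correction over windows.
#'
#' @param peaks peaks from [call_peaks()].
#' @param hsca result of [hsca_test()] on the same peaks.
#' @param window,slide window size and step, in peaks.
#' @param window_threshold nominal p-value threshold counting a peak as
#'   haplotype-selective inside a window.
#' @param genome_q_threshold BH q threshold defining the genome-wide
#'   haplotype-selective background count.
#' @return `data.table` per window: `chrom`, `start`, `end` (bp span of the
#'   window's peaks), `n_peaks`, `n_sig`, `p`, `q`.
#' @export
window_enrichment <- function(peaks, hsca, window = 100L, slide = 10L,
                              window_threshold = 0.05,
                              genome_q_threshold = 0.05) {
  x <- hsca[peaks[, .(peak_id, chrom, start, end)], on = c("peak_id", "chrom")]
  setorder(x, chrom, start)
  if (nrow(x) < window) {
    warning("fewer than ", window, " peaks; no windows formed")
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), n_peaks = integer(0),
                      n_sig = integer(0), p = numeric(0), q = numeric(0)))
  }
  sig_win <- !is.na(x$p) & x$p < window_threshold
  sig_gen <- !is.na(x$q) & x$q <= genome_q_threshold
  out <- list()
  for (ch in unique(x$chrom)) {
    rows <- which(x$chrom == ch)
    n <- length(rows)
    if (n < window) next
    first <- seq(1L, n - window + 1L, by = slide)
    for (s0 in first) {
      w <- rows[s0:(s0 + window - 1L)]
      a <- sum(sig_win[w])
      b <- window - a
      cc <- sum(sig_gen[-w])
      d <- nrow(x) - window - cc
      p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE))$p.value
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = min(x$start[w]), end = max(x$end[w]),
        n_peaks = window, n_sig = a, p = p)
    }
  }
  res <- rbindlist(out)
  res[, q := p.adjust(p, method = "BH")]
  res[]
}

cosine_sim <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) return(NA_real_)
  sum(v * w) / (nv * nw)
}

#' Windowed cosine similarity between haplotype actuation profiles
#'
#' Given percent-actuation vectors over a shared, genomically ordered peak
#' set for several haplotypes (e.g. two haplotypes from each of two
#' samples), computes the cosine similarity of every haplotype pair in
#' sliding windows of `window` peaks, and labels each pair intra-sample or
#' inter-sample.
#'
#' @param act numeric matrix, peaks (rows, genomic order) by haplotypes
#'   (named columns).
#' @param sample_ids character vector, the sample of each column.
#' @param window,slide window size and step, in peaks.
#' @return `data.table`: `win_id`, `first_peak`, `hap1`, `hap2`, `pair`
#'   (`"intra"` / `"inter"`), `similarity` (NA when a window vector is all
#'   zero).
#' @export
haplotype_similarity <- function(act, sample_ids, window = 100L, slide = 10L) {
  act <- as.matrix(act)
  stopifnot(ncol(act) == length(sample_ids), !is.null(colnames(act)))
  n <- nrow(act)
  if (n < window) stop("fewer peaks than the window size")
  first <- seq(1L, n - window + 1L, by = slide)
  cmb <- utils::combn(ncol(act), 2L)
  out <- list()
  for (wi in seq_along(first)) {
    rows <- first[wi]:(first[wi] + window - 1L)
    for (j in seq_len(ncol(cmb))) {
      c1 <- cmb[1L, j]; c2 <- cmb[2L, j]
      out[[length(out) + 1L]] <- data.table(
        win_id = wi, first_peak = first[wi],
        hap1 = colnames(act)[c1], hap2 = colnames(act)[c2],
        pair = if (sample_ids[c1] == sample_ids[c2]) "intra" else "inter",
        similarity = cosine_sim(act[rows, c1], act[rows, c2]))
    }
  }
  rbindlist(out)[]
}

#' Permutation test for annotation overlap of query windows
#'
#' The statistic is the percent of query windows intersecting the annotation
#' (>= 1 bp). The null relocates every window uniformly within its own
#' chromosome, preserving size, `n` times; optional `exclude` regions are
#' avoided by rejection sampling. The empirical p-value uses the +1
#' correction, `p = (1 + #null >= observed) / (1 + n)`, so it is never zero.
#'
#' @param query `data.table` of windows (`chrom`, `start`, `end`).
#' @param annotation `data.table` of annotation intervals.
#' @param chrom_sizes chromosome sizes.
#' @param n number of shuffles (default 10000).
#' @param seed integer seed.
#' @param exclude optional regions the shuffled windows must not overlap.
#' @return list: `observed` (percent), `p`, `null` (numeric vector of null
#'   percents).
#' @export
permutation_enrichment <- function(query, annotation, chrom_sizes, n = 10000L,
                                   seed = 1L, exclude = NULL) {
  cs <- as_chrom_sizes(chrom_sizes)
  query <- as.data.table(query)
  if (is.null(annotation) || !nrow(annotation)) {
    warning("empty annotation; p = 1 trivially")
    return(list(observed = 0, p = 1, null = rep(0, n)))
  }
  ann <- merge_regions(annotation)
  obs <- 100 * mean(overlap_any(query, ann))

  ## per-chromosome 0/1 coverage prefix sums for fast interval queries
  covcum <- lapply(names(cs), function(ch) {
    v <- interval_cover(ann[chrom == ch]$start, ann[chrom == ch]$end, cs[[ch]])
    c(0L, cumsum(as.integer(v > 0L)))
  })
  names(covcum) <- names(cs)
  exclcum <- if (!is.null(exclude) && nrow(exclude)) {
    ex <- merge_regions(as.data.table(exclude))
    setNames(lapply(names(cs), function(ch) {
      v <- interval_cover(ex[chrom == ch]$start, ex[chrom == ch]$end, cs[[ch]])
      c(0L, cumsum(as.integer(v > 0L)))
    }), names(cs))
  } else NULL

  set.seed(seed)
  lens <- query$end - query$start
  chq <- query$chrom
  Lq <- cs[chq]
  null <- numeric(n)
  for (it in seq_len(n)) {
    st <- floor(runif(nrow(query), 0, Lq - lens + 1))
    if (!is.null(exclcum)) {
      for (tries in seq_len(50L)) {
        bad <- vapply(seq_along(st), function(i) {
          e <- exclcum[[chq[i]]]
          (e[st[i] + lens[i] + 1L] - e[st[i] + 1L]) > 0L
        }, logical(1L))
        if (!any(bad)) break
        st[bad] <- floor(runif(sum(bad), 0, Lq[bad] - lens[bad] + 1))
      }
    }
    hit <- vapply(seq_along(st), function(i) {
      cc <- covcum[[chq[i]]]
      (cc[st[i] + lens[i] + 1L] - cc[st[i] + 1L]) > 0L
    }, logical(1L))
    null[it] <- 100 * mean(hit)
  }
  p <- (1 + sum(null >= obs)) / (1 + n)
  list(observed = obs, p = p, null = null)
}

#' Putative imprinted elements: consistent parent-of-origin skew
#'
#' Over the union of haplotype-selective sites across samples (haplotypes
#' oriented so that the actuation difference is maternal minus paternal),
#' retains sites significant in at least `min_samples` samples where every
#' significant sample is skewed in the same parental direction. Untested or
#' non-significant samples are neutral for the direction rule.
#'
#' @param hsca_by_sample `data.table` with columns `sample`, `site`, `q`,
#'   `diff` (maternal minus paternal actuation), or a named list of
#'   per-sample tables with `site`, `q`, `diff`.
#' @param min_samples minimum number of significant samples (default 10).
#' @param q_threshold significance level per sample.
#' @return `data.table`: `site`, `n_sig`, `direction` (`"maternal"` /
#'   `"paternal"`) for retained sites.
#' @export
consistent_poe <- function(hsca_by_sample, min_samples = 10L,
                           q_threshold = 0.05) {
  if (is.data.frame(hsca_by_sample)) x <- as.data.table(hsca_by_sample)
  else {
    if (is.null(names(hsca_by_sample)))
      names(hsca_by_sample) <- paste0("sample", seq_along(hsca_by_sample))
    x <- rbindlist(lapply(names(hsca_by_sample), function(s) {
      d <- as.data.table(hsca_by_sample[[s]])
      d[, sample := s]
      d
    }), fill = TRUE)
  }
  if (!all(c("site", "q", "diff") %in% names(x)))
    stop("expected columns site, q, diff (maternal minus paternal); ",
         "orient haplotypes before calling")
  sig <- x[!is.na(q) & q <= q_threshold & diff != 0]
  res <- sig[, .(n_sig = .N,
                 n_mat = sum(diff > 0), n_pat = sum(diff < 0)), by = site]
  res <- res[n_sig >= min_samples & (n_mat == 0L | n_pat == 0L)]
  res[, direction := fifelse(n_mat > 0L, "maternal", "paternal")]
  res[, .(site, n_sig, direction)][]
}

#' Haplotype difference in percent CpG methylation over peaks
#'
#' For each peak, the percent of methylated CpG calls among all CpG calls
#' overlapping the peak interval is computed per haplotype; the difference
#' (H1 minus H2, in percentage points) is reported. Peaks with fewer than
#' `min_calls` CpG calls on either haplotype are returned as missing.
#'
#' @param ft a `fire_fibers` table carrying CpG calls.
#' @param peaks peaks from [call_peaks()].
#' @param min_calls minimum CpG calls per haplotype (default 5).
#' @return `data.table`: `peak_id`, per-haplotype call counts and percent
#'   methylation, and `diff` in percentage points.
#' @export
cpg_hap_difference <- function(ft, peaks, min_calls = 5L) {
  cpg <- rbindlist(lapply(seq_len(nrow(ft)), function(i) {
    cp <- ft$cpg_pos[[i]]
    if (!length(cp)) return(NULL)
    data.table(chrom = ft$chrom[i], pos = ft$ref_start[i] + cp,
               meth = ft$cpg_meth[[i]], haplotype = ft$haplotype[i])
  }))
  res <- peaks[, .(peak_id, chrom, start, end)]
  res[, `:=`(n_cpg_h1 = 0L, n_cpg_h2 = 0L,
             pct_meth_h1 = NA_real_, pct_meth_h2 = NA_real_)]
  if (nrow(cpg)) {
    for (i in seq_len(nrow(res))) {
      sel <- cpg[chrom == res$chrom[i] & pos >= res$start[i] &
                   pos < res$end[i]]
      h1 <- sel[haplotype == "H1"]$meth
      h2 <- sel[haplotype == "H2"]$meth
      res$n_cpg_h1[i] <- length(h1)
      res$n_cpg_h2[i] <- length(h2)
      if (length(h1) >= min_calls) res$pct_meth_h1[i] <- 100 * mean(h1)
      if (length(h2) >= min_calls) res$pct_meth_h2[i] <- 100 * mean(h2)
    }
  }
  res[, diff := pct_meth_h1 - pct_meth_h2]
  res[, .(peak_id, n_cpg_h1, n_cpg_h2, pct_meth_h1, pct_meth_h2, diff)][]
}
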