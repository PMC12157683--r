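#' X-chromosome inactivation analysis configuration
#'
#' @param max_cov_dev maximum fractional deviation of a peak's read coverage
#'   from the mean coverage over the peak set (0.25).
#' @param max_unphased maximum fraction of unphased reads at a peak (0.35).
#' @param min_hap_cov minimum phased read coverage per haplotype (10).
#' @param min_actuation minimum actuation on at least one haplotype for
#'   eligibility (0.30).
#' @param specific_diff actuation difference classifying a peak as
#'   Xa- or Xi-specific (0.50).
#' @param escape_diff actuation difference below which an accessible-on-Xi
#'   TSS is fully escaping (0.25).
#' @param tss_pad width, in bp, to which TSS annotations are padded (20).
#' @param escape_bin,escape_max distance bin width and maximum distance for
#'   the promoter-proximal escape profile (5 kb bins to 100 kb).
#' @param footprint_max_m6a maximum m6A count inside a motif for a
#'   protein-bound call (1).
#' @return list of class `fire_xci_config`.
#' @export
xci_config <- function(max_cov_dev = 0.25, max_unphased = 0.35,
                       min_hap_cov = 10L, min_actuation = 0.30,
                       specific_diff = 0.50, escape_diff = 0.25,
                       tss_pad = 20L, escape_bin = 5000L,
                       escape_max = 100000L, footprint_max_m6a = 1L) {
  structure(list(max_cov_dev = max_cov_dev, max_unphased = max_unphased,
                 min_hap_cov = as.integer(min_hap_cov),
                 min_actuation = min_actuation, specific_diff = specific_diff,
                 escape_diff = escape_diff, tss_pad = as.integer(tss_pad),
                 escape_bin = as.integer(escape_bin),
                 escape_max = as.integer(escape_max),
                 footprint_max_m6a = as.integer(footprint_max_m6a)),
            class = "fire_xci_config")
}

## Pad every interval to at least `width` bp, centered.
pad_to_width <- function(bed, width) {
  b <- as.data.table(bed)
  ctr <- floor((b$start + b$end) / 2)
  half <- width %/% 2L
  b[, `:=`(start = pmax(0L, as.integer(ctr - half)),
           end = as.integer(ctr - half + width))]
  b[]
}

#' Filter X-chromosome peaks for XCI analysis
#'
#' Drops peaks overlapping the blacklist; requires read coverage within
#' `max_cov_dev` of the mean coverage over the peak set, an unphased-read
#' fraction below `max_unphased`, at least `min_hap_cov` phased reads on
#' each haplotype, and actuation of at least `min_actuation` on the Xa
#' and/or the Xi. Eligible peaks are tagged `is_tss` (intersecting both the
#' padded TSS annotation and a CAGE peak) and `is_ctcf`. Which haplotype is
#' the Xa is a per-sample mapping (`hap_map`); nothing is hard-coded.
#'
#' @param peaks peaks from [call_peaks()].
#' @param ft a `fire_fibers` table.
#' @param fires reference-projected FIRE elements with haplotype (the
#'   `fires` component of a [fire_score_track()]).
#' @param blacklist,tss,cage,ctcf BED-like annotation tables (`chrom`,
#'   `start`, `end`); `NULL` disables the corresponding tag/filter.
#' @param hap_map named character vector mapping `H1`/`H2` to `Xa`/`Xi`.
#' @param config a [xci_config()].
#' @return eligible peaks with `actuation_xa`, `actuation_xi`, `reads_xa`,
#'   `reads_xi`, `frac_unphased`, `is_tss`, `is_ctcf`.
#' @export
filter_x_peaks <- function(peaks, ft, fires, blacklist = NULL, tss = NULL,
                           cage = NULL, ctcf = NULL,
                           hap_map = c(H1 = "Xa", H2 = "Xi"),
                           config = xci_config()) {
  stopifnot(setequal(names(hap_map), c("H1", "H2")),
            setequal(unname(hap_map), c("Xa", "Xi")))
  x <- hsca_test(peaks, ft, fires, min_reads = config$min_hap_cov)
  x <- peaks[, .(peak_id, chrom, start, end, summit, n_reads)][x,
    on = c("peak_id", "chrom", "summit")]
  xa_h <- names(hap_map)[hap_map == "Xa"]
  if (xa_h == "H1") {
    x[, `:=`(actuation_xa = actuation_h1, actuation_xi = actuation_h2,
             reads_xa = reads_h1, reads_xi = reads_h2)]
  } else {
    x[, `:=`(actuation_xa = actuation_h2, actuation_xi = actuation_h1,
             reads_xa = reads_h2, reads_xi = reads_h1)]
  }
  x[, frac_unphased := pmax(0, n_reads - reads_h1 - reads_h2) / n_reads]

  keep <- rep(TRUE, nrow(x))
  if (!is.null(blacklist) && nrow(blacklist))
    keep <- keep & !overlap_any(x[, .(chrom, start, end)],
                                as.data.table(blacklist))
  mean_cov <- mean(x$n_reads)
  keep <- keep & abs(x$n_reads - mean_cov) / mean_cov <= config$max_cov_dev
  keep <- keep & x$frac_unphased < config$max_unphased
  keep <- keep & x$reads_xa >= config$min_hap_cov &
    x$reads_xi >= config$min_hap_cov
  keep <- keep & (pmax(x$actuation_xa, x$actuation_xi) >= config$min_actuation)
  x <- x[keep]

  x[, is_tss := FALSE]
  if (!is.null(tss) && nrow(tss)) {
    padded <- pad_to_width(tss, config$tss_pad)
    hit_tss <- overlap_any(x[, .(chrom, start, end)], padded)
    hit_cage <- if (!is.null(cage) && nrow(cage))
      overlap_any(x[, .(chrom, start, end)], as.data.table(cage))
    else rep(TRUE, nrow(x))
    x[, is_tss := hit_tss & hit_cage]
  }
  x[, is_ctcf := if (!is.null(ctcf) && nrow(ctcf))
    overlap_any(x[, .(chrom, start, end)], as.data.table(ctcf))
    else FALSE]
  x[]
}

#' Classify X-chromosome peaks by XCI status
#'
#' A peak with an actuation difference of at least `specific_diff` (50
#' percentage points) between haplotypes is `Xa_specific` or `Xi_specific`
#' according to which haplotype carries the higher actuation, provided that
#' haplotype is actuated on at least `min_actuation` (30%) of its reads.
#' Peaks actuated on at least 30% of reads on one or both haplotypes with a
#' smaller difference are `shared`; anything else is `unclassified`. For TSS
#' peaks an escape status is added: `inactivated` when Xi actuation is below
#' 30%; `fully_escaping` when Xi actuation is at least 30% and the
#' difference is below `escape_diff` (25 points); `intermediate` otherwise.
#'
#' @param xpeaks output of [filter_x_peaks()] (needs `actuation_xa`,
#'   `actuation_xi` and, for escape calls, `is_tss`).
#' @param config a [xci_config()].
#' @return `xpeaks` with added columns `xci_class` and `escape` (NA for
#'   non-TSS peaks).
#' @export
classify_xci <- function(xpeaks, config = xci_config()) {
  x <- as.data.table(copy(xpeaks))
  xa <- x$actuation_xa; xi <- x$actuation_xi
  d <- abs(xa - xi)
  hi <- pmax(xa, xi)
  cls <- rep("unclassified", nrow(x))
  spec <- d >= config$specific_diff & hi >= config$min_actuation
  cls[spec & xa > xi] <- "Xa_specific"
  cls[spec & xi > xa] <- "Xi_specific"
  cls[!spec & hi >= config$min_actuation] <- "shared"
  x[, xci_class := cls]
  esc <- rep(NA_character_, nrow(x))
  if ("is_tss" %in% names(x)) {
    tssrow <- which(x$is_tss)
    esc[tssrow] <- fifelse(xi[tssrow] < config$min_actuation, "inactivated",
                           fifelse(d[tssrow] < config$escape_diff,
                                   "fully_escaping", "intermediate"))
  }
  x[, escape := esc]
  x[]
}

#' Promoter-proximal escape profile
#'
#' For TSS peaks grouped by escape status, counts escaping non-TSS peaks in
#' `escape_bin`-wide bins of absolute summit-to-summit distance up to
#' `escape_max` (half-open bin edges; a peak at exactly the maximum distance
#' is excluded), normalized by the number of TSSs in the group.
#'
#' @param tss_peaks classified TSS peaks (with `escape` and `summit`).
#' @param nontss_escaping non-TSS peaks that escape XCI (with `summit`).
#' @param config a [xci_config()].
#' @return `data.table`: `group`, `bin_start`, `bin_end`, `normalized_count`.
#' @export
proximal_escape_profile <- function(tss_peaks, nontss_escaping,
                                    config = xci_config()) {
  nb <- config$escape_max %/% config$escape_bin
  edges <- seq(0L, config$escape_max, by = config$escape_bin)
  groups <- unique(tss_peaks$escape)
  groups <- groups[!is.na(groups)]
  out <- list()
  for (g in groups) {
    tssg <- tss_peaks[escape == g]
    counts <- numeric(nb)
    if (!nrow(tssg)) warning("empty TSS group: ", g)
    if (nrow(tssg) && nrow(nontss_escaping)) {
      for (i in seq_len(nrow(tssg))) {
        d <- abs(nontss_escaping[chrom == tssg$chrom[i]]$summit -
                   tssg$summit[i])
        d <- d[d < config$escape_max]
        if (length(d))
          counts <- counts + tabulate(d %/% config$escape_bin + 1L,
                                      nbins = nb)
      }
    }
    out[[g]] <- data.table(group = g, bin_start = edges[-(nb + 1L)],
                           bin_end = edges[-1L],
                           normalized_count = if (nrow(tssg))
                             counts / nrow(tssg) else counts)
  }
  rbindlist(out)[]
}

#' Per-molecule protein occupancy at motifs
#'
#' For every (FIRE element, motif) pair in which the element completely
#' overlaps the motif sub-interval, counts the fiber's m6A marks inside the
#' motif; the motif is called protein-bound on that fiber when the count is
#' at most `footprint_max_m6a` (default 1). Pairs with partial overlap (in
#' particular motifs wider than the element) are excluded and counted.
#'
#' @param fires reference-projected FIRE elements (`fiber_id`, `chrom`,
#'   `start`, `end`).
#' @param motifs motif sub-intervals (`chrom`, `start`, `end`, optional
#'   `motif_id`).
#' @param ft the `fire_fibers` table the elements come from.
#' @param config a [xci_config()].
#' @return `data.table` per retained pair: `fiber_id`, `motif_id`,
#'   `n_m6a_in_motif`, `bound`; the number of excluded partial-overlap pairs
#'   is in attribute `n_excluded`. Per-motif occupancy via
#'   [motif_occupancy()].
#' @export
motif_footprint <- function(fires, motifs, ft, config = xci_config()) {
  mo <- as.data.table(motifs)
  if (!"motif_id" %in% names(mo))
    mo[, motif_id := sprintf("motif_%03d", seq_len(.N))]
  f <- as.data.table(fires)[, .(fiber_id, chrom, fs = start, fe = end - 1L)]
  m <- mo[, .(motif_id, chrom, ms = start, me = end - 1L)]
  setkey(m, chrom, ms, me)
  hits <- foverlaps(f, m, by.x = c("chrom", "fs", "fe"), nomatch = NULL)
  full <- hits[fs <= ms & fe >= me]
  n_excluded <- nrow(hits) - nrow(full)
  if (!nrow(full)) {
    res <- data.table(fiber_id = character(0), motif_id = character(0),
                      n_m6a_in_motif = integer(0), bound = logical(0))
    setattr(res, "n_excluded", n_excluded)
    return(res[])
  }
  fi <- match(full$fiber_id, ft$fiber_id)
  cnt <- integer(nrow(full))
  for (i in seq_len(nrow(full))) {
    marks <- ft$m6a[[fi[i]]] + ft$ref_start[fi[i]]
    cnt[i] <- count_in(marks, full$ms[i], full$me[i] + 1L)
  }
  res <- data.table(fiber_id = full$fiber_id, motif_id = full$motif_id,
                    n_m6a_in_motif = cnt,
                    bound = cnt <= config$footprint_max_m6a)
  setattr(res, "n_excluded", n_excluded)
  res[]
}

#' Percent occupancy per motif
#' @param fp output of [motif_footprint()].
#' @return `data.table`: `motif_id`, `n_bound`, `n_total`, `pct_occupancy`.
#' @export
motif_occupancy <- function(fp) {
  fp[, .(n_bound = sum(bound), n_total = .N,
         pct_occupancy = 100 * mean(bound)), by = motif_id][]
}
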