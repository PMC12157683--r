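#' Peak calling configuration
#'
#' @param fdr_threshold FDR cutoff for candidate summits and wide-peak bases.
#' @param min_actuation minimum fraction of covering reads that must carry an
#'   overlapping FIRE element at the summit.
#' @param elem_share fraction of shared supporting FIRE elements (of the
#'   smaller support set) at which adjacent local maxima merge.
#' @param reciprocal_overlap reciprocal overlap of preliminary peak bounds at
#'   which adjacent local maxima merge.
#' @param wide_merge_bp wide peaks merge across gaps smaller than one
#'   nucleosome (147 bp).
#' @param min_elements positions covered by fewer FIRE elements than this are
#'   left unscored (sentinel -1).
#' @param ep_cap estimated precision is capped here before entering the
#'   score, bounding the score at 100.
#' @param coverage_sd_mult reliability band half-width in Poisson standard
#'   deviations around the median coverage.
#' @return list of class `fire_peak_config`.
#' @export
peak_config <- function(fdr_threshold = 0.05, min_actuation = 0.10,
                        elem_share = 0.50, reciprocal_overlap = 0.90,
                        wide_merge_bp = 147L, min_elements = 4L,
                        ep_cap = 0.99, coverage_sd_mult = 5) {
  structure(list(fdr_threshold = fdr_threshold, min_actuation = min_actuation,
                 elem_share = elem_share, reciprocal_overlap = reciprocal_overlap,
                 wide_merge_bp = as.integer(wide_merge_bp),
                 min_elements = as.integer(min_elements),
                 ep_cap = ep_cap, coverage_sd_mult = coverage_sd_mult),
            class = "fire_peak_config")
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- setNames(as.integer(chrom_sizes[[2L]]),
                            as.character(chrom_sizes[[1L]]))
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  chrom_sizes
}

## Per-base coverage of [start, end) intervals on a chromosome of length L.
interval_cover <- function(starts, ends, L) {
  d <- integer(L + 1L)
  if (length(starts)) {
    a <- tabulate(starts + 1L, nbins = L + 1L)
    b <- tabulate(ends + 1L, nbins = L + 1L)
    d <- a - b
  }
  cumsum(d)[seq_len(L)]
}

## Per-base sum of weights of covering [start, end) intervals.
weighted_cover <- function(starts, ends, w, L) {
  out <- numeric(L)
  if (!length(starts)) return(out)
  d <- numeric(L + 1L)
  a <- rowsum(c(w, -w), c(starts + 1L, ends + 1L))
  ix <- as.integer(rownames(a))
  keep <- ix <= L + 1L
  d[ix[keep]] <- a[keep, 1L]
  cumsum(d)[seq_len(L)]
}

#' Read coverage and reliability mask
#'
#' Computes per-base Fiber-seq read coverage and flags bases whose coverage
#' deviates from the genome-wide median (over covered bases) by more than
#' `coverage_sd_mult` Poisson standard deviations, `sqrt(median)`.
#'
#' @param ft a `fire_fibers` table.
#' @param chrom_sizes named integer vector (or two-column table) of
#'   chromosome sizes.
#' @param config a [peak_config()].
#' @return list of class `fire_mask`: per chromosome `R` (coverage) and
#'   `reliable` (logical), plus the genome-wide `median`.
#' @export
coverage_mask <- function(ft, chrom_sizes, config = peak_config()) {
  if (!nrow(ft)) stop("empty fiber table")
  cs <- as_chrom_sizes(chrom_sizes)
  chroms <- lapply(names(cs), function(ch) {
    f <- ft[chrom == ch]
    R <- interval_cover(f$ref_start, f$ref_end, cs[[ch]])
    list(R = R)
  })
  names(chroms) <- names(cs)
  allR <- unlist(lapply(chroms, `[[`, "R"), use.names = FALSE)
  med <- median(allR[allR > 0L])
  band <- config$coverage_sd_mult * sqrt(med)
  for (ch in names(cs))
    chroms[[ch]]$reliable <- abs(chroms[[ch]]$R - med) <= band
  structure(list(chroms = chroms, median = med, band = band,
                 chrom_sizes = cs), class = "fire_mask")
}

## Project FIRE elements (fiber-relative MSPs) to reference coordinates.
## Reads are gapless, so projection is a shift by ref_start.
project_fires <- function(ft, msps) {
  ref <- ft[, .(fiber_id, chrom, ref_start, haplotype)]
  x <- ref[msps, on = "fiber_id"]
  x[, `:=`(start = ref_start + start, end = ref_start + end)]
  x[, ref_start := NULL]
  x[, element_id := seq_len(.N)]
  x[]
}

#' Aggregate FIRE score track
#'
#' For every base `g`, with `R_g` covering reads, `C_g` covering FIRE
#' elements and estimated precisions `EP_i`, the score is
#' `S_g = -(50 / R_g) * sum_i log10(1 - min(EP_i, ep_cap))`.
#' With the default cap of 0.99 each element contributes at most
#' `2 * 50 / R_g`, so the score lies in `[0, 100]`. Positions covered by
#' fewer than `min_elements` (default 4) FIRE elements are not scored and
#' carry the sentinel value -1. Only MSPs flagged `is_fire` contribute.
#'
#' @param ft a `fire_fibers` table.
#' @param msps classified MSPs (from [classify_msps()]), with `ep` and
#'   `is_fire`.
#' @param chrom_sizes chromosome sizes.
#' @param config a [peak_config()].
#' @return list of class `fire_track`: per chromosome `R`, `C`, `S`; plus the
#'   reference-projected FIRE element table (`fires`).
#' @export
fire_score_track <- function(ft, msps, chrom_sizes, config = peak_config()) {
  stopifnot(all(c("ep", "is_fire") %in% names(msps)))
  cs <- as_chrom_sizes(chrom_sizes)
  fires <- project_fires(ft, msps[is_fire == TRUE])
  chroms <- vector("list", length(cs))
  names(chroms) <- names(cs)
  for (ch in names(cs)) {
    L <- cs[[ch]]
    f <- ft[chrom == ch]
    R <- interval_cover(f$ref_start, f$ref_end, L)
    fe <- fires[chrom == ch]
    C <- interval_cover(fe$start, fe$end, L)
    lsum <- weighted_cover(fe$start, fe$end,
                           -log10(1 - pmin(fe$ep, config$ep_cap)), L)
    if (any(C > 0L & R == 0L))
      stop("internal error: FIRE coverage exceeds read coverage")
    S <- numeric(L)
    scored <- C >= config$min_elements
    S[scored] <- (50 / R[scored]) * lsum[scored]
    S[!scored] <- -1
    chroms[[ch]] <- list(R = R, C = C, S = S)
  }
  structure(list(chroms = chroms, chrom_sizes = cs, fires = fires,
                 config = config), class = "fire_track")
}

#' Shuffle fiber positions to build an empirical null
#'
#' Relocates each read to a uniformly drawn start position on its own
#' chromosome, preserving read length and all internal structure (m6A
#' offsets are fiber-relative and move with the read). Reads whose start
#' base lies in a region of unreliable coverage are left in place, and
#' relocated reads are rejection-sampled so they do not land on unreliable
#' bases; a read that cannot be placed after `max_tries` draws keeps its
#' original position and is counted in the `n_unplaced` attribute.
#'
#' @param ft a `fire_fibers` table.
#' @param chrom_sizes chromosome sizes.
#' @param mask a [coverage_mask()].
#' @param seed integer seed; identical seeds give identical placements.
#' @param max_tries rejection-sampling cap per read.
#' @return a `fire_fibers` table with new `ref_start` / `ref_end`.
#' @export
shuffle_fibers <- function(ft, chrom_sizes, mask, seed = 1L, max_tries = 50L) {
  cs <- as_chrom_sizes(chrom_sizes)
  set.seed(seed)
  out <- copy(ft)
  n_unplaced <- 0L
  for (ch in names(cs)) {
    L <- cs[[ch]]
    rows <- which(out$chrom == ch)
    if (!length(rows)) next
    rel <- mask$chroms[[ch]]$reliable
    bad_cum <- c(0L, cumsum(!rel))
    lens <- out$ref_end[rows] - out$ref_start[rows]
    keep_put <- !rel[out$ref_start[rows] + 1L]   # reads originating in
    new_start <- out$ref_start[rows]             # unreliable regions stay
    todo <- which(!keep_put & lens <= L)
    tries <- 0L
    while (length(todo) && tries < max_tries) {
      cand <- floor(runif(length(todo), 0, L - lens[todo] + 1))
      ok <- (bad_cum[cand + lens[todo] + 1L] - bad_cum[cand + 1L]) == 0L
      new_start[todo[ok]] <- as.integer(cand[ok])
      todo <- todo[!ok]
      tries <- tries + 1L
    }
    n_unplaced <- n_unplaced + length(todo)
    if (length(todo))
      warning(length(todo), " read(s) on ", ch,
              " could not be placed in reliable territory; left in place")
    out$ref_start[rows] <- new_start
    out$ref_end[rows] <- new_start + lens
  }
  setattr(out, "n_unplaced", n_unplaced)
  out[]
}

#' FDR table from observed and shuffled score tracks
#'
#' For every attained observed score `s`, the FDR estimate is the number of
#' null (shuffled) bases with score at least `s` divided by the number of
#' observed bases with score at least `s`, clamped to `[0, 1]` and made
#' monotone non-increasing in score by a running minimum from the highest
#' score downward. Sentinel (-1) bases are excluded from both counts.
#'
#' @param observed,null `fire_track` objects on the same genome.
#' @return `data.table` of class `fire_fdr_table` with columns `threshold`,
#'   `n_obs`, `n_null`, `fdr`.
#' @export
fdr_table <- function(observed, null) {
  stopifnot(identical(names(observed$chroms), names(null$chroms)))
  so <- unlist(lapply(observed$chroms, function(x) x$S), use.names = FALSE)
  sn <- unlist(lapply(null$chroms, function(x) x$S), use.names = FALSE)
  so <- so[so >= 0]; sn <- sn[sn >= 0]
  if (!length(so)) stop("observed track has no scored bases")
  thr <- sort(unique(so))
  so_s <- sort(so); sn_s <- sort(sn)
  n_obs <- length(so) - findInterval(thr, so_s, left.open = TRUE)
  n_null <- length(sn) - findInterval(thr, sn_s, left.open = TRUE)
  fdr <- pmin(1, n_null / n_obs)
  fdr <- rev(cummin(rev(fdr)))  # running min from the highest score down
  res <- data.table(threshold = thr, n_obs = n_obs, n_null = n_null, fdr = fdr)
  setattr(res, "class", c("fire_fdr_table", class(res)))
  res[]
}

#' Per-base FDR lookup
#'
#' Maps scores to the FDR of the largest tabulated threshold not exceeding
#' them. Scores below every threshold (including the -1 sentinel) map to 1.
#'
#' @param tab a [fdr_table()].
#' @param score numeric scores.
#' @return numeric FDR values in `[0, 1]`.
#' @export
fdr_lookup <- function(tab, score) {
  idx <- findInterval(score, tab$threshold)
  out <- rep(1, length(score))
  out[idx > 0L] <- tab$fdr[idx[idx > 0L]]
  out
}

## Local maxima of a numeric track; returns the center base (0-based) of
## each maximal plateau that is strictly higher than both neighbours
## (track ends count as -Inf).
plateau_maxima <- function(S) {
  r <- rle(S)
  v <- r$values
  nr <- length(v)
  left <- c(-Inf, v[-nr])
  right <- c(v[-1L], -Inf)
  is_max <- v > left & v > right
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- floor((starts + ends) / 2)  # 1-based center
  mids[is_max] - 1L
}

#' Call accessibility peaks
#'
#' Candidate summits are local maxima of the aggregate score with FDR below
#' `fdr_threshold` and actuation (`C_g / R_g`) of at least `min_actuation`
#' at the summit. Adjacent candidates merge when they share at least
#' `elem_share` of the underlying FIRE elements (fraction of the smaller
#' support set) or when their preliminary bounds have at least
#' `reciprocal_overlap` reciprocal overlap; the higher summit is kept. Peak
#' bounds are the median start and end of the FIRE elements overlapping the
#' summit (lower median for the start, upper for the end), and actuation is
#' the fraction of summit-covering reads that carry a FIRE element
#' overlapping the summit.
#'
#' @param track a [fire_score_track()].
#' @param fdr_tab a [fdr_table()].
#' @param config a [peak_config()].
#' @return `data.table` of peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `score`, `fdr`, `actuation`, `n_fires`, `n_reads`, and a
#'   list-column `support` of contributing FIRE `element_id`s.
#' @export
call_peaks <- function(track, fdr_tab, config = peak_config()) {
  out <- list()
  for (ch in names(track$chroms)) {
    tr <- track$chroms[[ch]]
    fe <- track$fires[chrom == ch]
    if (!nrow(fe)) next
    summits <- plateau_maxima(tr$S)
    if (!length(summits)) next
    fdrv <- fdr_lookup(fdr_tab, tr$S[summits + 1L])
    act <- tr$C[summits + 1L] / pmax(1L, tr$R[summits + 1L])
    keep <- tr$S[summits + 1L] >= 0 & fdrv < config$fdr_threshold &
      act >= config$min_actuation
    summits <- summits[keep]; fdrv <- fdrv[keep]
    if (!length(summits)) next

    ## support and preliminary bounds per candidate
    fs <- fe$start; fx <- fe$end
    support <- lapply(summits, function(g) fe$element_id[fs <= g & fx > g])
    bounds <- t(vapply(support, function(ids) {
      i <- match(ids, fe$element_id)
      c(lower_median(fs[i]), upper_median(fx[i]))
    }, numeric(2L)))
    sc <- tr$S[summits + 1L]

    ## merge adjacent candidates
    i <- 1L
    while (i < length(summits)) {
      a <- support[[i]]; b <- support[[i + 1L]]
      share <- length(intersect(a, b)) / min(length(a), length(b))
      inter <- max(0, min(bounds[i, 2L], bounds[i + 1L, 2L]) -
                      max(bounds[i, 1L], bounds[i + 1L, 1L]))
      rec <- min(inter / (bounds[i, 2L] - bounds[i, 1L]),
                 inter / (bounds[i + 1L, 2L] - bounds[i + 1L, 1L]))
      if (share >= config$elem_share || rec >= config$reciprocal_overlap) {
        drop <- if (sc[i] >= sc[i + 1L]) i + 1L else i
        summits <- summits[-drop]; sc <- sc[-drop]; fdrv <- fdrv[-drop]
        support <- support[-drop]; bounds <- bounds[-drop, , drop = FALSE]
      } else i <- i + 1L
    }

    st <- pmin(bounds[, 1L], summits)
    en <- pmax(bounds[, 2L], summits + 1L)
    n_fires <- tr$C[summits + 1L]
    n_reads <- tr$R[summits + 1L]
    out[[ch]] <- data.table(chrom = ch, start = as.integer(st),
                            end = as.integer(en), summit = as.integer(summits),
                            score = sc, fdr = fdrv,
                            actuation = n_fires / n_reads,
                            n_fires = n_fires, n_reads = n_reads,
                            support = support)
  }
  res <- rbindlist(out)
  if (!nrow(res))
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      score = numeric(0), fdr = numeric(0),
                      actuation = numeric(0), n_fires = integer(0),
                      n_reads = integer(0), support = list(),
                      peak_id = character(0)))
  setorder(res, chrom, start)
  res[, peak_id := sprintf("peak_%05d", seq_len(.N))]
  res[]
}

#' Call wide peaks
#'
#' The union of the narrow peak intervals and every maximal run of bases
#' with FDR below the threshold, merged across gaps smaller than one
#' nucleosome (`wide_merge_bp`, default 147 bp).
#'
#' @param peaks narrow peaks from [call_peaks()].
#' @param track a [fire_score_track()].
#' @param fdr_tab a [fdr_table()].
#' @param config a [peak_config()].
#' @return `data.table` with `chrom`, `start`, `end`.
#' @export
call_wide_peaks <- function(peaks, track, fdr_tab, config = peak_config()) {
  runs <- list()
  for (ch in names(track$chroms)) {
    S <- track$chroms[[ch]]$S
    ok <- S >= 0 & fdr_lookup(fdr_tab, S) < config$fdr_threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (any(r$values))
      runs[[ch]] <- data.table(chrom = ch, start = starts[r$values] - 1L,
                               end = ends[r$values])
  }
  pieces <- rbindlist(runs)
  if (nrow(peaks))
    pieces <- rbind(pieces, peaks[, .(chrom, start, end)])
  if (!nrow(pieces))
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0)))
  merged <- merge_regions(pieces)
  merge_within_gap(merged, config$wide_merge_bp)[]
}
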