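## Count marks of a sorted integer vector falling in [a, b) (0-based).
count_in <- function(m, a, b) {
  findInterval(b - 1L, m) - findInterval(a - 1L, m)
}

#' Feature vectors for MSPs
#'
#' Turns each MSP into a fixed-length numeric feature vector:
#' the MSP length, the m6A count and per-bp rate inside the MSP, the log2
#' fold enrichment of the internal m6A rate over the whole-fiber rate (with a
#' symmetric pseudocount of 0.5 on numerator and denominator), the A/T
#' fraction of the MSP when the fiber carries sequence, and m6A counts and
#' per-bp rates in flanking windows of widths `window_widths` immediately
#' left and right of the MSP. Flank windows are truncated (never dropped) at
#' read ends; a fully clipped window has width 0, count 0 and rate 0. No
#' reference-genome information enters the features.
#'
#' @param ft a `fire_fibers` table.
#' @param msps MSP table from [derive_msps()] (columns `fiber_id`, `start`,
#'   `end`).
#' @param window_widths integer vector of flank window widths in bp.
#' @return A `data.table`: `fiber_id`, `start`, `end`, then one column per
#'   feature. Column order is fixed for a given `window_widths` and sequence
#'   availability.
#' @export
msp_features <- function(ft, msps, window_widths = c(30L, 100L, 200L)) {
  if (any(msps$end <= msps$start))
    stop("zero-length MSP in input")
  lens <- fiber_length(ft)
  has_seq <- !is.null(ft$seq) && all(!is.na(ft$seq))
  idx <- match(msps$fiber_id, ft$fiber_id)
  if (anyNA(idx)) stop("MSP refers to unknown fiber_id")

  nm <- nrow(msps)
  L <- lens[idx]
  s <- msps$start
  e <- msps$end
  msp_len <- e - s

  n_m6a_fiber <- vapply(ft$m6a, length, 1L)[idx]
  fiber_rate <- n_m6a_fiber / L

  cnt_in <- numeric(nm)
  flank <- matrix(0, nrow = nm, ncol = 4L * length(window_widths))
  at_frac <- if (has_seq) numeric(nm) else NULL
  for (fi in unique(idx)) {
    rows <- which(idx == fi)
    m <- ft$m6a[[fi]]
    Lf <- lens[fi]
    cnt_in[rows] <- count_in(m, s[rows], e[rows])
    col <- 1L
    for (w in window_widths) {
      ls <- pmax(0L, s[rows] - w); le <- s[rows]
      rs <- e[rows]; re <- pmin(Lf, e[rows] + w)
      lw <- le - ls; rw <- re - rs
      lc <- count_in(m, ls, le); rc <- count_in(m, rs, re)
      flank[rows, col] <- lc
      flank[rows, col + 1L] <- ifelse(lw > 0L, lc / lw, 0)
      flank[rows, col + 2L] <- rc
      flank[rows, col + 3L] <- ifelse(rw > 0L, rc / rw, 0)
      col <- col + 4L
    }
    if (has_seq) {
      sq <- ft$seq[fi]
      for (r in rows) {
        sub <- substr(sq, s[r] + 1L, e[r])
        at_frac[r] <- lengths(regmatches(sub, gregexpr("[ATat]", sub))) /
          nchar(sub)
      }
    }
  }

  res <- data.table(
    fiber_id = msps$fiber_id, start = s, end = e,
    msp_len = as.numeric(msp_len),
    m6a_count_in = cnt_in,
    m6a_frac_in = cnt_in / msp_len,
    log_fold_enrich = log2((cnt_in + 0.5) / (msp_len * fiber_rate + 0.5))
  )
  if (has_seq) res[, at_frac := at_frac]
  fl_names <- as.vector(vapply(window_widths, function(w)
    paste0(c("left_m6a_count_", "left_m6a_frac_",
             "right_m6a_count_", "right_m6a_frac_"), w), character(4L)))
  res[, (fl_names) := as.data.table(flank)]
  res[]
}

#' Names of the feature columns in a feature table
#' @param feat a table from [msp_features()] or [build_training_set()].
#' @return character vector of feature column names.
#' @export
feature_names <- function(feat) {
  setdiff(names(feat), c("fiber_id", "chrom", "start", "end", "label",
                         "split", "msp_id"))
}

#' Assemble a mixed-positive / clean-negative training set
#'
#' Fibers are subsampled, segmented into nucleosome footprints and MSPs, and
#' every MSP is labelled by reference overlap: `mixed_positive` if it overlaps
#' (by at least 1 bp) a putative-positive region (e.g. bulk accessibility
#' peaks), `clean_negative` if it overlaps neither the positive nor the
#' exclusion set. MSPs overlapping only the exclusion set are dropped. The
#' positive labels are a mixture of truly actuated elements and ordinary
#' linkers, hence "mixed"; the negatives are clean. The train/test split is
#' assigned per fiber, never per MSP, so no fiber contributes rows to both.
#'
#' @param ft a `fire_fibers` table.
#' @param positive_regions `data.table`/`data.frame` with `chrom`, `start`,
#'   `end` (0-based half-open) of putative-positive regions.
#' @param negative_exclusion optional regions excluded from negative labels.
#' @param sample_frac fraction of fibers to sample.
#' @param test_frac fraction of sampled fibers held out as the test split.
#' @param seed integer seed controlling sampling and the split.
#' @param params nucleosome caller parameters.
#' @param window_widths flank window widths passed to [msp_features()].
#' @return A labelled feature `data.table` with columns `fiber_id`, `start`,
#'   `end`, `label`, `split` and the feature columns.
#' @export
build_training_set <- function(ft, positive_regions, negative_exclusion = NULL,
                               sample_frac = 0.1, test_frac = 0.2, seed = 1L,
                               params = nucleosome_params(),
                               window_widths = c(30L, 100L, 200L)) {
  set.seed(seed)
  ids <- ft$fiber_id
  n_keep <- max(1L, round(length(ids) * sample_frac))
  keep <- sort(sample(seq_along(ids), n_keep))
  sub <- ft[keep]
  setattr(sub, "class", class(ft))

  fp <- call_nucleosomes(sub, params)
  msps <- derive_msps(sub, fp)
  feat <- msp_features(sub, msps, window_widths)

  ref <- sub[, .(fiber_id, chrom, ref_start)]
  feat <- ref[feat, on = "fiber_id"]
  feat[, `:=`(xstart = ref_start + start, xend = ref_start + end)]

  pos <- merge_regions(positive_regions)
  is_pos <- overlap_any(feat[, .(chrom, start = xstart, end = xend)], pos)
  is_excl <- if (!is.null(negative_exclusion) && nrow(negative_exclusion))
    overlap_any(feat[, .(chrom, start = xstart, end = xend)],
                merge_regions(negative_exclusion))
  else rep(FALSE, nrow(feat))

  feat[, label := fifelse(is_pos, "mixed_positive",
                          fifelse(is_excl, NA_character_, "clean_negative"))]
  feat <- feat[!is.na(label)]
  if (!any(feat$label == "mixed_positive") ||
      !any(feat$label == "clean_negative"))
    stop("training set assembly produced no ",
         if (any(feat$label == "mixed_positive")) "negatives" else "positives")

  ufib <- unique(feat$fiber_id)
  n_test <- max(1L, round(length(ufib) * test_frac))
  test_fibers <- sample(ufib, n_test)
  feat[, split := fifelse(fiber_id %in% test_fibers, "test", "train")]
  feat[, c("ref_start", "xstart", "xend", "chrom") := NULL]
  setcolorder(feat, c("fiber_id", "start", "end", "label", "split"))
  feat[]
}
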