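## Interval helpers. All genomic intervals in the package are 0-based
## half-open [start, end), the BED convention.

#' Merge (flatten) possibly overlapping regions
#' @param regions `data.frame` with `chrom`, `start`, `end`.
#' @return sorted `data.table` of disjoint regions.
#' @export
merge_regions <- function(regions) {
  r <- as.data.table(regions)[, .(chrom, start = as.integer(start),
                                  end = as.integer(end))]
  stopifnot(all(r$end > r$start))
  setorder(r, chrom, start, end)
  r[, grp := cumsum(c(1L, (start > cummax(shift(end, fill = end[1])))[-1])),
    by = chrom]
  out <- r[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[]
}

## Logical: does each query interval overlap (>= 1 bp) any subject interval?
overlap_any <- function(query, subject) {
  if (is.null(subject) || !nrow(subject)) return(rep(FALSE, nrow(query)))
  q <- as.data.table(query)[, .(chrom, qs = start, qe = end - 1L,
                                row = seq_len(nrow(query)))]
  s <- as.data.table(subject)[, .(chrom, ss = start, se = end - 1L)]
  setkey(s, chrom, ss, se)
  hits <- foverlaps(q, s, by.x = c("chrom", "qs", "qe"),
                    by.y = c("chrom", "ss", "se"), nomatch = NULL,
                    which = TRUE, type = "any")
  res <- rep(FALSE, nrow(query))
  res[q$row[hits$xid]] <- TRUE
  res
}

## Count of subject intervals overlapped by each query interval.
overlap_count <- function(query, subject) {
  if (is.null(subject) || !nrow(subject)) return(rep(0L, nrow(query)))
  q <- as.data.table(query)[, .(chrom, qs = start, qe = end - 1L)]
  s <- as.data.table(subject)[, .(chrom, ss = start, se = end - 1L)]
  setkey(s, chrom, ss, se)
  hits <- foverlaps(q, s, by.x = c("chrom", "qs", "qe"),
                    by.y = c("chrom", "ss", "se"), nomatch = NULL,
                    which = TRUE, type = "any")
  tab <- tabulate(hits$xid, nbins = nrow(query))
  tab
}

## Lower and upper medians of an integer vector (even counts take the
## lower / upper of the two central order statistics respectively, so a peak
## never shrinks past half its support).
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
upper_median <- function(x) sort(x)[floor(length(x) / 2) + 1L]

## Merge sorted disjoint intervals whose gap is < gap_bp.
merge_within_gap <- function(dt, gap_bp) {
  if (!nrow(dt)) return(dt)
  setorder(dt, chrom, start, end)
  dt[, grp := cumsum(c(1L, (start - shift(cummax(end)) >= gap_bp)[-1])),
     by = chrom]
  out <- dt[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[]
}
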