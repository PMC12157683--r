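#' Parameters of the heuristic nucleosome caller
#'
#' Three tunable lengths drive the four-phase caller: `n`, the minimum
#' nucleosome length (default 75 bp); `c`, the minimum combined length for
#' rescuing a stretch interrupted by a single (putatively false-positive) m6A
#' call (default 100 bp); and `e`, the minimum number of unmethylated bases
#' that must be gained for a footprint to be extended across one additional
#' m6A mark (default 25 bp).
#'
#' @param n minimum nucleosome length in bp.
#' @param c minimum combined length in bp (must be >= `n`).
#' @param e minimum extension length in bp.
#' @return A named list of class `nucleosome_params`.
#' @export
nucleosome_params <- function(n = 75L, c = 100L, e = 25L) {
  n <- as.integer(n); c <- as.integer(c); e <- as.integer(e)
  stopifnot(n > 0L, c > 0L, e > 0L, n <= c)
  structure(list(n = n, c = c, e = e), class = "nucleosome_params")
}

## Four-phase caller on a single fiber.
##
## Marks at offsets `m` (sorted, 0-based) on a fiber of length `L`.
## An m6A-free run between marks i < j is the open interval (i, j), i.e. the
## half-open [i + 1, j); read ends act as boundaries.
##  phase 1: every maximal m6A-free run of length >= n is a candidate.
##  phase 2: for every mark, the region between its two neighbouring
##           boundaries (one internal m6A) of length >= c is a candidate.
##  phase 3: a candidate is extended across one adjacent m6A when doing so
##           adds >= e m6A-free bases (left side first, then the right);
##           candidates left adjacent across a single m6A merge.
##  phase 4: phase 3 repeats until a fixed point.
## Returns an integer matrix with columns start, end (half-open, disjoint,
## sorted).
nuc_call_one <- function(m, L, params) {
  n <- params$n; cmin <- params$c; e <- params$e
  k <- length(m)
  b <- c(-1L, m, L)

  ## phase 1
  rs <- b[-length(b)] + 1L
  re <- b[-1L]
  keep <- (re - rs) >= n
  starts <- rs[keep]
  ends <- re[keep]

  ## phase 2: region bounded by the marks flanking mark t (or read ends)
  if (k) {
    p2s <- b[seq_len(k)] + 1L
    p2e <- b[seq_len(k) + 2L]
    k2 <- (p2e - p2s) >= cmin
    starts <- c(starts, p2s[k2])
    ends <- c(ends, p2e[k2])
  }
  if (!length(starts))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))

  ## merge overlapping or touching candidates
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  os <- integer(0); oe <- integer(0)
  if (length(starts) > 1L) {
    for (i in 2L:length(starts)) {
      if (starts[i] <= me) {
        me <- max(me, ends[i])
      } else {
        os <- c(os, ms); oe <- c(oe, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  starts <- c(os, ms); ends <- c(oe, me)

  ## phases 3 and 4
  repeat {
    changed <- FALSE
    i <- 1L
    while (i <= length(starts)) {
      ## left extension: span the mark at start - 1
      s <- starts[i]
      if (s > 0L) {
        j <- findInterval(s - 2L, m)          # last mark left of the spanned one
        run_start <- if (j >= 1L) m[j] + 1L else 0L
        if ((s - 1L) - run_start >= e) {
          starts[i] <- run_start
          changed <- TRUE
          if (i > 1L && starts[i] - ends[i - 1L] <= 1L) {
            starts[i] <- starts[i - 1L]
            starts <- starts[-(i - 1L)]
            ends <- ends[-(i - 1L)]
            i <- i - 1L
          }
        }
      }
      ## right extension: span the mark at end
      en <- ends[i]
      if (en < L) {
        idx <- findInterval(en, m)            # the spanned mark is m[idx]
        nxt <- if (idx + 1L <= k) m[idx + 1L] else L
        if (nxt - en - 1L >= e) {
          ends[i] <- nxt
          changed <- TRUE
          if (i < length(starts) && starts[i + 1L] - ends[i] <= 1L) {
            ends[i] <- ends[i + 1L]
            starts <- starts[-(i + 1L)]
            ends <- ends[-(i + 1L)]
          }
        }
      }
      i <- i + 1L
    }
    if (!changed) break
  }

  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("internal error: overlapping nucleosome candidates")
  cbind(start = starts, end = ends)
}

#' Call nucleosome footprints on each fiber
#'
#' Protected (m6A-free) stretches are identified with a four-phase heuristic:
#' maximal m6A-free runs of at least `n` bases; stretches of at least `c`
#' bases interrupted by exactly one internal m6A (a putative false-positive
#' call); extension of a footprint across one adjacent m6A whenever at least
#' `e` unmethylated bases are gained, applied left side first; and repetition
#' of the extension step to a fixed point. Footprints on a fiber are disjoint
#' and sorted, and extensions can only lengthen them.
#'
#' @param ft a `fire_fibers` table (see [fibers()]).
#' @param params a [nucleosome_params()] object.
#' @return A `data.table` with columns `fiber_id`, `start`, `end`
#'   (fiber-relative, 0-based half-open).
#' @export
call_nucleosomes <- function(ft, params = nucleosome_params()) {
  stopifnot(inherits(params, "nucleosome_params"))
  lens <- fiber_length(ft)
  out <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    fp <- nuc_call_one(ft$m6a[[i]], lens[i], params)
    if (nrow(fp))
      out[[i]] <- data.table(fiber_id = ft$fiber_id[i],
                             start = fp[, 1L], end = fp[, 2L])
  }
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(fiber_id = character(0), start = integer(0),
                      end = integer(0))
  res[]
}

#' Derive methyltransferase-sensitive patches (MSPs)
#'
#' MSPs are the set complement of the nucleosome footprints within
#' `[0, fiber length)`: every stretch of a fiber that is not protected.
#' Zero-length gaps are omitted.
#'
#' @param ft a `fire_fibers` table.
#' @param footprints footprint table from [call_nucleosomes()].
#' @return A `data.table` with columns `fiber_id`, `start`, `end`.
#' @export
derive_msps <- function(ft, footprints) {
  lens <- setNames(fiber_length(ft), ft$fiber_id)
  fp_by <- split(footprints[, .(start, end)], footprints$fiber_id)
  out <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    id <- ft$fiber_id[i]
    L <- lens[[id]]
    fp <- fp_by[[id]]
    if (is.null(fp) || !nrow(fp)) {
      out[[i]] <- data.table(fiber_id = id, start = 0L, end = L)
      next
    }
    fp <- fp[order(start)]
    if (fp$start[1L] < 0L || fp$end[nrow(fp)] > L)
      stop("footprints out of bounds for fiber ", id)
    gs <- c(0L, fp$end)
    ge <- c(fp$start, L)
    keep <- ge > gs
    if (any(keep))
      out[[i]] <- data.table(fiber_id = id, start = gs[keep], end = ge[keep])
  }
  res <- rbindlist(out)
  if (!nrow(res))
    res <- data.table(fiber_id = character(0), start = integer(0),
                      end = integer(0))
  res[]
}
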