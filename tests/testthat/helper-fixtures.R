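## Small constructors used across test files.

mk_fiber <- function(m6a = integer(0), len = 500L, id = "f1", chrom = "chrT",
                     start = 0L, hap = "UNK", seq = NA_character_,
                     cpg_pos = integer(0), cpg_meth = integer(0)) {
  fibers(fiber_id = id, chrom = chrom, ref_start = start,
         ref_end = start + len, strand = "+", haplotype = hap,
         m6a = list(as.integer(m6a)), cpg_pos = list(as.integer(cpg_pos)),
         cpg_meth = list(as.integer(cpg_meth)), seq = seq)
}

mk_fibers <- function(...) {
  fts <- list(...)
  out <- data.table::rbindlist(fts)
  data.table::setattr(out, "class", class(fts[[1]]))
  out
}

## A synthetic peak locus for haplotype testing: `reads` phased reads per
## haplotype covering [1000, 3000) with actuation probabilities p1/p2; the
## classified-MSP table marks the whole read as a FIRE element on actuated
## reads. Returns list(ft, fires, peaks).
mk_hsca_fixture <- function(reads = 15L, p1 = 0.5, p2 = 0.5, n_peaks = 1L,
                            seed = 1L, chrom = "chrT") {
  set.seed(seed)
  rows <- list(); msp_rows <- list()
  peak_rows <- list()
  for (pk in seq_len(n_peaks)) {
    off <- (pk - 1L) * 10000L
    for (h in c("H1", "H2")) {
      p <- if (h == "H1") p1 else p2
      for (r in seq_len(reads)) {
        id <- sprintf("p%d_%s_r%02d", pk, h, r)
        rows[[id]] <- data.table::data.table(
          fiber_id = id, chrom = chrom, ref_start = off,
          ref_end = off + 3000L, strand = "+", haplotype = h,
          m6a = list(integer(0)), cpg_pos = list(integer(0)),
          cpg_meth = list(integer(0)), seq = NA_character_)
        actuated <- stats::runif(1) < p
        msp_rows[[id]] <- data.table::data.table(
          fiber_id = id, start = 500L, end = 2500L,
          ep = if (actuated) 0.97 else 0.1, is_fire = actuated)
      }
    }
    peak_rows[[pk]] <- data.table::data.table(
      peak_id = sprintf("peak_%05d", pk), chrom = chrom,
      start = off + 900L, end = off + 2100L, summit = off + 1500L)
  }
  ft <- data.table::rbindlist(rows)
  data.table::setattr(ft, "class", c("fire_fibers", class(ft)))
  msps <- data.table::rbindlist(msp_rows)
  fires <- fireseq:::project_fires(ft, msps[msps$is_fire == TRUE])
  list(ft = ft, fires = fires, peaks = data.table::rbindlist(peak_rows))
}
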