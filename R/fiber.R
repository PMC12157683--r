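#' Construct a table of single-molecule fiber records
#'
#' A fiber is one sequenced chromatin molecule: its placement on the
#' reference, a haplotype tag, and the positions of m6A (and optionally CpG)
#' marks along the molecule. Offsets are fiber-relative, 0-based; reference
#' coordinates are 0-based half-open. Reads are treated as gapless relative to
#' the reference, so reference projection of an offset `x` is `ref_start + x`.
#'
#' @param fiber_id character vector of unique read identifiers.
#' @param chrom character vector of chromosome names.
#' @param ref_start,ref_end integer reference coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param haplotype one of `"H1"`, `"H2"`, `"UNK"`.
#' @param m6a list of strictly increasing integer offset vectors
#'   (0-based, fiber-relative), one per fiber. May contain empty vectors.
#' @param cpg_pos,cpg_meth optional lists of CpG offsets and their 0/1
#'   methylation calls (parallel vectors per fiber).
#' @param seq optional character vector of read sequences over `ACGTN`
#'   (length `ref_end - ref_start`), or `NA`.
#'
#' @return A `data.table` of class `fire_fibers` with list-columns `m6a`,
#'   `cpg_pos`, `cpg_meth`.
#' @export
fibers <- function(fiber_id, chrom, ref_start, ref_end,
                   strand = "+", haplotype = "UNK",
                   m6a = vector("list", length(fiber_id)),
                   cpg_pos = vector("list", length(fiber_id)),
                   cpg_meth = vector("list", length(fiber_id)),
                   seq = NA_character_) {
  ft <- data.table(
    fiber_id = as.character(fiber_id),
    chrom = as.character(chrom),
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    strand = rep_len(as.character(strand), length(fiber_id)),
    haplotype = rep_len(as.character(haplotype), length(fiber_id)),
    m6a = lapply(m6a, function(x) as.integer(x)),
    cpg_pos = lapply(cpg_pos, function(x) as.integer(x)),
    cpg_meth = lapply(cpg_meth, function(x) as.integer(x)),
    seq = rep_len(as.character(seq), length(fiber_id))
  )
  setattr(ft, "class", c("fire_fibers", class(ft)))
  validate_fibers(ft)
  ft[]
}

#' Validate fiber records
#'
#' Checks the structural invariants of a fiber table: positive read length,
#' strictly increasing in-bounds m6A offsets, known haplotype tokens, and
#' sequence length (when present) equal to the reference span.
#'
#' @param ft a `fire_fibers` table.
#' @return `ft`, invisibly. Errors with the offending fiber id otherwise.
#' @export
validate_fibers <- function(ft) {
  stopifnot(is.data.frame(ft))
  req <- c("fiber_id", "chrom", "ref_start", "ref_end", "strand",
           "haplotype", "m6a")
  miss <- setdiff(req, names(ft))
  if (length(miss)) stop("fiber table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ft$fiber_id))
    stop("duplicate fiber_id values in fiber table")
  bad <- which(ft$ref_end <= ft$ref_start)
  if (length(bad))
    stop("fiber ", ft$fiber_id[bad[1]], ": ref_start must be < ref_end")
  if (!all(ft$haplotype %in% c("H1", "H2", "UNK")))
    stop("haplotype must be one of H1, H2, UNK")
  if (!all(ft$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  lens <- ft$ref_end - ft$ref_start
  for (i in seq_len(nrow(ft))) {
    m <- ft$m6a[[i]]
    if (length(m)) {
      if (is.unsorted(m, strictly = TRUE))
        stop("fiber ", ft$fiber_id[i], ": m6a offsets must be strictly increasing")
      if (m[1] < 0L || m[length(m)] >= lens[i])
        stop("fiber ", ft$fiber_id[i], ": m6a offset out of range [0, length)")
    }
    if (!is.null(ft$cpg_pos) && length(ft$cpg_pos[[i]])) {
      cp <- ft$cpg_pos[[i]]
      if (any(cp < 0L) || any(cp >= lens[i]))
        stop("fiber ", ft$fiber_id[i], ": cpg offset out of range")
      if (length(cp) != length(ft$cpg_meth[[i]]))
        stop("fiber ", ft$fiber_id[i], ": cpg_pos and cpg_meth lengths differ")
    }
    if (!is.null(ft$seq) && !is.na(ft$seq[i]) && nchar(ft$seq[i]) != lens[i])
      stop("fiber ", ft$fiber_id[i], ": seq length != ref_end - ref_start")
  }
  invisible(ft)
}

#' Fiber lengths in bp
#' @param ft a `fire_fibers` table.
#' @return integer vector `ref_end - ref_start`.
#' @export
fiber_length <- function(ft) ft$ref_end - ft$ref_start
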