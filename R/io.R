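## Fiber-table TSV schema (tab-separated, header required):
##   fiber_id chrom ref_start ref_end strand haplotype m6a cpg seq
## m6a: comma-separated fiber-relative offsets or "."
## cpg: comma-separated "offset:0" / "offset:1" or "."
## seq: read sequence or "."

FIBER_COLS <- c("fiber_id", "chrom", "ref_start", "ref_end", "strand",
                "haplotype", "m6a", "cpg", "seq")

#' Read a fiber table from TSV
#'
#' Parses and validates the tabular fiber format (see
#' [write_fiber_table()]); validation failures report the offending file
#' line.
#'
#' @param path path to a fiber-table TSV.
#' @return a `fire_fibers` table.
#' @export
read_fiber_table <- function(path) {
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("fiber_id", "chrom", "strand", "haplotype", "m6a",
                  "cpg", "seq")))
  if (!identical(names(raw), FIBER_COLS))
    stop("fiber table header must be: ", paste(FIBER_COLS, collapse = ", "))
  parse_ints <- function(s) {
    if (s == ".") integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  }
  n <- nrow(raw)
  m6a <- vector("list", n); cpg_pos <- vector("list", n)
  cpg_meth <- vector("list", n)
  for (i in seq_len(n)) {
    line <- i + 1L
    m <- tryCatch(parse_ints(raw$m6a[i]),
                  warning = function(w) stop("line ", line,
                                             ": malformed m6a field"))
    if (anyNA(m)) stop("line ", line, ": malformed m6a field")
    if (length(m) && is.unsorted(m, strictly = TRUE))
      stop("line ", line, ": m6a offsets not strictly increasing")
    if (length(m) && (m[1L] < 0L ||
                      m[length(m)] >= raw$ref_end[i] - raw$ref_start[i]))
      stop("line ", line, ": m6a offset out of range")
    m6a[[i]] <- m
    if (raw$cpg[i] != ".") {
      parts <- strsplit(strsplit(raw$cpg[i], ",", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
      if (any(lengths(parts) != 2L))
        stop("line ", line, ": malformed cpg field")
      cpg_pos[[i]] <- as.integer(vapply(parts, `[`, "", 1L))
      cpg_meth[[i]] <- as.integer(vapply(parts, `[`, "", 2L))
      if (anyNA(cpg_pos[[i]]) || !all(cpg_meth[[i]] %in% c(0L, 1L)))
        stop("line ", line, ": malformed cpg field")
    } else {
      cpg_pos[[i]] <- integer(0); cpg_meth[[i]] <- integer(0)
    }
    if (!raw$haplotype[i] %in% c("H1", "H2", "UNK"))
      stop("line ", line, ": unknown haplotype token '", raw$haplotype[i], "'")
  }
  fibers(fiber_id = raw$fiber_id, chrom = raw$chrom,
         ref_start = raw$ref_start, ref_end = raw$ref_end,
         strand = raw$strand, haplotype = raw$haplotype,
         m6a = m6a, cpg_pos = cpg_pos, cpg_meth = cpg_meth,
         seq = fifelse(raw$seq == ".", NA_character_, raw$seq))
}

#' Write a fiber table to TSV
#'
#' Canonical serialization: header, tab separators, offsets comma-joined,
#' empty fields as `"."`. `write_fiber_table(read_fiber_table(f))`
#' reproduces `f` byte for byte.
#'
#' @param ft a `fire_fibers` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(ft, path) {
  join <- function(x) if (length(x)) paste(x, collapse = ",") else "."
  out <- data.table(
    fiber_id = ft$fiber_id, chrom = ft$chrom,
    ref_start = ft$ref_start, ref_end = ft$ref_end,
    strand = ft$strand, haplotype = ft$haplotype,
    m6a = vapply(ft$m6a, join, ""),
    cpg = vapply(seq_len(nrow(ft)), function(i) {
      cp <- ft$cpg_pos[[i]]
      if (!length(cp)) "." else paste(cp, ft$cpg_meth[[i]], sep = ":",
                                      collapse = ",")
    }, ""),
    seq = fifelse(is.na(ft$seq), ".", ft$seq))
  fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a BED file (3+ columns, 0-based half-open)
#' @param path BED path.
#' @param col_names optional names for columns beyond the first three.
#' @return `data.table` with `chrom`, `start`, `end` (+ extras).
#' @export
read_bed <- function(path, col_names = NULL) {
  b <- fread(path, sep = "\t", header = FALSE)
  nm <- c("chrom", "start", "end")
  if (ncol(b) > 3L)
    nm <- c(nm, if (!is.null(col_names)) col_names
            else paste0("V", seq_len(ncol(b) - 3L) + 3L))
  setnames(b, nm[seq_len(ncol(b))])
  b[]
}

#' Write intervals as BED (sorted, 0-based half-open, no header)
#' @param dt table with `chrom`, `start`, `end` and optional extra columns.
#' @param path output path.
#' @param extra_cols character vector of extra columns to append after the
#'   first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path, extra_cols = NULL) {
  d <- as.data.table(dt)[, c("chrom", "start", "end", extra_cols),
                         with = FALSE]
  setorder(d, chrom, start, end)
  fwrite(d, path, sep = "\t", quote = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a score track as bedGraph
#'
#' Emits runs of constant value as `chrom start end value` lines, sorted.
#'
#' @param track a `fire_track` or `fire_mask`.
#' @param path output path.
#' @param what which per-base array to export (`"S"`, `"C"`, `"R"`, or
#'   `"actuation"` for `C/R`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, what = "S") {
  rows <- list()
  for (ch in names(track$chroms)) {
    tr <- track$chroms[[ch]]
    v <- switch(what,
                S = tr$S, C = tr$C, R = tr$R,
                actuation = ifelse(tr$R > 0L, tr$C / tr$R, 0),
                stop("unknown track component: ", what))
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    rows[[ch]] <- data.table(chrom = ch, start = starts[keep],
                             end = ends[keep], value = r$values[keep])
  }
  d <- rbindlist(rows)
  setorder(d, chrom, start)
  fwrite(d, path, sep = "\t", quote = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#' @param path path to a `chrom.sizes` TSV (name, length).
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- fread(path, sep = "\t", header = FALSE)
  setNames(as.integer(d[[2L]]), as.character(d[[1L]]))
}

#' Write a run-configuration snapshot as plain key = value text
#' @param config a named list (nested lists are flattened with `$`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste0(names(flat), " = ", vapply(flat, format, "")), path)
  invisible(path)
}
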