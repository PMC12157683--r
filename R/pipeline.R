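#' Run the full per-sample pipeline
#'
#' Segments every fiber into nucleosome footprints and MSPs, classifies the
#' MSPs with a trained model, builds the coverage mask and aggregate score
#' track, shuffles the reads to obtain the empirical null, derives the FDR
#' table, and calls narrow and wide peaks.
#'
#' @param ft a `fire_fibers` table.
#' @param model a trained `fire_model`.
#' @param chrom_sizes chromosome sizes.
#' @param params nucleosome caller parameters.
#' @param config peak calling configuration.
#' @param shuffle_seed seed for the read shuffle.
#' @return list with `msps`, `mask`, `track`, `null_track`, `fdr`,
#'   `peaks`, `wide_peaks`.
#' @export
fire_pipeline <- function(ft, model, chrom_sizes,
                          params = nucleosome_params(),
                          config = peak_config(), shuffle_seed = 1L) {
  msps <- classify_msps(model, ft, params = params)
  mask <- coverage_mask(ft, chrom_sizes, config)
  track <- fire_score_track(ft, msps, chrom_sizes, config)
  shuf <- shuffle_fibers(ft, chrom_sizes, mask, seed = shuffle_seed)
  null_track <- fire_score_track(shuf, msps, chrom_sizes, config)
  fdr <- fdr_table(track, null_track)
  peaks <- call_peaks(track, fdr, config)
  wide <- call_wide_peaks(peaks, track, fdr, config)
  list(msps = msps, mask = mask, track = track, null_track = null_track,
       fdr = fdr, peaks = peaks, wide_peaks = wide)
}
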