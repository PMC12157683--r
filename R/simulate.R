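#' Simulation configuration
#'
#' Describes a synthetic Fiber-seq experiment: a genome, regulatory elements
#' with per-haplotype actuation probabilities, a nucleosome-array model
#' (protected footprints punctuated by methylatable linkers), and per-state
#' m6A rates. Defaults emulate a human-like chromatin fiber: 147 bp
#' nucleosome footprints, ~60 bp linkers, and m6A rates that place the
#' global methylation level inside the range observed across real
#' experiments (roughly 6-13% of adenines). Rates are per bp when no
#' sequence is generated (the default); with `gen_seq = TRUE` marks are
#' placed only at A/T bases at correspondingly rescaled rates.
#'
#' @param genome named integer vector of chromosome sizes.
#' @param n_elements number of regulatory elements (distributed over
#'   chromosomes proportionally to size).
#' @param element_len min/max element length (bp, uniform).
#' @param min_separation minimum gap between elements (bp).
#' @param actuation min/max per-element actuation probability (uniform; both
#'   haplotypes equal unless `frac_hap_selective > 0`).
#' @param frac_hap_selective fraction of elements given haplotype-selective
#'   actuation.
#' @param hs_actuation high/low actuation for haplotype-selective elements
#'   (assigned to a random haplotype each).
#' @param prop_tss,prop_ctcf fractions of elements annotated as TSS / CTCF
#'   motifs (the rest are generic regulatory elements).
#' @param nucleosome_len,linker_len mean and sd (bp) of footprint and linker
#'   lengths.
#' @param p_m6a_accessible,p_m6a_linker,p_m6a_nucleosome per-base m6A
#'   probabilities by chromatin state.
#' @param rate_multiplier global multiplier emulating sample-to-sample drift
#'   in the methylation rate.
#' @param gen_seq generate random read sequence and place m6A only at A/T.
#' @param gen_cpg simulate CpG calls.
#' @param cpg_density per-base probability of a CpG call.
#' @param cpg_meth_background,cpg_meth_element methylation probability of a
#'   CpG outside / inside an element (element value per haplotype, recycled).
#' @return list of class `fire_sim_config`.
#' @export
sim_config <- function(genome = c(chrS = 2000000L),
                       n_elements = 60L,
                       element_len = c(150L, 250L),
                       min_separation = 3000L,
                       actuation = c(0.2, 0.9),
                       frac_hap_selective = 0,
                       hs_actuation = c(0.8, 0.2),
                       prop_tss = 0.15, prop_ctcf = 0.15,
                       nucleosome_len = c(147, 15),
                       linker_len = c(60, 15),
                       p_m6a_accessible = 0.15,
                       p_m6a_linker = 0.15,
                       p_m6a_nucleosome = 0.0005,
                       rate_multiplier = 1,
                       gen_seq = FALSE, gen_cpg = FALSE,
                       cpg_density = 0.01,
                       cpg_meth_background = 0.8,
                       cpg_meth_element = c(0.2, 0.2)) {
  stopifnot(all(c(p_m6a_accessible, p_m6a_linker, p_m6a_nucleosome) >= 0),
            all(c(p_m6a_accessible, p_m6a_linker, p_m6a_nucleosome) <= 1),
            length(actuation) == 2L, all(actuation >= 0), all(actuation <= 1))
  structure(list(genome = as_chrom_sizes(genome),
                 n_elements = as.integer(n_elements),
                 element_len = as.integer(element_len),
                 min_separation = as.integer(min_separation),
                 actuation = actuation,
                 frac_hap_selective = frac_hap_selective,
                 hs_actuation = hs_actuation,
                 prop_tss = prop_tss, prop_ctcf = prop_ctcf,
                 nucleosome_len = nucleosome_len, linker_len = linker_len,
                 p_m6a_accessible = p_m6a_accessible,
                 p_m6a_linker = p_m6a_linker,
                 p_m6a_nucleosome = p_m6a_nucleosome,
                 rate_multiplier = rate_multiplier,
                 gen_seq = gen_seq, gen_cpg = gen_cpg,
                 cpg_density = cpg_density,
                 cpg_meth_background = cpg_meth_background,
                 cpg_meth_element = rep_len(cpg_meth_element, 2L)),
            class = "fire_sim_config")
}

#' Simulate a ground-truth element set
#'
#' Places non-overlapping elements uniformly on each chromosome with the
#' configured minimum separation (an exact uniform draw over the feasible
#' arrangements), assigns each a per-haplotype actuation probability and a
#' kind (`regulatory`, `tss`, `ctcf_motif`). Deterministic for a given
#' config and seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `fire_truth` with `chrom_sizes`, `elements`
#'   (`data.table`), and `config`.
#' @export
simulate_truth <- function(config, seed = 1L) {
  set.seed(seed)
  cs <- config$genome
  total <- sum(as.numeric(cs))
  elements <- list()
  eid <- 0L
  for (ch in names(cs)) {
    n <- max(0L, round(config$n_elements * cs[[ch]] / total))
    if (!n) next
    lens <- sample(config$element_len[1L]:config$element_len[2L], n,
                   replace = TRUE)
    free <- cs[[ch]] - sum(lens) - (n - 1L) * config$min_separation
    if (free < 0)
      stop("cannot place ", n, " elements with separation ",
           config$min_separation, " on ", ch, " (", cs[[ch]], " bp)")
    u <- sort(runif(n, 0, free))
    starts <- as.integer(floor(u) +
                           cumsum(c(0L, lens[-n] + config$min_separation)))
    if (n == 1L) starts <- as.integer(floor(u))
    a <- runif(n, config$actuation[1L], config$actuation[2L])
    a1 <- a; a2 <- a
    n_hs <- round(config$frac_hap_selective * n)
    if (n_hs > 0L) {
      hs <- sample(n, n_hs)
      flip <- runif(n_hs) < 0.5
      a1[hs] <- ifelse(flip, config$hs_actuation[2L], config$hs_actuation[1L])
      a2[hs] <- ifelse(flip, config$hs_actuation[1L], config$hs_actuation[2L])
    }
    kind <- sample(c("tss", "ctcf_motif", "regulatory"), n, replace = TRUE,
                   prob = c(config$prop_tss, config$prop_ctcf,
                            1 - config$prop_tss - config$prop_ctcf))
    elements[[ch]] <- data.table(
      element_id = sprintf("el_%s_%03d", ch, seq_len(n) + eid),
      chrom = ch, start = starts, end = starts + lens,
      actuation_h1 = a1, actuation_h2 = a2, kind = kind)
    eid <- eid + n
  }
  el <- rbindlist(elements)
  if (!nrow(el))
    el <- data.table(element_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     actuation_h1 = numeric(0), actuation_h2 = numeric(0),
                     kind = character(0))
  structure(list(chrom_sizes = cs, elements = el, config = config),
            class = "fire_truth")
}

## One read's chromatin-state vector: 0 = nucleosome, 1 = linker,
## 2 = accessible element. Starts the alternating array at a random phase.
sim_states <- function(L, config) {
  period <- config$nucleosome_len[1L] + config$linker_len[1L]
  k <- ceiling((L + 2 * period) / period) + 2L
  nl <- pmax(20, round(rnorm(k, config$nucleosome_len[1L],
                             config$nucleosome_len[2L])))
  ll <- pmax(5, round(rnorm(k, config$linker_len[1L], config$linker_len[2L])))
  seg_state <- rep(c(0L, 1L), k)
  seg_len <- as.integer(rbind(nl, ll))
  v <- rep(seg_state, seg_len)
  off <- sample.int(period, 1L)
  while (length(v) < off + L - 1L) {   # guard against short random draws
    extra_n <- max(20L, as.integer(round(rnorm(1, config$nucleosome_len[1L],
                                               config$nucleosome_len[2L]))))
    extra_l <- max(5L, as.integer(round(rnorm(1, config$linker_len[1L],
                                              config$linker_len[2L]))))
    v <- c(v, rep(c(0L, 1L), c(extra_n, extra_l)))
  }
  v[off:(off + L - 1L)]
}

#' Simulate Fiber-seq reads from a truth set
#'
#' Draws reads of normally distributed length at uniform positions, assigns
#' each a haplotype (fair coin, masked to `UNK` at `unphased_frac`), lays
#' down a nucleosome/linker array, actuates each overlapped element with its
#' haplotype's probability (making the overlap accessible), and deposits
#' m6A marks per base at the state-specific rate scaled by the sample
#' multiplier. Optionally simulates CpG calls. Reads longer than their
#' chromosome are truncated (and counted in attribute `n_truncated`).
#'
#' Attributes of the result: `actuation_truth` (one row per read x
#' overlapped element with the realized actuation), `true_hap` (haplotype
#' before unphasing), `state_bases` (total simulated bases per chromatin
#' state), `n_truncated`.
#'
#' @param truth a [simulate_truth()] result.
#' @param coverage target fold coverage.
#' @param read_len mean and sd of read length (bp).
#' @param unphased_frac fraction of reads masked to `UNK`.
#' @param seed integer seed; identical seeds give identical fiber tables.
#' @return a `fire_fibers` table.
#' @export
simulate_fibers <- function(truth, coverage = 30, read_len = c(20000, 2000),
                            unphased_frac = 0.1, seed = 1L) {
  stopifnot(coverage > 0)
  config <- truth$config
  set.seed(seed)
  cs <- truth$chrom_sizes
  rows <- list()
  act_rows <- list()
  state_bases <- c(nucleosome = 0, linker = 0, accessible = 0)
  state_m6a <- c(nucleosome = 0, linker = 0, accessible = 0)
  n_trunc <- 0L
  p_state <- c(config$p_m6a_nucleosome, config$p_m6a_linker,
               config$p_m6a_accessible) * config$rate_multiplier
  for (ch in names(cs)) {
    sz <- cs[[ch]]
    n_reads <- max(1L, round(sz * coverage / read_len[1L]))
    lens <- pmax(500L, as.integer(round(rnorm(n_reads, read_len[1L],
                                              read_len[2L]))))
    too_long <- lens > sz
    n_trunc <- n_trunc + sum(too_long)
    lens[too_long] <- sz
    starts <- as.integer(floor(runif(n_reads, 0, sz - lens + 1)))
    true_hap <- sample(c("H1", "H2"), n_reads, replace = TRUE)
    hap <- ifelse(runif(n_reads) < unphased_frac, "UNK", true_hap)
    el <- truth$elements[chrom == ch]
    for (i in seq_len(n_reads)) {
      L <- lens[i]; s0 <- starts[i]
      st <- sim_states(L, config)
      ov <- el[end > s0 & start < s0 + L]
      if (nrow(ov)) {
        pa <- if (true_hap[i] == "H1") ov$actuation_h1 else ov$actuation_h2
        actuated <- runif(nrow(ov)) < pa
        for (j in which(actuated))
          st[max(1L, ov$start[j] - s0 + 1L):min(L, ov$end[j] - s0)] <- 2L
        act_rows[[length(act_rows) + 1L]] <- data.table(
          fiber_id = sprintf("%s_r%06d", ch, i), element_id = ov$element_id,
          actuated = actuated, true_hap = true_hap[i])
      }
      tb <- tabulate(st + 1L, nbins = 3L)
      state_bases <- state_bases + tb
      if (config$gen_seq) {
        sq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        is_at <- sq %in% c("A", "T")
        at_frac <- mean(is_at)
        pm <- pmin(1, p_state[st + 1L] / at_frac) * is_at
      } else {
        sq <- NULL
        pm <- p_state[st + 1L]
      }
      hits <- runif(L) < pm
      m <- which(hits) - 1L
      state_m6a <- state_m6a + tabulate(st[hits] + 1L, nbins = 3L)
      cpos <- integer(0); cmeth <- integer(0)
      if (config$gen_cpg) {
        cpos <- which(runif(L) < config$cpg_density) - 1L
        if (length(cpos)) {
          in_el <- rep(FALSE, length(cpos))
          if (nrow(ov))
            for (j in seq_len(nrow(ov)))
              in_el <- in_el | (cpos >= ov$start[j] - s0 &
                                  cpos < ov$end[j] - s0)
          pme <- ifelse(in_el,
                        config$cpg_meth_element[
                          if (true_hap[i] == "H1") 1L else 2L],
                        config$cpg_meth_background)
          cmeth <- rbinom(length(cpos), 1L, pme)
        }
      }
      rows[[length(rows) + 1L]] <- list(
        fiber_id = sprintf("%s_r%06d", ch, i), chrom = ch,
        ref_start = s0, ref_end = s0 + L, strand = "+",
        haplotype = hap[i], m6a = list(m), cpg_pos = list(cpos),
        cpg_meth = list(cmeth), seq = if (is.null(sq)) NA_character_
        else paste(sq, collapse = ""))
    }
  }
  ft <- rbindlist(rows)
  setattr(ft, "class", c("fire_fibers", class(ft)))
  at <- rbindlist(act_rows)
  if (!nrow(at))
    at <- data.table(fiber_id = character(0), element_id = character(0),
                     actuated = logical(0), true_hap = character(0))
  setattr(ft, "actuation_truth", at)
  setattr(ft, "state_bases", state_bases)
  setattr(ft, "state_m6a", state_m6a)
  setattr(ft, "n_truncated", n_trunc)
  ft[]
}

#' Score called peaks and haplotype tests against the simulation truth
#'
#' A peak is a true positive when its summit lies inside a truth element.
#' Reports peak precision and recall, the mean absolute error between the
#' peak's measured actuation and the truth actuation (averaged over
#' haplotypes) of its element, and, when a [hsca_test()] result is given,
#' the power and false-discovery proportion of the haplotype-selectivity
#' calls against the planted per-haplotype actuations.
#'
#' @param peaks peaks from [call_peaks()].
#' @param truth a [simulate_truth()] result.
#' @param hsca optional [hsca_test()] result on the same peaks.
#' @return `data.table` with columns `metric`, `value` (precision and
#'   recall missing when undefined).
#' @export
evaluate_against_truth <- function(peaks, truth, hsca = NULL) {
  el <- truth$elements
  metrics <- list()
  if (!nrow(peaks)) {
    metrics$peak_precision <- NA_real_
    metrics$peak_recall <- 0
  } else {
    hit_el <- rep(NA_character_, nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      m <- el[chrom == peaks$chrom[i] & start <= peaks$summit[i] &
                end > peaks$summit[i]]
      if (nrow(m)) hit_el[i] <- m$element_id[1L]
    }
    tp <- !is.na(hit_el)
    metrics$peak_precision <- mean(tp)
    metrics$peak_recall <- mean(el$element_id %in% hit_el)
    if (any(tp)) {
      ta <- el[match(hit_el[tp], element_id),
               (actuation_h1 + actuation_h2) / 2]
      metrics$actuation_mae <- mean(abs(peaks$actuation[tp] - ta))
    }
    if (!is.null(hsca) && nrow(hsca)) {
      h <- hsca[match(peaks$peak_id, peak_id)]
      truly_hs <- !is.na(hit_el) &
        abs(el$actuation_h1 - el$actuation_h2)[
          match(hit_el, el$element_id)] > 0
      called <- !is.na(h$q) & h$q <= 0.05
      if (any(truly_hs & h$tested))
        metrics$hsca_power <- mean(called[truly_hs & h$tested])
      if (any(called))
        metrics$hsca_fdp <- mean(!truly_hs[called])
    }
  }
  data.table(metric = names(metrics),
             value = unlist(metrics, use.names = FALSE))
}
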