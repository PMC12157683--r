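## Heavyweight fixtures shared across test files, built once per session.
## The shared classifier is trained on a 2-Mb, 30-fold simulation under the
## package's default study conditions.

.fire_cache <- new.env(parent = emptyenv())

shared_training <- function() {
  if (is.null(.fire_cache$model)) {
    truth <- simulate_truth(sim_config(), seed = 1000)
    ft <- simulate_fibers(truth, coverage = 30, seed = 1000)
    labeled <- build_training_set(ft, truth$elements, sample_frac = 0.25,
                                  seed = 1000)
    model <- train_fire_model(labeled, classifier_config(seed = 1000))
    .fire_cache$truth <- truth
    .fire_cache$ft <- ft
    .fire_cache$labeled <- labeled
    .fire_cache$model <- model
  }
  list(truth = .fire_cache$truth, ft = .fire_cache$ft,
       labeled = .fire_cache$labeled, model = .fire_cache$model)
}

shared_model <- function() shared_training()$model

## Seeded false-discovery experiment: 2-Mb genomes at 30-fold coverage with
## elements planted at 50% actuation, the shared model applied across seeds.
shared_fdp_experiment <- function(seeds = 1:20) {
  if (is.null(.fire_cache$fdp)) {
    model <- shared_model()
    n_fp <- 0L; n_peaks <- 0L; min_act <- Inf
    for (s in seeds) {
      truth <- simulate_truth(sim_config(actuation = c(0.5, 0.5)), seed = s)
      ft <- simulate_fibers(truth, coverage = 30, seed = s)
      res <- fire_pipeline(ft, model, truth$chrom_sizes, shuffle_seed = s)
      ev <- evaluate_against_truth(res$peaks, truth)
      prec <- ev[ev$metric == "peak_precision", ]$value
      n_peaks <- n_peaks + nrow(res$peaks)
      n_fp <- n_fp + round((1 - prec) * nrow(res$peaks))
      if (nrow(res$peaks)) min_act <- min(min_act, res$peaks$actuation)
    }
    .fire_cache$fdp <- list(n_fp = n_fp, n_peaks = n_peaks,
                            fdp = n_fp / n_peaks, min_actuation = min_act,
                            n_seeds = length(seeds))
  }
  .fire_cache$fdp
}

## One full pipeline run on an independent evaluation simulation.
shared_eval_run <- function() {
  if (is.null(.fire_cache$eval_run)) {
    truth <- simulate_truth(sim_config(), seed = 2000)
    ft <- simulate_fibers(truth, coverage = 30, seed = 2000)
    res <- fire_pipeline(ft, shared_model(), truth$chrom_sizes,
                         shuffle_seed = 2000)
    .fire_cache$eval_run <- list(truth = truth, ft = ft, res = res)
  }
  .fire_cache$eval_run
}
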