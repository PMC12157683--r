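#' Classifier configuration
#'
#' Hyperparameters of the gradient-boosted ensemble and the semi-supervised
#' loop. The tree parameters are ordinary XGBoost defaults for tabular data
#' of this size; they are configuration values, not claims about an optimal
#' model.
#'
#' @param nrounds boosting rounds per fold model.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param target_ep estimated-precision level used to derive positive labels
#'   during the semi-supervised iterations (0.95).
#' @param fire_ep estimated-precision threshold at which an MSP is designated
#'   a FIRE element (0.90).
#' @param max_iter iteration cap for the semi-supervised loop.
#' @param nfold number of cross-validation folds (assigned per fiber).
#' @param seed integer seed for fold assignment and test-set balancing.
#' @param nthread threads for xgboost (1 keeps runs deterministic).
#' @return list of class `fire_classifier_config`.
#' @export
classifier_config <- function(nrounds = 50L, max_depth = 4L, eta = 0.3,
                              target_ep = 0.95, fire_ep = 0.90,
                              max_iter = 25L, nfold = 5L, seed = 1L,
                              nthread = 1L) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, target_ep = target_ep, fire_ep = fire_ep,
                 max_iter = as.integer(max_iter), nfold = as.integer(nfold),
                 seed = as.integer(seed), nthread = as.integer(nthread)),
            class = "fire_classifier_config")
}

#' Estimated-precision curve from scores and labels
#'
#' For every attained score threshold `t`, `TMP` is the number of
#' mixed-positive rows scoring at least `t` and `FP` the number of negative
#' rows scoring at least `t`; the raw estimated precision is
#' `EP = 1 - (FP * ratio + 1) / TMP` (floored at 0), with a pseudocount of
#' one on the false positives so small collections are never scored
#' liberally. `ratio` rescales the negatives to the balanced design the
#' formula presumes. The curve is then monotonized by scanning thresholds
#' from the lowest score upward and taking the running maximum, so EP is
#' non-decreasing in score and equal scores receive equal EP.
#'
#' @param score numeric scores.
#' @param is_pos logical, `TRUE` for mixed-positive rows.
#' @param ratio scale factor applied to the FP count (`n_pos / n_neg`
#'   balances an unbalanced input; use 1 for an already balanced set).
#' @return `data.table` of class `fire_precision_curve` with columns
#'   `threshold`, `tmp`, `fp`, `ep_raw`, `ep`, sorted by threshold.
#' @export
precision_curve <- function(score, is_pos, ratio = 1) {
  stopifnot(length(score) == length(is_pos), length(score) > 0L)
  o <- order(score, decreasing = TRUE)
  s <- score[o]; pos <- is_pos[o]
  cp <- cumsum(pos); cn <- cumsum(!pos)
  idx <- which(!duplicated(s, fromLast = TRUE))  # deepest row per unique score
  thr <- s[idx]; tmp <- cp[idx]; fp <- cn[idx]
  ep_raw <- ifelse(tmp > 0, pmax(0, 1 - (fp * ratio + 1) / tmp), 0)
  ## ascending thresholds, running max from the lowest score up
  ord <- order(thr)
  curve <- data.table(threshold = thr[ord], tmp = tmp[ord], fp = fp[ord],
                      ep_raw = ep_raw[ord])
  curve[, ep := cummax(ep_raw)]
  setattr(curve, "class", c("fire_precision_curve", class(curve)))
  curve[]
}

#' Estimated precision of a score
#'
#' Looks up the monotonized EP for each score: the EP of the largest
#' tabulated threshold not exceeding the score (equivalently, the maximum EP
#' attained at or below it). Scores below the lowest threshold map to 0.
#'
#' @param curve a [precision_curve()] object.
#' @param score numeric vector of classifier scores.
#' @return numeric vector of EP values in `[0, 1]`.
#' @export
estimated_precision <- function(curve, score) {
  stopifnot(nrow(curve) > 0L)
  idx <- findInterval(score, curve$threshold)
  out <- numeric(length(score))
  out[idx > 0L] <- curve$ep[idx[idx > 0L]]
  out
}

#' Single-feature initialization of the positive set
#'
#' Scans every feature in both orientations for the threshold at which the
#' mixed-positive labels separate from the clean negatives at the target
#' estimated precision, and returns the feature/orientation capturing the
#' most mixed-positives at that precision. Ties go to the lower feature
#' index, ascending orientation first.
#'
#' @param labeled a labelled set from [build_training_set()].
#' @param target_ep required estimated precision (default 0.95).
#' @return list with `feature`, `orientation` (+1 / -1), `threshold` (on the
#'   oriented feature), `n_captured`, `positive_rows` (train-row indices of
#'   the captured mixed-positives) and a `diagnostics` table of the best EP
#'   per feature.
#' @export
initialize_positives <- function(labeled, target_ep = 0.95) {
  train <- labeled[split == "train"]
  fn <- feature_names(labeled)
  is_pos <- train$label == "mixed_positive"
  if (!any(is_pos) || all(is_pos)) stop("both label classes must be present")

  best <- list(n_captured = -1L)
  diag <- data.table(feature = character(0), orientation = integer(0),
                     best_ep = numeric(0))
  for (f in fn) {
    for (orient in c(1, -1)) {
      sc <- orient * train[[f]]
      curve <- precision_curve(sc, is_pos)
      ok <- curve$ep >= target_ep
      diag <- rbind(diag, data.table(feature = f, orientation = orient,
                                     best_ep = max(curve$ep)))
      if (!any(ok)) next
      thr <- curve$threshold[which(ok)[1L]]
      captured <- which(is_pos & sc >= thr)
      if (length(captured) > best$n_captured) {
        best <- list(feature = f, orientation = orient, threshold = thr,
                     n_captured = length(captured), positive_rows = captured)
      }
    }
  }
  if (best$n_captured < 0L)
    stop("no feature reaches the target estimated precision; best per feature:\n",
         paste(utils::capture.output(print(diag[order(-best_ep)])), collapse = "\n"))
  best$diagnostics <- diag
  best
}

## Per-fiber fold assignment, seeded.
assign_folds <- function(fiber_ids, nfold, seed) {
  uf <- unique(fiber_ids)
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(nfold), length(uf))), uf)
  unname(fold_of[fiber_ids])
}

xgb_params <- function(config, n_pos, n_neg) {
  list(objective = "binary:logistic", max_depth = config$max_depth,
       eta = config$eta, nthread = config$nthread,
       scale_pos_weight = n_neg / n_pos,  # positives are scarce
       eval_metric = "logloss")
}

## Train one xgboost round over the folds; returns list(models, oof_score)
## where oof_score covers every train row (scored by the model whose fold
## held that row out).
xgb_cv_round <- function(X, y_pos_rows, neg_rows, fold, config) {
  n <- nrow(X)
  y <- rep(NA_real_, n)
  y[y_pos_rows] <- 1; y[neg_rows] <- 0
  use <- !is.na(y)
  oof <- rep(NA_real_, n)
  models <- vector("list", config$nfold)
  for (f in seq_len(config$nfold)) {
    tr <- use & fold != f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    set.seed(config$seed + f)
    models[[f]] <- xgboost::xgb.train(
      params = xgb_params(config, sum(y[tr] == 1), sum(y[tr] == 0)),
      data = dtr, nrounds = config$nrounds, verbose = 0)
    ho <- which(fold == f)
    oof[ho] <- predict(models[[f]],
                       xgboost::xgb.DMatrix(X[ho, , drop = FALSE]))
  }
  list(models = models, oof = oof)
}

#' Semi-supervised training of the FIRE classifier
#'
#' Implements the iterative mixed-positive / clean-negative scheme: the
#' positive set is initialized from the single best-discriminating feature at
#' the target estimated precision, then an XGBoost ensemble is trained on the
#' current positives against all clean negatives with per-fiber k-fold
#' cross-validation, every training row is re-scored out of fold, and the
#' positive set is re-derived as the mixed-positives at the target EP. The
#' loop stops when the count of positives at the target EP (the validation
#' count, computed on out-of-fold train scores) ceases to increase, or at the
#' iteration cap; the iteration with the maximal count is kept. The final
#' estimated-precision curve is built on the untouched test split with raw
#' counts: test fibers are a random sample of the input, so the split's
#' label mix matches the population the model is applied to and the EP
#' stays calibrated at the genome scale.
#'
#' @param labeled a labelled set from [build_training_set()].
#' @param config a [classifier_config()].
#' @return An object of class `fire_model`: fold models, the test-split
#'   precision curve, the feature registry, the iteration log and the
#'   configuration.
#' @export
train_fire_model <- function(labeled, config = classifier_config()) {
  fn <- feature_names(labeled)
  train <- labeled[split == "train"]
  test <- labeled[split == "test"]
  if (!nrow(test)) stop("labelled set has no test split")
  X <- as.matrix(train[, ..fn])
  is_pos <- train$label == "mixed_positive"
  neg_rows <- which(!is_pos)
  fold <- assign_folds(train$fiber_id, config$nfold, config$seed)

  init <- initialize_positives(labeled, config$target_ep)
  pos_rows <- init$positive_rows
  log <- data.table(iteration = integer(0), n_positive_labels = integer(0),
                    n_at_target_ep = integer(0))
  best <- NULL

  for (it in seq_len(config$max_iter)) {
    if (!length(pos_rows)) {
      print(log)
      stop("positive set collapsed to empty at iteration ", it)
    }
    rnd <- xgb_cv_round(X, pos_rows, neg_rows, fold, config)
    curve <- precision_curve(rnd$oof, is_pos)
    ok <- which(curve$ep >= config$target_ep)
    if (!length(ok)) {
      log <- rbind(log, data.table(iteration = it,
                                   n_positive_labels = length(pos_rows),
                                   n_at_target_ep = 0L))
      if (is.null(best)) {
        print(log)
        stop("no score threshold reaches the target estimated precision")
      }
      break
    }
    thr <- curve$threshold[ok[1L]]
    new_pos <- which(is_pos & rnd$oof >= thr)
    count <- length(new_pos)
    log <- rbind(log, data.table(iteration = it,
                                 n_positive_labels = length(pos_rows),
                                 n_at_target_ep = count))
    if (is.null(best) || count > best$count) {
      best <- list(models = rnd$models, count = count, iteration = it)
      pos_rows <- new_pos
    } else {
      break  # validation count ceased to increase
    }
  }

  ## final curve on the untouched test split. The split is a random sample
  ## of fibers, so its label mix matches the population the model is applied
  ## to; raw counts keep the estimated precision calibrated genome-wide
  ## (downsampling to a balanced set would let the EP threshold admit a
  ## fixed quantile of the background regardless of classifier quality).
  Xt <- as.matrix(test[, ..fn])
  sc_t <- rowMeans(vapply(best$models, function(m)
    predict(m, xgboost::xgb.DMatrix(Xt)), numeric(nrow(Xt))))
  pos_t <- test$label == "mixed_positive"
  curve <- precision_curve(sc_t, pos_t, ratio = 1)

  structure(list(models = best$models, curve = curve, features = fn,
                 iteration_log = log, best_iteration = best$iteration,
                 init = init[c("feature", "orientation", "threshold",
                               "n_captured")],
                 config = config),
            class = "fire_model")
}

#' @export
print.fire_model <- function(x, ...) {
  cat("FIRE classifier:", length(x$models), "fold models,",
      length(x$features), "features\n")
  cat("converged at iteration", x$best_iteration, "with",
      x$iteration_log[iteration == x$best_iteration]$n_at_target_ep,
      "positives at the target EP\n")
  invisible(x)
}

## Average prediction of the fold models (rows unseen by every fold model).
fire_score <- function(model, X) {
  dm <- xgboost::xgb.DMatrix(X)
  rowMeans(vapply(model$models, function(m) predict(m, dm),
                  numeric(nrow(X))))
}

#' Classify MSPs as FIRE elements
#'
#' Computes features for every MSP, scores them with the trained ensemble
#' (averaging the fold models), converts scores to estimated precision via
#' the model's test-split curve, and flags MSPs with `ep >= fire_ep`
#' (default 0.90) as FIRE elements.
#'
#' @param model a `fire_model` from [train_fire_model()].
#' @param ft a `fire_fibers` table.
#' @param msps optional MSP table; segmented from `ft` when `NULL`.
#' @param params nucleosome caller parameters used when segmenting.
#' @param window_widths flank window widths (must reproduce the training
#'   feature registry).
#' @param fire_ep FIRE designation threshold on EP; defaults to the model
#'   configuration.
#' @return the MSP table with added columns `score`, `ep`, `is_fire`.
#' @export
classify_msps <- function(model, ft, msps = NULL,
                          params = nucleosome_params(),
                          window_widths = c(30L, 100L, 200L),
                          fire_ep = NULL) {
  if (is.null(fire_ep)) fire_ep <- model$config$fire_ep
  if (is.null(msps)) {
    fp <- call_nucleosomes(ft, params)
    msps <- derive_msps(ft, fp)
  }
  if (!nrow(msps)) {
    out <- copy(msps)
    out[, `:=`(score = numeric(0), ep = numeric(0), is_fire = logical(0))]
    return(out[])
  }
  feat <- msp_features(ft, msps, window_widths)
  fn <- feature_names(feat)
  if (!identical(fn, model$features))
    stop("feature registry mismatch: model was trained on a different ",
         "feature set")
  sc <- fire_score(model, as.matrix(feat[, ..fn]))
  out <- feat[, .(fiber_id, start, end)]
  out[, score := sc]
  out[, ep := estimated_precision(model$curve, sc)]
  out[, is_fire := ep >= fire_ep]
  out[]
}
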