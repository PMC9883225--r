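## The fitted-pipeline object: pah_fit() trains segmentation-to-vote on a
## labelled corpus and returns a `pah_model`; predict() reproduces the whole
## chain (segment, featurize, deep-extract, select, classify, vote) on new
## records.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline, with defaults reproducing the
#' method's printed constants: 2500 Hz working rate, 0.1 s envelope frames,
#' 50 ms merge distance, pre-emphasis 0.95, medium-time half-window 2, 1/15
#' power law, Adam (0.001, 0.9, 0.999), variance threshold 0.05, selection
#' target 212, booster 600/7/1/1/3/0.01.
#'
#' @param working_rate Working sample rate (Hz).
#' @param normalize Peak-normalize records before segmentation.
#' @param segmentation List: `window_s`, `W`, `merge_ms`, `spread_direction`,
#'   `refine`.
#' @param pncc A [pncc_config()].
#' @param cnn A [cnn_spec()].
#' @param boost A [boost_config()].
#' @param selection List: `variance_threshold`, `target_dim`.
#' @param use_deep Include the CNN deep-feature block.
#' @param split Train/validation/test record fractions.
#' @param min_s2_s Minimum S2 duration (s) for a cycle to be featurized.
#' @param seed Master seed.
#' @return A list of class `pah_config`.
#' @export
pah_config <- function(working_rate = 2500L, normalize = TRUE,
                       segmentation = list(window_s = 0.1, W = 5,
                                           merge_ms = 50,
                                           spread_direction = "<=",
                                           refine = TRUE),
                       pncc = pncc_config(), cnn = cnn_spec(),
                       boost = boost_config(),
                       selection = list(variance_threshold = 0.05,
                                        target_dim = 212L),
                       use_deep = TRUE, split = c(0.6, 0.2, 0.2),
                       min_s2_s = 0.05, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3L)
  structure(as.list(environment()), class = "pah_config")
}

## Segment + featurize one preprocessed record.  Returns NULL when the
## record is unsegmentable or yields no valid cycle.
featurize_record <- function(rec, config) {
  seg <- config$segmentation
  ann <- segment_record(rec, window_s = seg$window_s, W = seg$W,
                        merge_ms = seg$merge_ms,
                        spread_direction = seg$spread_direction,
                        refine = seg$refine)
  if (isTRUE(attr(ann, "unsegmentable"))) return(NULL)
  cyc <- extract_cycles(rec, ann)
  min_s2 <- as.integer(round(config$min_s2_s * rec$sample_rate))
  min_cyc <- max(256L, config$pncc$n_frames_out)
  feats <- list(); waves <- list(); k <- 0L
  for (cw in cyc) {
    if (length(cw$s2) < min_s2 || length(cw$cycle) < min_cyc) next
    tf <- tryCatch(time_features(cw$cycle, cw$s2, rec$sample_rate),
                   error = function(e) NULL)
    if (is.null(tf)) next
    ff <- freq_features(cw$cycle, cw$s2, rec$sample_rate)
    k <- k + 1L
    feats[[k]] <- c(tf, ff)
    waves[[k]] <- cw$cycle
  }
  if (k == 0L) return(NULL)
  list(features = do.call(rbind, feats), cycles = waves, annotation = ann)
}

## Stratified-by-record train/val/test split.
split_records <- function(labels, split, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  assign <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- max(1L, round(split[1L] * n))
    n_va <- max(0L, round(split[2L] * n))
    if (n_tr + n_va >= n) n_va <- max(0L, n - n_tr - 1L)
    assign[idx[seq_len(n_tr)]] <- "train"
    if (n_va > 0L) assign[idx[n_tr + seq_len(n_va)]] <- "validation"
    assign[idx[assign[idx] == ""]] <- "test"
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  assign
}

#' Fit the CHD-PAH screening pipeline
#'
#' Segments every record into cardiac cycles, extracts time- and
#' frequency-domain features of each cycle and its S2, optionally trains the
#' CNN on PNCC images of the training cycles and appends its 64 deep
#' features, applies the variance filter and importance selection (fitted on
#' training cycles only and replayed elsewhere), and trains the
#' gradient-boosted three-class cycle classifier. Records are split into
#' train/validation/test strata by record, never by cycle, so cycles of one
#' record never straddle a split.
#'
#' @param records List of [pcg_record()] (any rate; resampled internally) or
#'   a character vector of WAV paths.
#' @param labels Class label per record; defaults to the records' own labels.
#' @param config A [pah_config()].
#' @return An object of class `pah_model`.
#' @export
pah_fit <- function(records, labels = NULL, config = pah_config()) {
  if (is.character(records)) records <- lapply(records, load_record)
  stopifnot(length(records) >= 3L)
  if (is.null(labels))
    labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  if (any(is.na(labels))) stop("pah_fit: missing labels")
  labels <- as.character(labels)

  recs <- lapply(records, preprocess_record,
                 working_rate = config$working_rate,
                 normalize = config$normalize)
  feat <- lapply(recs, featurize_record, config = config)
  ok <- !vapply(feat, is.null, logical(1))
  if (sum(ok) < 3L) stop("pah_fit: fewer than 3 segmentable records")
  dropped <- vapply(recs[!ok], function(r) r$record_id, character(1))
  recs <- recs[ok]; feat <- feat[ok]; labels <- labels[ok]

  rec_ids <- vapply(recs, function(r) r$record_id, character(1))
  n_cyc <- vapply(feat, function(f) nrow(f$features), integer(1))
  cyc_record <- rep(seq_along(recs), n_cyc)
  X <- do.call(rbind, lapply(feat, `[[`, "features"))
  y_cyc <- labels[cyc_record]

  assign <- split_records(labels, config$split, config$seed)
  cyc_set <- assign[cyc_record]
  tr <- cyc_set == "train"

  cnn <- NULL
  if (config$use_deep) {
    pcfg <- config$pncc
    images <- vector("list", nrow(X))
    pos <- 0L
    for (i in seq_along(feat)) for (w in feat[[i]]$cycles) {
      pos <- pos + 1L
      images[[pos]] <- pncc_image(w, pcfg, config$working_rate)
    }
    cspec <- config$cnn
    cspec$input_dim <- c(pcfg$n_frames_out, pcfg$n_channels)
    cspec$seed <- config$seed
    cnn <- train_feature_extractor(images[tr], y_cyc[tr], cspec)
    deep <- extract_deep_features(images, cnn)
    X <- cbind(X, deep)
  }

  ## the variance filter screens the time-frequency block; the deep block
  ## passes through intact (the fused vector always carries all 64 deep
  ## features, matching the method's final composition)
  vf <- variance_filter(X[tr, , drop = FALSE],
                        config$selection$variance_threshold)
  keep <- vf$keep | grepl("^deep_", colnames(X))
  Xv <- X[, keep, drop = FALSE]
  sel <- importance_select(Xv[tr, , drop = FALSE], y_cyc[tr],
                           config$boost, config$selection$target_dim)
  Xs <- Xv[, sel$keep, drop = FALSE]
  booster <- train_classifier(Xs[tr, , drop = FALSE], y_cyc[tr], config$boost)

  ## per-split cycle and record accuracies
  pred_cyc <- predict(booster, Xs)
  metrics <- list()
  for (s in c("train", "validation", "test")) {
    ridx <- which(assign == s)
    if (length(ridx) == 0L) next
    cidx <- which(cyc_set == s)
    cyc_acc <- mean(pred_cyc[cidx] == y_cyc[cidx])
    rec_pred <- vapply(ridx, function(i)
      as.character(majority_vote(pred_cyc[cyc_record == i])), character(1))
    metrics[[s]] <- list(
      cycle_accuracy = cyc_acc,
      record_accuracy = mean(rec_pred == labels[ridx]),
      n_records = length(ridx), n_cycles = length(cidx),
      confusion = table(truth = factor(labels[ridx], pah_classes()),
                        predicted = factor(rec_pred, pah_classes())))
  }

  structure(list(
    booster = booster, cnn = cnn, config = config,
    variance_keep = keep, importance_keep = sel$keep,
    feature_names = colnames(Xs),
    split_assignment = data.frame(record_id = rec_ids, label = labels,
                                  set = assign, n_cycles = n_cyc),
    dropped_records = dropped, metrics = metrics,
    classes = pah_classes()
  ), class = "pah_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the class of a heart-sound record
#'
#' Segments the record, featurizes every cycle exactly as in training
#' (replaying the frozen selection masks), classifies each cycle, and
#' majority-votes the record label. A record that cannot be segmented
#' returns the explicit label `"undetermined"` rather than a silent class.
#'
#' @param object A `pah_model`.
#' @param newdata A [pcg_record()], a WAV path, or a list of either.
#' @param ... Unused.
#' @return A `data.frame` with one row per record: `record_id`,
#'   `record_label`, `n_cycles`, per-class vote counts, and the per-cycle
#'   labels as a list column `cycle_labels`.
#' @export
predict.pah_model <- function(object, newdata, ...) {
  if (inherits(newdata, "pcg_record") || is.character(newdata) &&
      length(newdata) == 1L) newdata <- list(newdata)
  config <- object$config
  rows <- lapply(newdata, function(r) {
    if (is.character(r)) r <- load_record(r)
    rec <- preprocess_record(r, config$working_rate, config$normalize)
    f <- featurize_record(rec, config)
    if (is.null(f)) {
      return(data.frame(record_id = rec$record_id,
                        record_label = "undetermined", n_cycles = 0L,
                        votes_Normal = 0L, votes_CHD = 0L, votes_CHDPAH = 0L))
    }
    X <- f$features
    if (!is.null(object$cnn)) {
      images <- lapply(f$cycles, pncc_image, config = config$pncc,
                       rate = config$working_rate)
      X <- cbind(X, extract_deep_features(images, object$cnn))
    }
    Xs <- X[, object$feature_names, drop = FALSE]
    cyc_lab <- predict(object$booster, Xs)
    v <- majority_vote(cyc_lab)
    cnts <- attr(v, "counts")
    nvotes <- function(cl)
      if (cl %in% names(cnts)) as.integer(cnts[[cl]]) else 0L
    out <- data.frame(record_id = rec$record_id,
                      record_label = as.character(v),
                      n_cycles = length(cyc_lab),
                      votes_Normal = nvotes("Normal"),
                      votes_CHD = nvotes("CHD"),
                      votes_CHDPAH = nvotes("CHD-PAH"))
    out$cycle_labels <- list(cyc_lab)
    out
  })
  do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$cycle_labels)) r$cycle_labels <- list(character(0)); r
  }))
}

#' Evaluate a fitted model on labelled records
#'
#' @param object A `pah_model`.
#' @param records List of [pcg_record()] or WAV paths.
#' @param labels True class per record (defaults to the records' labels).
#' @return `list(confusion, record_accuracy, cycle_accuracy, predictions)`.
#' @export
pah_evaluate <- function(object, records, labels = NULL) {
  if (is.character(records)) records <- lapply(records, load_record)
  if (is.null(labels))
    labels <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  pred <- predict(object, records)
  keep <- pred$record_label != "undetermined"
  conf <- table(truth = factor(labels[keep], pah_classes()),
                predicted = factor(pred$record_label[keep], pah_classes()))
  cyc_truth <- rep(labels, vapply(pred$cycle_labels, length, integer(1)))
  cyc_pred <- unlist(pred$cycle_labels)
  list(confusion = conf,
       record_accuracy = mean(pred$record_label == labels),
       cycle_accuracy = if (length(cyc_pred)) mean(cyc_pred == cyc_truth) else NA_real_,
       predictions = pred)
}

#' @export
print.pah_model <- function(x, ...) {
  n <- nrow(x$split_assignment)
  cat(sprintf("<pah_model>  %d records, %d cycles, %d fused features%s\n",
              n, sum(x$split_assignment$n_cycles),
              length(x$feature_names),
              if (is.null(x$cnn)) " (time-frequency only)" else " (incl. 64 deep)"))
  for (s in names(x$metrics)) {
    m <- x$metrics[[s]]
    cat(sprintf("  %-11s record accuracy %.3f  cycle accuracy %.3f  (n=%d)\n",
                s, m$record_accuracy, m$cycle_accuracy, m$n_records))
  }
  invisible(x)
}

#' @export
summary.pah_model <- function(object, ...) {
  cat("CHD-PAH heart-sound screening model\n")
  print(object)
  cat("\nSelected features (", length(object$feature_names), "):\n  ",
      paste(utils::head(object$feature_names, 20L), collapse = ", "),
      if (length(object$feature_names) > 20L) ", ..." else "", "\n", sep = "")
  if (!is.null(object$metrics$test)) {
    cat("\nTest-set record confusion matrix:\n")
    print(object$metrics$test$confusion)
  }
  if (length(object$dropped_records))
    cat("\nUnsegmentable records dropped: ",
        paste(object$dropped_records, collapse = ", "), "\n")
  invisible(object)
}
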