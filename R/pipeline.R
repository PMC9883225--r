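## Declarative entry point wiring the pipeline stages, with YAML config
## round-tripping and a run manifest accompanying every artifact.  The
## command-line wrapper at inst/cli/pcgpah.R is a thin shell over
## run_pipeline().

#' Write / read a pipeline configuration as YAML
#'
#' Every printed constant of the method lives in the generated default file,
#' so fidelity is auditable in one place. The round trip is lossless for all
#' numeric and character fields.
#'
#' @param config A [pah_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pah_config` (read).
#' @export
write_config <- function(config = pah_config(), path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pah_config()
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], new[[nm]])
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  out <- merge_in(unclass(cfg), raw)
  class(out) <- "pah_config"
  class(out$pncc) <- "pncc_config"
  class(out$cnn) <- "cnn_spec"
  class(out$boost) <- "boost_config"
  out
}

#' Run a pipeline stage
#'
#' Commands:
#' \describe{
#'   \item{simulate}{`n_per_class`, `seed`, `out`: write WAVs, ground-truth
#'     and manifest CSVs.}
#'   \item{segment}{`input` WAV, `out` CSV of labelled intervals.}
#'   \item{features}{`input` WAV, `out` CSV feature table (one row per cycle).}
#'   \item{train}{`manifest` CSV (`path`, `record_id`, `label`), `out` model
#'     bundle directory.}
#'   \item{predict}{`model` bundle dir, `input` WAV: returns the predicted
#'     label.}
#'   \item{evaluate}{`model`, `manifest`, `out` confusion CSV.}
#'   \item{init-config}{`out`: write the default YAML config.}
#' }
#' Each artifact directory receives a `run_manifest.json` with the seed and
#' package version. Per-record failures in `evaluate` are itemized and
#' reported, not silently skipped.
#'
#' @param command One of the verbs above.
#' @param config A [pah_config()].
#' @param ... Command arguments as named values (see above).
#' @return Command-specific value, invisibly where the result is a file.
#' @export
run_pipeline <- function(command = c("simulate", "segment", "features",
                                     "train", "predict", "evaluate",
                                     "init-config"),
                         config = pah_config(), ...) {
  command <- match.arg(command)
  args <- list(...)
  arg <- function(nm, default = NULL) args[[nm]] %||% default

  manifest_stamp <- function(dir) {
    jsonlite::write_json(
      list(seed = config$seed,
           package = as.character(utils::packageVersion("pcgpah")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file.path(dir, "run_manifest.json"), auto_unbox = TRUE)
  }

  switch(command,
    "simulate" = {
      out <- arg("out"); n <- arg("n_per_class", 5L)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      ds <- generate_dataset(n, seed = arg("seed", config$seed))
      paths <- character(length(ds$records))
      for (i in seq_along(ds$records)) {
        paths[i] <- file.path(out, paste0(ds$records[[i]]$record_id, ".wav"))
        write_record(ds$records[[i]], paths[i], sidecar = TRUE)
        utils::write.csv(ds$truths[[i]],
                         sub("\\.wav$", "_truth.csv", paths[i]),
                         row.names = FALSE)
      }
      man <- cbind(path = paths, ds$manifest)
      utils::write.csv(man, file.path(out, "manifest.csv"), row.names = FALSE)
      manifest_stamp(out)
      invisible(man)
    },
    "segment" = {
      rec <- preprocess_record(load_record(arg("input")),
                               config$working_rate, config$normalize)
      seg <- config$segmentation
      ann <- segment_record(rec, seg$window_s, seg$W, seg$merge_ms,
                            seg$spread_direction, seg$refine)
      if (!is.null(arg("out")))
        write_annotation(ann, rec$record_id, arg("out"), rec$sample_rate)
      invisible(ann)
    },
    "features" = {
      rec <- preprocess_record(load_record(arg("input")),
                               config$working_rate, config$normalize)
      f <- featurize_record(rec, config)
      if (is.null(f)) stop("run_pipeline: record unsegmentable: ", rec$record_id)
      df <- data.frame(record_id = rec$record_id,
                       cycle = seq_len(nrow(f$features)), f$features)
      if (!is.null(arg("out")))
        utils::write.csv(df, arg("out"), row.names = FALSE)
      invisible(df)
    },
    "train" = {
      man <- utils::read.csv(arg("manifest"), stringsAsFactors = FALSE)
      model <- pah_fit(man$path, man$label, config)
      out <- arg("out")
      if (!is.null(out)) {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        saveRDS(model, file.path(out, "model.rds"))
        jsonlite::write_json(
          list(variance_keep = as.list(model$variance_keep),
               selected = model$feature_names),
          file.path(out, "selection_masks.json"), auto_unbox = TRUE)
        write_config(config, file.path(out, "config.yaml"))
        manifest_stamp(out)
      }
      invisible(model)
    },
    "predict" = {
      model <- readRDS(file.path(arg("model"), "model.rds"))
      predict(model, arg("input"))
    },
    "evaluate" = {
      model <- readRDS(file.path(arg("model"), "model.rds"))
      man <- utils::read.csv(arg("manifest"), stringsAsFactors = FALSE)
      results <- vector("list", nrow(man))
      failures <- character(0)
      for (i in seq_len(nrow(man))) {
        results[[i]] <- tryCatch(predict(model, man$path[i]),
                                 error = function(e) {
          failures <<- c(failures, sprintf("%s: %s", man$record_id[i],
                                           conditionMessage(e)))
          NULL
        })
      }
      ok <- !vapply(results, is.null, logical(1))
      pred <- do.call(rbind, results[ok])
      conf <- table(truth = factor(man$label[ok], pah_classes()),
                    predicted = factor(pred$record_label,
                                       c(pah_classes(), "undetermined")))
      if (!is.null(arg("out")))
        utils::write.csv(as.data.frame.matrix(conf), arg("out"))
      if (length(failures))
        warning("evaluate: failures:\n  ", paste(failures, collapse = "\n  "))
      list(confusion = conf,
           record_accuracy = mean(pred$record_label == man$label[ok]),
           failures = failures)
    },
    "init-config" = {
      write_config(config, arg("out", "pcgpah-config.yaml"))
    })
}
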