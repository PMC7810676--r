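# Container and table I/O.  Recordings are stored as Apache Arrow
# Feather files (chunked columnar numeric storage with embedded
# metadata, readable from Python via pyarrow): one column per channel,
# sample rate / channel names / truth intervals carried in the file's
# R metadata.  Tables (events, features, folds) are plain CSV
# (comma-separated, '.' decimal, header row, UTF-8); summaries are
# JSON.  Sample indices in all files are 0-based with half-open
# [start, end) intervals.

#' Write a recording to a Feather container
#'
#' @param recording A \code{wb_recording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "wb_recording"))
  df <- as.data.frame(t(recording$samples))
  colnames(df) <- recording$sensor$channel_names
  attr(df, "wb_sample_rate") <- recording$sensor$sample_rate
  attr(df, "wb_bandwidth") <- recording$sensor$bandwidth
  attr(df, "wb_wavelengths") <- recording$sensor$wavelengths
  attr(df, "wb_truth") <- recording$truth
  arrow::write_feather(df, path)
  invisible(path)
}

#' Read a recording from a Feather container
#'
#' @param path File written by [write_recording()].
#' @return A \code{wb_recording}; errors if the container does not
#'   hold exactly 4 channels or lacks a sample rate.
#' @export
read_recording <- function(path) {
  df <- as.data.frame(arrow::read_feather(path))
  if (ncol(df) != 4L)
    stop(sprintf("recording container must have 4 channels, found %d",
                 ncol(df)), call. = FALSE)
  fs <- attr(df, "wb_sample_rate")
  if (is.null(fs)) stop("container lacks a sample rate", call. = FALSE)
  sensor <- sensor_config(
    sample_rate = fs,
    bandwidth = attr(df, "wb_bandwidth") %||% (fs / 4),
    wavelengths = attr(df, "wb_wavelengths") %||% c(808, 980),
    channel_names = colnames(df))
  truth <- attr(df, "wb_truth") %||%
    data.frame(start = integer(0), end = integer(0),
               species = character(0))
  samples <- t(as.matrix(df))
  dimnames(samples) <- list(colnames(df), NULL)
  structure(list(samples = samples, sensor = sensor, truth = truth),
            class = "wb_recording")
}

#' Write truth intervals as CSV
#'
#' Columns: \code{start_sample}, \code{end_sample} (0-based,
#' half-open), \code{species}.
#'
#' @param recording A \code{wb_recording}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_truth_csv <- function(recording, path) {
  stopifnot(inherits(recording, "wb_recording"))
  df <- data.frame(start_sample = recording$truth$start,
                   end_sample = recording$truth$end,
                   species = recording$truth$species)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write detected events as CSV
#'
#' Columns: \code{recording_id}, \code{start_sample},
#' \code{end_sample} (0-based, half-open), \code{duration_ms},
#' \code{peak_snr}.
#'
#' @param events List of \code{wb_event}.
#' @param path Output CSV path.
#' @param recording_id Identifier written in the first column.
#' @return \code{path}, invisibly.
#' @export
write_events_csv <- function(events, path, recording_id = "recording") {
  df <- data.frame(
    recording_id = recording_id,
    start_sample = vapply(events, `[[`, integer(1), "start"),
    end_sample = vapply(events, `[[`, integer(1), "end"),
    duration_ms = vapply(events, function(e) 1000 * e$duration,
                         numeric(1)),
    peak_snr = vapply(events, `[[`, numeric(1), "peak_snr"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as CSV
#'
#' One row per event: \code{event_id}, \code{label}, then the 12
#' features in canonical [feature_names()] order.
#'
#' @param dataset A \code{wb_event_set}.
#' @param path Output CSV path.
#' @param features Optional precomputed [feature_matrix()].
#' @return \code{path}, invisibly.
#' @export
write_features_csv <- function(dataset, path, features = NULL) {
  stopifnot(inherits(dataset, "wb_event_set"))
  if (is.null(features)) features <- feature_matrix(dataset)
  df <- cbind(data.frame(event_id = seq_len(nrow(features)) - 1L,
                         label = dataset$labels),
              as.data.frame(features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-fold accuracies as CSV
#'
#' One row per fold x target x method: the overall accuracy on the
#' full test set, then one \code{acc_<species>} column per species
#' holding the pairwise accuracy against that other species (NA in
#' the target's own column).
#'
#' @param evaluation A [run_experiment()] result.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_folds_csv <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "wb_evaluation"))
  species <- sort(unique(c(evaluation$pairwise$other,
                           evaluation$pairwise$target)))
  wide <- evaluation$folds
  names(wide)[names(wide) == "accuracy"] <- "overall_accuracy"
  for (sp in species) wide[[paste0("acc_", sp)]] <- NA_real_
  pw <- evaluation$pairwise
  key <- function(t, m, f) paste(t, m, f, sep = "\r")
  row_of <- match(key(pw$target, pw$method, pw$fold),
                  key(wide$target, wide$method, wide$fold))
  for (i in seq_len(nrow(pw)))
    wide[row_of[i], paste0("acc_", pw$other[i])] <- pw$accuracy[i]
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read a folds CSV back into a \code{wb_evaluation}
#'
#' @param path CSV written by [write_folds_csv()].
#' @return A \code{wb_evaluation} (without run parameters beyond what
#'   the table implies).
#' @export
read_folds_csv <- function(path) {
  wide <- read.csv(path)
  acc_cols <- grep("^acc_", names(wide), value = TRUE)
  species <- sub("^acc_", "", acc_cols)
  folds <- wide[c("target", "method", "fold", "overall_accuracy")]
  names(folds)[4] <- "accuracy"
  pair_rows <- lapply(seq_along(acc_cols), function(j) {
    v <- wide[[acc_cols[j]]]
    keep <- !is.na(v)
    data.frame(target = wide$target[keep], method = wide$method[keep],
               fold = wide$fold[keep], other = species[j],
               accuracy = v[keep])
  })
  pairwise <- do.call(rbind, pair_rows)
  pairwise <- pairwise[order(pairwise$target, pairwise$method,
                             pairwise$fold, pairwise$other), ]
  rownames(pairwise) <- NULL
  structure(list(folds = folds, pairwise = pairwise,
                 n_train_sessions = nrow(folds),
                 n_pairwise_sessions = nrow(pairwise),
                 methods = unique(folds$method),
                 targets = unique(folds$target),
                 n_folds = max(folds$fold), seed = NA_integer_),
            class = "wb_evaluation")
}

#' Write an evaluation summary as JSON
#'
#' @param summary A [summary.wb_evaluation()] result.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "wb_evaluation_summary"))
  jsonlite::write_json(list(level = summary$level,
                            overall = summary$overall,
                            pairwise = summary$pairwise,
                            hardest = summary$hardest),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write mean pairwise accuracy matrices as CSV
#'
#' Long-form stack of the per-method matrices: columns \code{method},
#' \code{target}, then one column per other species (target's own
#' column empty).
#'
#' @param summary A [summary.wb_evaluation()] result.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(summary, path) {
  stopifnot(inherits(summary, "wb_evaluation_summary"))
  methods <- unique(summary$pairwise$method)
  rows <- lapply(methods, function(m) {
    mat <- accuracy_matrix(summary, m)
    cbind(data.frame(method = m, target = rownames(mat)),
          as.data.frame(mat))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
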