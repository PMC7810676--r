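# One-vs-all evaluation: the 333/42/50 split design, fold loop,
# accuracies, bootstrap intervals and pairwise summaries.

#' Split specification
#'
#' One fold's sampling design for a given target species: 333 target
#' events plus 42 from each of the 8 other species (336) for training
#' (669 in total), and 50 per species (450) for testing.
#'
#' @param target Target species label.
#' @param n_target_train Target events in the training set.
#' @param n_other_train_each Training events from each other species.
#' @param n_test_each Test events per species (target included).
#' @param seed Integer seed for the fold's random draws.
#' @param strict If \code{TRUE} (default), train and test draws are
#'   disjoint, requiring pools of at least
#'   \code{n_target_train + n_test_each} target events and
#'   \code{n_other_train_each + n_test_each} per other species.  If
#'   \code{FALSE} (lenient), the test set is drawn from the full pool
#'   and may overlap the training set, with a warning; this
#'   accommodates pools too small for disjoint draws.
#' @return An object of class \code{wb_split_spec}.
#' @export
split_spec <- function(target,
                       n_target_train = 333L,
                       n_other_train_each = 42L,
                       n_test_each = 50L,
                       seed = 1L,
                       strict = TRUE) {
  stopifnot(n_target_train >= 1L, n_other_train_each >= 1L,
            n_test_each >= 1L)
  structure(list(target = target,
                 n_target_train = as.integer(n_target_train),
                 n_other_train_each = as.integer(n_other_train_each),
                 n_test_each = as.integer(n_test_each),
                 seed = as.integer(seed),
                 strict = strict),
            class = "wb_split_spec")
}

#' Build one train/test split
#'
#' Samples, without replacement and deterministically in the spec's
#' seed, the training and test indices for one fold.  With the default
#' counts and nine species this yields 333 + 8 x 42 = 669 training and
#' 9 x 50 = 450 test events.
#'
#' @param labels Character vector of species labels (one per event),
#'   or a \code{wb_event_set}.
#' @param spec A [split_spec()].
#' @return List with \code{train} and \code{test} integer index
#'   vectors (into the label vector), and \code{target}.
#' @export
build_split <- function(labels, spec) {
  if (inherits(labels, "wb_event_set")) labels <- labels$labels
  stopifnot(inherits(spec, "wb_split_spec"))
  species <- sort(unique(labels))
  if (!spec$target %in% species)
    stop("target species not present in dataset", call. = FALSE)
  others <- setdiff(species, spec$target)

  withr::with_seed(spec$seed, {
    take <- function(sp, n_train, n_test) {
      pool <- which(labels == sp)
      if (spec$strict) {
        if (length(pool) < n_train + n_test)
          stop(sprintf(
            "species '%s' pool (%d) too small for disjoint %d train + %d test (strict mode)",
            sp, length(pool), n_train, n_test), call. = FALSE)
        idx <- sample(pool, n_train + n_test)
        list(train = idx[seq_len(n_train)],
             test = idx[n_train + seq_len(n_test)])
      } else {
        if (length(pool) < max(n_train, n_test))
          stop(sprintf("species '%s' pool (%d) too small", sp,
                       length(pool)), call. = FALSE)
        list(train = sample(pool, n_train), test = sample(pool, n_test))
      }
    }
    parts <- c(list(take(spec$target, spec$n_target_train,
                         spec$n_test_each)),
               lapply(others, take, spec$n_other_train_each,
                      spec$n_test_each))
  })
  if (!spec$strict)
    warning("lenient split: test events may overlap training events",
            call. = FALSE)
  list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
       test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE),
       target = spec$target)
}

#' Classification accuracy
#'
#' The fraction of correctly classified events: true positives plus
#' true negatives, divided by the number of events.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A fraction in [0, 1].
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stop("predicted and truth must be non-empty and of equal length",
         call. = FALSE)
  mean(predicted == truth)
}

#' Pairwise accuracy against one specific other species
#'
#' Accuracy restricted to the test events of the target species and of
#' one specific other species (with the default design, 50 + 50 = 100
#' events): the binary accuracy the classifier achieves when the only
#' confusable species present is \code{other}.
#'
#' @param predicted Predicted binary labels
#'   (\code{"target"}/\code{"other"}) for the test events.
#' @param truth_species True species label of each test event.
#' @param target,other Species labels selecting the pair.
#' @return A fraction in [0, 1].
#' @export
pairwise_accuracy <- function(predicted, truth_species, target, other) {
  if (!any(truth_species == target) || !any(truth_species == other))
    stop("no test events for this pair", call. = FALSE)
  sel <- truth_species %in% c(target, other)
  truth_bin <- ifelse(truth_species[sel] == target, "target", "other")
  classification_accuracy(predicted[sel], truth_bin)
}

#' Percentile bootstrap interval
#'
#' The central interval of a statistic across randomized folds, by the
#' linear-interpolation percentile convention (R's default quantile
#' type 7).  At the default level this is the 5th-95th percentile
#' range, the "90% bootstrapping interval".
#'
#' @param values Numeric vector (at least 2 values).
#' @param level Coverage level.
#' @return Named numeric vector \code{c(low, high)}.
#' @examples
#' bootstrap_interval(1:100)   # c(5.95, 95.05)
#' @export
bootstrap_interval <- function(values, level = 0.90) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  a <- (1 - level) / 2
  setNames(quantile(values, probs = c(a, 1 - a), type = 7, names = FALSE),
           c("low", "high"))
}

#' Precompute classifier inputs for an event set
#'
#' One pass over the events computing, per event, the zero-padded
#' spectrum and from it the dominant frequency (WBF method input), the
#' 12 scalar features and the 2048-point spectral vector.  Computing
#' these once and passing the result to [run_experiment()] avoids
#' repeating the transforms across folds.
#'
#' @param dataset A \code{wb_event_set}.
#' @param band Search band in Hz.
#' @return An object of class \code{wb_design}: list with \code{wbf}
#'   (n x 1), \code{features} (n x 12), \code{vectors} (n x 2048),
#'   \code{labels}.
#' @export
design_matrices <- function(dataset, band = c(30, 1000)) {
  stopifnot(inherits(dataset, "wb_event_set"))
  n <- length(dataset$events)
  feats <- matrix(NA_real_, n, 12L, dimnames = list(NULL, feature_names()))
  vecs <- matrix(NA_real_, n, 2048L)
  for (i in seq_len(n)) {
    ps <- power_spectrum(dataset$events[[i]])
    feats[i, ] <- as.numeric(full_feature_set(dataset$events[[i]],
                                              spectrum = ps, band = band))
    vecs[i, ] <- spectral_vector(ps)
  }
  structure(list(wbf = feats[, "wbf", drop = FALSE],
                 features = feats,
                 vectors = vecs,
                 labels = dataset$labels),
            class = "wb_design")
}

method_inputs <- function(design, method) {
  switch(method,
         wbf = design$wbf,
         features = design$features,
         nn = design$vectors,
         stop("unknown method: ", method, call. = FALSE))
}

#' Run the full one-vs-all evaluation loop
#'
#' For every target species, method and fold: build a fresh randomized
#' split (per-fold seeds derived deterministically from the master
#' seed, so folds are reproducible and independent of evaluation
#' order), fit the classifier on the 669 training events, predict the
#' 450 test events, and record the overall accuracy plus the eight
#' pairwise accuracies against each specific other species.
#'
#' @param dataset A \code{wb_event_set}, or \code{NULL} if
#'   \code{design} is supplied.
#' @param methods Character subset of \code{c("wbf", "features", "nn")}.
#' @param n_folds Randomized repetitions per (target, method).
#' @param seed Master seed.
#' @param design Optional precomputed [design_matrices()].
#' @param targets Target species; defaults to all species present.
#' @param nn A [nn_config()] for the \code{"nn"} method.
#' @param num_trees Forest size for the tree-based methods.
#' @param split Baseline [split_spec()] counts (target field ignored).
#' @param strict Disjoint train/test draws (see [split_spec()]).
#' @param verbose Print per-target progress.
#' @return An object of class \code{wb_evaluation}: list with
#'   \code{folds} (data.frame: target, method, fold, overall
#'   accuracy), \code{pairwise} (data.frame: target, method, fold,
#'   other, accuracy), \code{n_train_sessions},
#'   \code{n_pairwise_sessions}, and the run parameters.
#' @export
run_experiment <- function(dataset = NULL,
                           methods = c("wbf", "features", "nn"),
                           n_folds = 100L,
                           seed = 1L,
                           design = NULL,
                           targets = NULL,
                           nn = nn_config(),
                           num_trees = 500L,
                           split = split_spec("placeholder"),
                           strict = TRUE,
                           verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(design)) {
    stopifnot(inherits(dataset, "wb_event_set"))
    design <- design_matrices(dataset)
  }
  labels <- design$labels
  if (is.null(targets)) targets <- sort(unique(labels))
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 1L)

  folds_rows <- list()
  pair_rows <- list()
  n_train_sessions <- 0L
  n_pairwise_sessions <- 0L

  for (target in targets) {
    if (verbose) message("target: ", target)
    others <- sort(setdiff(unique(labels), target))
    for (method in methods) {
      x_all <- method_inputs(design, method)
      for (fold in seq_len(n_folds)) {
        fold_seed <- derive_seed(seed, target, method, fold)
        sp <- split_spec(target,
                         n_target_train = split$n_target_train,
                         n_other_train_each = split$n_other_train_each,
                         n_test_each = split$n_test_each,
                         seed = fold_seed, strict = strict)
        idx <- build_split(labels, sp)
        y_train <- ifelse(labels[idx$train] == target, "target", "other")
        clf <- fit_classifier(method,
                              x_all[idx$train, , drop = FALSE], y_train,
                              seed = derive_seed(fold_seed, "fit"),
                              num_trees = num_trees, nn = nn)
        n_train_sessions <- n_train_sessions + 1L
        pred <- predict(clf, x_all[idx$test, , drop = FALSE])
        truth_species <- labels[idx$test]
        truth_bin <- ifelse(truth_species == target, "target", "other")
        folds_rows[[length(folds_rows) + 1L]] <- data.frame(
          target = target, method = method, fold = fold,
          accuracy = classification_accuracy(pred, truth_bin))
        for (other in others) {
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            target = target, method = method, fold = fold, other = other,
            accuracy = pairwise_accuracy(pred, truth_species, target,
                                         other))
          n_pairwise_sessions <- n_pairwise_sessions + 1L
        }
      }
    }
  }
  structure(list(folds = do.call(rbind, folds_rows),
                 pairwise = do.call(rbind, pair_rows),
                 n_train_sessions = n_train_sessions,
                 n_pairwise_sessions = n_pairwise_sessions,
                 methods = methods, targets = targets,
                 n_folds = n_folds, seed = seed),
            class = "wb_evaluation")
}

#' @export
print.wb_evaluation <- function(x, ...) {
  cat(sprintf("<wb_evaluation> %d targets x %d methods x %d folds: %d training sessions, %d pairwise test sessions\n",
              length(x$targets), length(x$methods), x$n_folds,
              x$n_train_sessions, x$n_pairwise_sessions))
  invisible(x)
}

#' Summarize an evaluation
#'
#' Per (target, method) and per (target, method, other species):
#' mean, median and the 90% bootstrap interval of the accuracy across
#' folds; plus, per (target, method), the hardest other species (the
#' one with the lowest mean pairwise accuracy, the floor of attainable
#' accuracy for that target).
#'
#' @param object A \code{wb_evaluation}.
#' @param level Bootstrap-interval coverage.
#' @param ... Unused.
#' @return An object of class \code{wb_evaluation_summary}: list with
#'   data frames \code{overall}, \code{pairwise}, \code{hardest}.
#' @export
summary.wb_evaluation <- function(object, level = 0.90, ...) {
  summarize <- function(df, by) {
    agg <- aggregate(df$accuracy, df[by], function(v) {
      bi <- if (length(v) >= 2L) bootstrap_interval(v, level)
            else c(low = v, high = v)
      c(mean = mean(v), median = median(v), low = bi[["low"]],
        high = bi[["high"]])
    })
    out <- cbind(agg[by], as.data.frame(agg$x))
    out[do.call(order, unname(out[by])), , drop = FALSE]
  }
  overall <- summarize(object$folds, c("target", "method"))
  pairwise <- summarize(object$pairwise, c("target", "method", "other"))
  hardest <- do.call(rbind, lapply(split(
    pairwise, pairwise[c("target", "method")], drop = TRUE),
    function(g) {
      g <- g[order(g$mean, g$other), ]   # ties: lexicographically first
      data.frame(target = g$target[1], method = g$method[1],
                 other = g$other[1], mean = g$mean[1])
    }))
  rownames(overall) <- rownames(pairwise) <- rownames(hardest) <- NULL
  structure(list(overall = overall, pairwise = pairwise,
                 hardest = hardest, level = level),
            class = "wb_evaluation_summary")
}

#' @export
print.wb_evaluation_summary <- function(x, ...) {
  cat("<wb_evaluation_summary> overall accuracy by target and method:\n")
  print(x$overall, digits = 3)
  invisible(x)
}

#' Hardest other species for a target and method
#'
#' The other species with the lowest mean pairwise accuracy across
#' folds; ties are broken lexicographically.
#'
#' @param summary A [summary.wb_evaluation()] result.
#' @param target,method Cell selectors.
#' @return A species label.
#' @export
hardest_other <- function(summary, target, method) {
  stopifnot(inherits(summary, "wb_evaluation_summary"))
  row <- summary$hardest[summary$hardest$target == target &
                           summary$hardest$method == method, ]
  if (nrow(row) == 0L) stop("no such (target, method) cell", call. = FALSE)
  row$other[1]
}

#' Compare two methods over all (target, other) pairs
#'
#' Counts, over the full grid of (target, other) species pairs (72
#' with nine species), how often each method attains the higher mean
#' pairwise accuracy.
#'
#' @param summary A [summary.wb_evaluation()] result.
#' @param method_a,method_b Method names.
#' @return List with \code{a_wins}, \code{b_wins}, \code{ties},
#'   \code{n_pairs}.
#' @export
compare_methods <- function(summary, method_a, method_b) {
  stopifnot(inherits(summary, "wb_evaluation_summary"))
  pw <- summary$pairwise
  a <- pw[pw$method == method_a, c("target", "other", "mean")]
  b <- pw[pw$method == method_b, c("target", "other", "mean")]
  m <- merge(a, b, by = c("target", "other"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L ||
      nrow(m) != nrow(a) || nrow(m) != nrow(b))
    stop("methods were not evaluated on the same (target, other) grid",
         call. = FALSE)
  list(a_wins = sum(m$mean_a > m$mean_b),
       b_wins = sum(m$mean_b > m$mean_a),
       ties = sum(m$mean_a == m$mean_b),
       n_pairs = nrow(m))
}

#' Mean pairwise accuracy matrix
#'
#' The 9 x 9 matrix (per method) of mean pairwise accuracies: rows are
#' target species, columns the specific other species tested against;
#' the diagonal is undefined (NA).
#'
#' @param summary A [summary.wb_evaluation()] result.
#' @param method Method name.
#' @return A numeric matrix with species row/column names.
#' @export
accuracy_matrix <- function(summary, method) {
  stopifnot(inherits(summary, "wb_evaluation_summary"))
  pw <- summary$pairwise[summary$pairwise$method == method, ]
  if (nrow(pw) == 0L) stop("method not in summary", call. = FALSE)
  species <- sort(unique(c(pw$target, pw$other)))
  m <- matrix(NA_real_, length(species), length(species),
              dimnames = list(target = species, other = species))
  m[cbind(pw$target, pw$other)] <- pw$mean
  m
}
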