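# One-vs-all binary classifiers: "wbf" (dominant wingbeat frequency
# only), "features" (Random Forest on the 12 scalar features) and
# "nn" (three-layer network on the 2048-point spectral vector).

#' Fit a one-vs-all binary classifier
#'
#' All three methods solve the same task -- label an event as
#' \code{"target"} or \code{"other"} -- from different representations
#' of the event:
#' \describe{
#'   \item{\code{"wbf"}}{the single dominant-frequency feature.  By
#'     default this uses the same tree-ensemble machinery as the
#'     Features method restricted to one input, isolating the effect
#'     of the representation; \code{wbf_classifier = "gaussian"}
#'     substitutes a 1-D Gaussian class-conditional classifier.}
#'   \item{\code{"features"}}{a Random Forest (500 trees, square-root
#'     feature subsampling, unlimited depth) on the 12 scalar
#'     features.}
#'   \item{\code{"nn"}}{the three-layer neural network
#'     (see [nn_config()]) on the 2048-point spectral vector.}
#' }
#'
#' @param method One of \code{"wbf"}, \code{"features"}, \code{"nn"}.
#' @param x Input matrix: n x 1 (wbf), n x 12 (features) or n x 2048
#'   (nn).  A vector is accepted for \code{"wbf"}.
#' @param y Labels: a factor/character vector with values
#'   \code{"target"}/\code{"other"}, or a logical vector
#'   (\code{TRUE} = target).  Both classes must be present.
#' @param seed Integer seed; fitting is deterministic given the seed.
#' @param num_trees Trees in the forest-based methods.
#' @param nn Passed to the \code{"nn"} method: a [nn_config()].
#' @param wbf_classifier \code{"forest"} or \code{"gaussian"}.
#' @param decision_threshold Probability above which an event is
#'   labelled \code{"target"}.
#' @return An object of class \code{wb_classifier}.
#' @examples
#' x <- matrix(c(rnorm(30, 100, 5), rnorm(30, 400, 5)))
#' y <- rep(c("target", "other"), each = 30)
#' clf <- fit_classifier("wbf", x, y, seed = 1)
#' predict(clf, matrix(c(101, 395)))
#' @export
fit_classifier <- function(method = c("wbf", "features", "nn"),
                           x, y, seed = 1L,
                           num_trees = 500L,
                           nn = nn_config(),
                           wbf_classifier = c("forest", "gaussian"),
                           decision_threshold = 0.5) {
  method <- match.arg(method)
  wbf_classifier <- match.arg(wbf_classifier)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  y <- normalize_labels(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels",
         call. = FALSE)
  expected_p <- c(wbf = 1L, features = 12L, nn = 2048L)[[method]]
  if (ncol(x) != expected_p)
    stop(sprintf("method '%s' expects %d input column(s), got %d",
                 method, expected_p, ncol(x)), call. = FALSE)

  model <- if (method == "nn") {
    nn_fit(x, y == "target", config = nn, seed = seed)
  } else if (method == "wbf" && wbf_classifier == "gaussian") {
    fit_gaussian_1d(as.vector(x), y)
  } else {
    df <- as.data.frame(x)
    colnames(df) <- paste0("f", seq_len(ncol(df)))
    ranger::ranger(x = df, y = factor(y, levels = c("other", "target")),
                   num.trees = num_trees,
                   mtry = max(1L, floor(sqrt(ncol(df)))),
                   probability = TRUE, seed = seed, num.threads = 1L)
  }
  structure(list(method = method,
                 model = model,
                 wbf_classifier = wbf_classifier,
                 decision_threshold = decision_threshold,
                 n_features = ncol(x),
                 seed = seed),
            class = "wb_classifier")
}

normalize_labels <- function(y) {
  if (is.logical(y)) return(ifelse(y, "target", "other"))
  y <- as.character(y)
  if (!all(y %in% c("target", "other")))
    stop('labels must be "target"/"other" or logical', call. = FALSE)
  y
}

# class-conditional univariate Gaussians with empirical priors
fit_gaussian_1d <- function(x, y) {
  fitc <- function(v) list(mean = mean(v), sd = max(sd(v), 1e-6))
  list(target = fitc(x[y == "target"]),
       other = fitc(x[y == "other"]),
       prior_target = mean(y == "target"))
}

#' Predicted probability of the target class
#'
#' @param classifier A fitted [fit_classifier()] object.
#' @param x Input matrix with the method's expected number of columns.
#' @return Numeric vector of probabilities in [0, 1], one per row.
#' @export
predict_proba <- function(classifier, x) {
  stopifnot(inherits(classifier, "wb_classifier"))
  if (!is.matrix(x)) x <- matrix(x, ncol = classifier$n_features)
  if (ncol(x) != classifier$n_features)
    stop(sprintf("expected %d input column(s), got %d",
                 classifier$n_features, ncol(x)), call. = FALSE)
  m <- classifier$model
  if (inherits(m, "wb_nn")) {
    nn_predict(m, x)
  } else if (inherits(m, "ranger")) {
    df <- as.data.frame(x)
    colnames(df) <- paste0("f", seq_len(ncol(df)))
    pr <- predict(m, data = df, num.threads = 1L)$predictions
    as.vector(pr[, "target"])
  } else {
    v <- as.vector(x)
    lt <- dnorm(v, m$target$mean, m$target$sd) * m$prior_target
    lo <- dnorm(v, m$other$mean, m$other$sd) * (1 - m$prior_target)
    ifelse(lt + lo > 0, lt / (lt + lo), 0.5)
  }
}

#' Predict labels or probabilities
#'
#' @param object A fitted \code{wb_classifier}.
#' @param x Input matrix.
#' @param type \code{"label"} (default) or \code{"prob"}.
#' @param ... Unused.
#' @return Character vector of \code{"target"}/\code{"other"}, or a
#'   probability vector.
#' @export
predict.wb_classifier <- function(object, x, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, x)
  if (type == "prob") p
  else ifelse(p >= object$decision_threshold, "target", "other")
}

#' @export
print.wb_classifier <- function(x, ...) {
  cat(sprintf("<wb_classifier> method = %s (%d input feature%s), threshold %.2f\n",
              x$method, x$n_features, if (x$n_features > 1) "s" else "",
              x$decision_threshold))
  invisible(x)
}
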