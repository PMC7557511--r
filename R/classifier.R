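# Per-feature z-scoring. Raw band energies span orders of magnitude (and
# scale quadratically with amplitude), so features are standardized with
# statistics fitted on training data only; constant features get sd 1 so
# they standardize to 0 instead of NaN.
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_standardizer <- function(std, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Fit a facial-action classifier
#'
#' End-to-end supervised fit: z-scores the feature table (statistics from
#' this training set only), encodes labels to the two-bit targets, and
#' trains the single-hidden-layer log-sigmoid network with the requested
#' optimizer. The hidden layer defaults to 16 units, giving the 12-16-2
#' production layout on the 12 band-energy features.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Character vector of action labels, one per row.
#' @param optimizer `"lmbp"` (Levenberg-Marquardt, default) or `"adam"`.
#' @param hidden Hidden-layer width (default 16).
#' @param config `training_config`.
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `facemyo_classifier`: the trained `net`, the
#'   `standardizer`, the training `trace`/`termination`, and metadata.
#' @export
#' @examples
#' ds <- synthesize_dataset(session_plan(2, 2), seed = 1)
#' ft <- build_feature_table(extract_epochs(preprocess_recording(ds$recording)))
#' clf <- fit_classifier(ft$features, ft$labels, seed = 1,
#'                       config = training_config(max_epochs = 50))
#' mean(predict(clf, ft$features) == ft$labels)
fit_classifier <- function(features, labels, optimizer = c("lmbp", "adam"),
                           hidden = 16, config = training_config(),
                           seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(nrow(features) == length(labels))
  std <- fit_standardizer(features)
  Xs <- apply_standardizer(std, features)
  Y <- encode_actions(labels)
  net <- init_network(c(ncol(features), hidden, 2), seed = seed)
  fit <- if (optimizer == "lmbp") train_lmbp(net, Xs, Y, config)
         else train_adam(net, Xs, Y, config)
  structure(
    list(net = fit$net, standardizer = std, optimizer = optimizer,
         trace = fit$trace, termination = fit$termination,
         E_final = fit$E_final, epochs = fit$epochs,
         feature_names = colnames(features)),
    class = "facemyo_classifier"
  )
}

#' Predict facial actions
#'
#' Standardizes the rows with the training-set statistics, runs the forward
#' pass, thresholds each output unit at 0.5 and decodes the bit pair to an
#' action label.
#'
#' @param object `facemyo_classifier`.
#' @param newdata Feature matrix (samples x features).
#' @param ... Unused.
#' @return Character vector of predicted action labels.
#' @export
predict.facemyo_classifier <- function(object, newdata, ...) {
  Xs <- apply_standardizer(object$standardizer, newdata)
  decode_outputs(forward(object$net, Xs)$output)
}

#' Continuous network outputs for a feature matrix
#'
#' @param object `facemyo_classifier`.
#' @param newdata Feature matrix.
#' @return Samples x 2 matrix of log-sigmoid outputs in (0, 1).
#' @export
classifier_outputs <- function(object, newdata) {
  stopifnot(inherits(object, "facemyo_classifier"))
  Xs <- apply_standardizer(object$standardizer, newdata)
  forward(object$net, Xs)$output
}

#' @export
print.facemyo_classifier <- function(x, ...) {
  cat(sprintf("<facemyo_classifier> %s, layout %s, final E = %.3g (%s after %d epochs)\n",
              x$optimizer, paste(x$net$layout, collapse = "-"),
              x$E_final, x$termination, x$epochs))
  invisible(x)
}
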