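#' Discretize a feature value into one of 20 bins
#'
#' The per-patient expression-difference features range over [0, 1]; they
#' are discretized into 20 half-open bins `[k/20, (k+1)/20)` with the value
#' 1.0 folded into the last bin (index 19, zero-based). Values slightly
#' outside [0, 1] are clamped with a warning.
#'
#' @param value numeric vector of feature values.
#' @param n_bins number of bins (20 by default).
#' @return Integer vector of bin indices in `0:(n_bins - 1)`.
#' @export
discretize <- function(value, n_bins = 20L) {
  if (any(!is.finite(value))) stop("discretize: non-finite value")
  if (any(value < 0 | value > 1)) {
    warning("discretize: values outside [0, 1] clamped")
    value <- pmin(pmax(value, 0), 1)
  }
  pmin(as.integer(floor(value * n_bins)), n_bins - 1L)
}

#' Fit the binned naive Bayes outcome classifier
#'
#' Class priors are empirical frequencies (X_good / X). Per signature and
#' class, bin likelihoods are `(count in bin + alpha) / (X_class +
#' n_bins * alpha)`; `alpha = 0` gives the plain empirical frequencies,
#' the default `alpha = 1` (Laplace) keeps every likelihood positive so
#' log scores stay finite on bins unseen in training.
#'
#' @param features patients x signatures matrix in [0, 1]
#'   (e.g. from [patient_features()]).
#' @param labels named character vector, patient -> "good"/"poor"; only
#'   patients present in `features` are used.
#' @param alpha Laplace pseudocount >= 0.
#' @param n_bins number of discretization bins.
#' @return A list of class `caerus_nb`: `classes`, `priors`, `likelihoods`
#'   (per signature, 2 x n_bins matrix), `class_counts`, `alpha`, `n_bins`,
#'   `signatures`.
#' @export
nb_fit <- function(features, labels, alpha = 1, n_bins = 20L) {
  stopifnot(is.matrix(features), alpha >= 0)
  patients <- rownames(features)
  labels <- labels[patients]
  if (any(is.na(labels))) stop("every training patient needs a label")
  classes <- c("good", "poor")
  counts <- c(good = sum(labels == "good"), poor = sum(labels == "poor"))
  if (any(counts == 0)) stop("each class needs at least one training patient")
  priors <- counts / sum(counts)
  bins <- matrix(discretize(features, n_bins), nrow = nrow(features),
                 dimnames = dimnames(features))
  likelihoods <- lapply(colnames(features), function(s) {
    lk <- vapply(classes, function(cl) {
      b <- bins[labels == cl, s]
      (tabulate(b + 1L, nbins = n_bins) + alpha) / (counts[[cl]] + n_bins * alpha)
    }, numeric(n_bins))
    t(lk)   # classes x bins
  })
  names(likelihoods) <- colnames(features)
  structure(
    list(
      classes = classes, priors = priors, likelihoods = likelihoods,
      class_counts = counts, alpha = alpha, n_bins = as.integer(n_bins),
      signatures = colnames(features)
    ),
    class = "caerus_nb"
  )
}

#' Predict outcome for patients with a fitted naive Bayes model
#'
#' Per class, the log score is `log prior + sum over signatures of
#' log likelihood[bin]`; the predicted class maximizes the score, with
#' exact ties resolved to "good" (the majority outcome in typical
#' cohorts; conservative for poor calls). The good-class posterior is the
#' log-sum-exp-normalized score. With `alpha = 0` a zero-probability bin
#' drives a class's score to -Inf; if both classes hit -Inf the patient is
#' called "good" with a warning.
#'
#' @param model a `caerus_nb` from [nb_fit()].
#' @param features patients x signatures matrix covering the model's
#'   signatures (a single patient's named vector is also accepted).
#' @return data.frame with columns `patient`, `predicted`, `score_good`,
#'   `score_poor`, `posterior_good`.
#' @export
nb_predict <- function(model, features) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("patient", names(features)))
  }
  miss <- setdiff(model$signatures, colnames(features))
  if (length(miss)) {
    stop(sprintf("feature matrix missing model signatures: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  features <- features[, model$signatures, drop = FALSE]
  bins <- matrix(discretize(features, model$n_bins), nrow = nrow(features))
  n <- nrow(features)
  score <- matrix(rep(log(model$priors), each = n), nrow = n,
                  dimnames = list(rownames(features), model$classes))
  for (j in seq_along(model$signatures)) {
    lk <- model$likelihoods[[j]]
    score[, "good"] <- score[, "good"] + log(lk["good", bins[, j] + 1L])
    score[, "poor"] <- score[, "poor"] + log(lk["poor", bins[, j] + 1L])
  }
  both_dead <- score[, "good"] == -Inf & score[, "poor"] == -Inf
  if (any(both_dead)) {
    warning("zero posterior under both classes; predicting 'good'")
  }
  predicted <- ifelse(score[, "poor"] > score[, "good"], "poor", "good")
  m <- pmax(score[, "good"], score[, "poor"])
  m[both_dead] <- 0  # define posterior 0.5 for the doubly-impossible case
  pg <- exp(score[, "good"] - m) /
    (exp(score[, "good"] - m) + exp(score[, "poor"] - m))
  pg[both_dead] <- 0.5
  data.frame(
    patient = rownames(features) %||% paste0("p", seq_len(n)),
    predicted = unname(predicted),
    score_good = unname(score[, "good"]),
    score_poor = unname(score[, "poor"]),
    posterior_good = unname(pg)
  )
}

#' Serialize a fitted model to versioned JSON
#'
#' @param model a `caerus_nb`.
#' @param path output file path.
#' @export
nb_write_json <- function(model, path) {
  obj <- list(
    format = "caerus-nb", version = 1L,
    classes = model$classes,
    priors = as.list(model$priors),
    class_counts = as.list(model$class_counts),
    alpha = model$alpha, n_bins = model$n_bins,
    signatures = model$signatures,
    likelihoods = lapply(model$likelihoods, function(m) {
      list(good = unname(m["good", ]), poor = unname(m["poor", ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [nb_write_json()]
#'
#' @param path JSON file path.
#' @return A `caerus_nb` model.
#' @export
nb_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "caerus-nb")) stop("not a caerus-nb model file")
  likelihoods <- lapply(obj$likelihoods, function(l) {
    rbind(good = as.numeric(l$good), poor = as.numeric(l$poor))
  })
  structure(
    list(
      classes = obj$classes,
      priors = stats::setNames(as.numeric(obj$priors), names(obj$priors)),
      likelihoods = likelihoods[obj$signatures],
      class_counts = stats::setNames(as.numeric(obj$class_counts),
                                     names(obj$class_counts)),
      alpha = obj$alpha, n_bins = as.integer(obj$n_bins),
      signatures = obj$signatures
    ),
    class = "caerus_nb"
  )
}
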