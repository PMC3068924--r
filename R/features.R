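#' Pearson correlation with explicit degeneracy handling
#'
#' Standard product-moment correlation. Constant vectors make the
#' correlation undefined; downstream code treats such neighbors as
#' unusable, so here the undefined case returns `NA` with a warning rather
#' than an error.
#'
#' @param xs,ys numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("pearson: length mismatch")
  if (length(xs) < 3) stop("pearson: need at least 3 observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    warning("pearson: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(xs, ys)
}

#' Group-level co-expression discrimination score of a signature
#'
#' Measures how differently a gene signature co-expresses with its PPI
#' neighbors between outcome groups: for each usable neighbor p the Pearson
#' correlation of signature and neighbor expression is computed separately
#' within good-outcome and poor-outcome patients, and the score is the mean
#' absolute correlation difference divided by 2, mapping the raw range
#' [0, 2] onto [0, 1]. Neighbors absent from the expression matrix or with
#' an undefined correlation in either group are excluded and the
#' denominator reduced.
#'
#' This is a training-set diagnostic over patient groups; the per-patient
#' classifier features come from [patient_features()].
#'
#' @param signature protein/gene id present in the cohort.
#' @param bundle a `caerus_bundle` supplying the PPI neighborhood.
#' @param cohort a `caerus_cohort`; each outcome group needs >= 3 patients.
#' @return A list of class `caerus_discrimination`: `signature`,
#'   `n_neighbors`, `per_neighbor` (data.frame neighbor/r_good/r_poor),
#'   `score` in [0, 1].
#' @export
discrimination_score <- function(signature, bundle, cohort) {
  assert_protein(bundle, signature)
  if (!signature %in% cohort$genes) {
    stop(sprintf("signature '%s' not measured in the cohort", signature))
  }
  good <- cohort$patients[cohort$labels == "good"]
  poor <- cohort$patients[cohort$labels == "poor"]
  if (length(good) < 3 || length(poor) < 3) {
    stop("each outcome group needs at least 3 patients")
  }
  nb <- intersect(neighbors(bundle, signature), cohort$genes)
  x_good <- cohort$values[signature, good]
  x_poor <- cohort$values[signature, poor]
  rows <- list()
  for (p in nb) {
    r_g <- suppressWarnings(pearson(x_good, cohort$values[p, good]))
    r_p <- suppressWarnings(pearson(x_poor, cohort$values[p, poor]))
    if (is.na(r_g) || is.na(r_p)) {
      warning(sprintf("neighbor '%s' of '%s' excluded: undefined correlation",
                      p, signature))
      next
    }
    rows[[p]] <- data.frame(neighbor = p, r_good = r_g, r_poor = r_p)
  }
  if (!length(rows)) {
    stop(sprintf("signature '%s' has no usable neighbor in the cohort", signature))
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  n <- nrow(per)
  structure(
    list(
      signature = signature, n_neighbors = n, per_neighbor = per,
      score = sum(abs(per$r_good - per$r_poor)) / (2 * n)
    ),
    class = "caerus_discrimination"
  )
}

#' Rank-scale one patient's expression column
#'
#' Within a single patient, genes are ranked ascending (average ranks on
#' ties) and mapped to `(rank - 1) / (G - 1)`, so every patient's profile
#' occupies [0, 1] regardless of platform or scale. A fully constant column
#' maps to 0.5 everywhere.
#'
#' @param column numeric vector of expression values over >= 2 genes.
#' @return Numeric vector in [0, 1], same length and names.
#' @export
rank_scale_patient <- function(column) {
  g <- length(column)
  if (g < 2) stop("rank_scale_patient: need at least 2 genes")
  (rank(column, ties.method = "average") - 1) / (g - 1)
}

#' Per-patient signature-neighborhood expression-difference features
#'
#' For each patient x and signature i with usable neighbors N_i, the
#' feature is the mean absolute difference between the rank-scaled
#' expression of the signature and of each neighbor:
#' `v_i(x) = mean over p in N_i of |e_x(i) - e_x(p)|`, with `e_x` the
#' patient's rank-scaled profile ([rank_scale_patient()]) so that every
#' feature lies in [0, 1]. With `mode = "raw"` the raw expression values
#' are min-max scaled per patient instead of rank-scaled.
#'
#' Signatures not measured in the cohort or with no measured neighbor are
#' dropped with a warning.
#'
#' @param signatures ordered character vector of signature ids.
#' @param bundle a `caerus_bundle`.
#' @param cohort a `caerus_cohort`.
#' @param mode "rank" (default) or "raw" per-patient scaling.
#' @return Numeric matrix patients x signatures with values in [0, 1],
#'   of class `caerus_features`.
#' @export
patient_features <- function(signatures, bundle, cohort,
                             mode = c("rank", "raw")) {
  mode <- match.arg(mode)
  if (!length(signatures)) stop("empty signature list")
  usable <- list()
  for (s in signatures) {
    if (!s %in% cohort$genes) {
      warning(sprintf("signature '%s' not measured in the cohort; dropped", s))
      next
    }
    nb <- intersect(neighbors(bundle, s), cohort$genes)
    nb <- setdiff(nb, s)
    if (!length(nb)) {
      warning(sprintf("signature '%s' has no measured neighbor; dropped", s))
      next
    }
    usable[[s]] <- nb
  }
  if (!length(usable)) stop("no signature with usable neighbors")
  scaled <- apply(cohort$values, 2, function(col) {
    if (mode == "rank") {
      rank_scale_patient(col)
    } else {
      rng <- range(col)
      if (rng[1] == rng[2]) rep(0.5, length(col))
      else (col - rng[1]) / (rng[2] - rng[1])
    }
  })
  rownames(scaled) <- cohort$genes
  feat <- vapply(names(usable), function(s) {
    nb <- usable[[s]]
    d <- abs(sweep(scaled[nb, , drop = FALSE], 2, scaled[s, ]))
    colMeans(d)
  }, numeric(length(cohort$patients)))
  feat <- matrix(feat, nrow = length(cohort$patients),
                 dimnames = list(cohort$patients, names(usable)))
  structure(feat, class = c("caerus_features", "matrix", "array"))
}
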