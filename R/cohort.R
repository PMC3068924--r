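#' Construct a patient cohort
#'
#' Bundles an expression matrix (genes in rows, patients in columns) with
#' binary outcome labels. Every patient must carry a label of `"good"`
#' (disease-free after follow-up) or `"poor"` (died of disease).
#'
#' @param values numeric matrix, genes x patients, with row and column names.
#' @param labels named character vector mapping patient id to
#'   "good"/"poor"; order-independent.
#' @return An object of class `caerus_cohort` with components `genes`,
#'   `patients`, `values`, `labels`.
#' @export
patient_cohort <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (genes x patients)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and patient colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate patient identifiers")
  patients <- colnames(values)
  missing <- setdiff(patients, names(labels))
  if (length(missing)) {
    stop(sprintf("patients without outcome label: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  labels <- labels[patients]
  if (!all(labels %in% c("good", "poor"))) {
    stop("labels must be 'good' or 'poor'")
  }
  structure(
    list(
      genes = rownames(values),
      patients = patients,
      values = values,
      labels = labels
    ),
    class = "caerus_cohort"
  )
}

#' @export
print.caerus_cohort <- function(x, ...) {
  cat(sprintf(
    "<caerus_cohort> %d genes x %d patients (%d good, %d poor)\n",
    length(x$genes), length(x$patients),
    sum(x$labels == "good"), sum(x$labels == "poor")
  ))
  invisible(x)
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort a `caerus_cohort`.
#' @param patients patient ids to keep, in the given order.
#' @return A `caerus_cohort` over the subset.
#' @export
subset_patients <- function(cohort, patients) {
  stopifnot(all(patients %in% cohort$patients))
  patient_cohort(cohort$values[, patients, drop = FALSE], cohort$labels)
}
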