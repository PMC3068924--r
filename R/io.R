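#' Read a two-column tab-delimited file
#'
#' TSV dialect used throughout: tab-separated, UTF-8, `#` comment lines,
#' no header unless stated, no quoting. Identifiers are opaque
#' case-sensitive strings.
#'
#' @param path file path.
#' @param what label used in error messages.
#' @param allow_empty if `TRUE`, a file with no records yields a 0-row
#'   matrix instead of an error.
#' @return Character matrix with two columns.
#' @keywords internal
read_two_col <- function(path, what = "input", allow_empty = FALSE) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    if (allow_empty) return(matrix(character(0), ncol = 2))
    stop(sprintf("%s file is empty: %s", what, path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("%s file %s: malformed line %d (expected 2 tab-separated fields)",
                 what, path, bad[1]))
  }
  matrix(unlist(parts), ncol = 2, byrow = TRUE)
}

#' Read an interactome bundle from its four input files
#'
#' @param ppi_path two-column TSV of protein pairs (required).
#' @param annotation_path two-column TSV (protein, domain); optional.
#' @param ddi_path two-column TSV of domain pairs; optional.
#' @param mutation_path two-column TSV (domain, non-negative count);
#'   optional.
#' @param quiet suppress the parse-summary message.
#' @return A `caerus_bundle`.
#' @export
read_bundle <- function(ppi_path, annotation_path = NULL, ddi_path = NULL,
                        mutation_path = NULL, quiet = FALSE) {
  edges <- read_two_col(ppi_path, "PPI edge list")
  annotation <- if (!is.null(annotation_path)) {
    read_two_col(annotation_path, "domain annotation", allow_empty = TRUE)
  }
  ddi <- if (!is.null(ddi_path)) {
    read_two_col(ddi_path, "DDI catalog", allow_empty = TRUE)
  }
  mutation_counts <- NULL
  if (!is.null(mutation_path)) {
    m <- read_two_col(mutation_path, "mutation counts", allow_empty = TRUE)
    cnt <- suppressWarnings(as.numeric(m[, 2]))
    if (any(is.na(cnt))) stop("mutation counts must be numeric")
    mutation_counts <- tapply(cnt, m[, 1], sum)
    mutation_counts <- stats::setNames(as.numeric(mutation_counts),
                                       names(mutation_counts))
  }
  interactome_bundle(edges, annotation, ddi, mutation_counts, quiet = quiet)
}

#' Write an interactome bundle to the four input files
#'
#' Inverse of [read_bundle()]: writes canonical edges, annotation rows,
#' DDI pairs and non-zero mutation counts.
#'
#' @param bundle a `caerus_bundle`.
#' @param ppi_path,annotation_path,ddi_path,mutation_path output paths.
#' @export
write_bundle <- function(bundle, ppi_path, annotation_path, ddi_path,
                         mutation_path) {
  write_tsv_matrix(bundle$edges, ppi_path)
  ann <- do.call(rbind, lapply(names(bundle$annotation), function(p) {
    cbind(p, sort(bundle$annotation[[p]]))
  }))
  write_tsv_matrix(ann %||% matrix(character(0), ncol = 2), annotation_path)
  ddi <- do.call(rbind, strsplit(sort(bundle$ddi_keys), "|", fixed = TRUE))
  write_tsv_matrix(ddi %||% matrix(character(0), ncol = 2), ddi_path)
  mut <- bundle$mutation_counts
  mutm <- cbind(names(mut), as.character(mut))
  write_tsv_matrix(mutm[order(names(mut)), , drop = FALSE], mutation_path)
  invisible(NULL)
}

write_tsv_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an expression cohort from TSV files
#'
#' The expression matrix has a header row of patient ids and a first
#' column of gene ids; the label file is a two-column TSV
#' (patient, good|poor), no header.
#'
#' @param expression_path expression matrix TSV.
#' @param labels_path outcome label TSV.
#' @return A `caerus_cohort`.
#' @export
read_cohort <- function(expression_path, labels_path) {
  if (!file.exists(expression_path)) {
    stop(sprintf("expression file not found: %s", expression_path))
  }
  df <- utils::read.delim(expression_path, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  lab <- read_two_col(labels_path, "labels")
  labels <- stats::setNames(lab[, 2], lab[, 1])
  patient_cohort(values, labels)
}

#' Write an expression cohort to TSV files
#'
#' @param cohort a `caerus_cohort`.
#' @param expression_path,labels_path output paths.
#' @export
write_cohort <- function(cohort, expression_path, labels_path) {
  df <- data.frame(gene = cohort$genes, cohort$values, check.names = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_matrix(cbind(cohort$patients, unname(cohort$labels)), labels_path)
  invisible(NULL)
}

#' Write the per-protein scoring report
#'
#' @param report data.frame from [score_report()].
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as TSV
#'
#' @param features patients x signatures matrix.
#' @param path output TSV path (first column `patient`).
#' @export
write_features <- function(features, path) {
  df <- data.frame(patient = rownames(features),
                   unclass(features)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation result as JSON (plus prediction/ROC TSVs)
#'
#' @param cv a `caerus_cv` result.
#' @param dir output directory (created if absent).
#' @return Paths of the written files, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf_list <- function(m) {
    if (is.null(m)) return(NULL)
    list(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
         accuracy = m$accuracy, sensitivity = m$sensitivity,
         specificity = m$specificity)
  }
  obj <- list(
    seed = cv$seed,
    auc = cv$auc,
    pooled = conf_list(cv$pooled),
    folds = lapply(cv$folds, function(f) {
      list(chosen_c = f$chosen_c, metrics = conf_list(f$metrics))
    })
  )
  json_path <- file.path(dir, "cv_report.json")
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  pred_path <- file.path(dir, "predictions.tsv")
  utils::write.table(cv$predictions, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roc_path <- file.path(dir, "roc.tsv")
  utils::write.table(cv$roc, roc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, predictions = pred_path, roc = roc_path))
}

#' Run the full scoring-to-classification pipeline
#'
#' Reads the interactome files and the cohort, scores all proteins,
#' selects signatures, builds per-patient features, runs the requested
#' cross-validation protocol and writes all reports into `out_dir`:
#' `score_report.tsv`, `signatures.txt`, `features.tsv`, `cv_report.json`,
#' `predictions.tsv`, `roc.tsv`.
#'
#' @param ppi_path,annotation_path,ddi_path,mutation_path interactome
#'   input files (see [read_bundle()]).
#' @param expression_path,labels_path cohort input files
#'   (see [read_cohort()]).
#' @param out_dir output directory.
#' @param protocol "five_fold" ([nested_cv()]) or "loocv" ([loocv()]).
#' @param c_grid candidate thresholds for tuning.
#' @param use_mutations use the mutation-weighted score.
#' @param seed integer seed (mandatory).
#' @param cfg a [score_config()].
#' @param alpha classifier smoothing.
#' @param feature_mode "rank" or "raw".
#' @return The `caerus_cv` result, invisibly.
#' @export
run_pipeline <- function(ppi_path, annotation_path, ddi_path, mutation_path,
                         expression_path, labels_path, out_dir,
                         protocol = c("five_fold", "loocv"),
                         c_grid = seq(10, 150, by = 10),
                         use_mutations = FALSE, seed,
                         cfg = score_config(), alpha = 1,
                         feature_mode = "rank") {
  protocol <- match.arg(protocol)
  if (missing(seed)) stop("seed is mandatory for the pipeline")
  bundle <- read_bundle(ppi_path, annotation_path, ddi_path, mutation_path,
                        quiet = TRUE)
  cohort <- read_cohort(expression_path, labels_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- score_report(bundle, cfg, use_mutations)
  write_report(report, file.path(out_dir, "score_report.tsv"))
  sigs <- sort(unique(report$protein[report$is_signature]))
  writeLines(sigs, file.path(out_dir, "signatures.txt"))
  if (length(sigs)) {
    feats <- tryCatch(
      suppressWarnings(patient_features(sigs, bundle, cohort, feature_mode)),
      error = function(e) NULL
    )
    if (!is.null(feats)) {
      write_features(feats, file.path(out_dir, "features.tsv"))
    }
  }
  cv <- if (protocol == "five_fold") {
    nested_cv(bundle, cohort, c_grid, use_mutations, seed, cfg, alpha,
              feature_mode = feature_mode)
  } else {
    loocv(bundle, cohort, c_grid, use_mutations, seed, cfg, alpha,
          feature_mode = feature_mode)
  }
  write_cv_report(cv, out_dir)
  invisible(cv)
}

#' Write a simulated bundle, cohort and ground truth to a directory
#'
#' Emits the five pipeline input files (`ppi.tsv`, `annotation.tsv`,
#' `ddi.tsv`, `mutations.tsv`, `expression.tsv` + `labels.tsv`) plus
#' `truth.json` naming the planted signatures.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @return File paths, invisibly.
#' @export
simulate_to_files <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_bundle(cfg)
  cohort <- simulate_cohort(sim, cfg)
  paths <- c(
    ppi = file.path(dir, "ppi.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    ddi = file.path(dir, "ddi.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_bundle(sim$bundle, paths["ppi"], paths["annotation"], paths["ddi"],
               paths["mutations"])
  write_cohort(cohort, paths["expression"], paths["labels"])
  jsonlite::write_json(
    list(planted_signatures = sim$truth$planted_signatures,
         hub_domains = as.list(sim$truth$hub_domains),
         effect_delta = cfg$effect_delta, noise_sigma = cfg$noise_sigma,
         seed = cfg$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
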