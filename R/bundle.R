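#' Construct an interactome bundle
#'
#' An `InteractomeBundle` holds the four data layers the scoring model
#' operates on: a protein-protein interaction (PPI) graph, a protein-to-Pfam
#' domain annotation, a catalog of structurally observed domain-domain
#' interactions (DDIs), and per-domain somatic mutation counts.
#'
#' Edges are stored canonically (lexicographically ordered endpoints),
#' duplicates and self-interactions are dropped, and an adjacency list is
#' precomputed for neighbor lookups. Proteins mentioned only in the
#' annotation are retained as isolated (degree-0) nodes; proteins with no
#' annotation row have an empty domain set. Mutation counts default to 0 for
#' unlisted domains.
#'
#' @param edges two-column character matrix or data.frame of undirected
#'   protein pairs (one interaction per row).
#' @param annotation two-column character matrix or data.frame
#'   (protein, domain), one row per protein-domain assignment.
#' @param ddi two-column character matrix or data.frame of unordered
#'   interacting domain pairs.
#' @param mutation_counts named numeric vector of non-negative somatic
#'   mutation counts per domain (may be empty or `NULL`).
#' @param quiet suppress the parse-summary message.
#' @return An object of class `caerus_bundle` with components `proteins`,
#'   `edges` (canonical two-column matrix), `adjacency` (named list of
#'   neighbor vectors), `annotation` (named list of domain character
#'   vectors), `ddi_keys` (canonical "a|b" keys of the DDI catalog) and
#'   `mutation_counts`.
#' @examples
#' b <- interactome_bundle(
#'   edges = cbind(c("A", "A"), c("B", "C")),
#'   annotation = cbind(c("A", "B", "C"), c("d1", "d2", "d2")),
#'   ddi = cbind("d1", "d2")
#' )
#' neighbors(b, "A")
#' @export
interactome_bundle <- function(edges, annotation = NULL, ddi = NULL,
                               mutation_counts = NULL, quiet = TRUE) {
  edges <- as_two_col(edges, "edges")
  n_raw <- nrow(edges)
  self <- edges[, 1] == edges[, 2]
  edges <- edges[!self, , drop = FALSE]
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    dup <- duplicated(paste(edges[, 1], edges[, 2], sep = "\r"))
    edges <- edges[!dup, , drop = FALSE]
  } else {
    dup <- logical(0)
  }
  if (!quiet) {
    message(sprintf(
      "interactome_bundle: %d edge records read, %d self-interactions and %d duplicates dropped, %d edges kept",
      n_raw, sum(self), sum(dup), nrow(edges)
    ))
  }

  annotation <- if (is.null(annotation)) {
    matrix(character(0), ncol = 2)
  } else {
    as_two_col(annotation, "annotation")
  }
  ann_list <- lapply(
    split(annotation[, 2], factor(annotation[, 1], levels = unique(annotation[, 1]))),
    unique
  )

  proteins <- sort(unique(c(edges[, 1], edges[, 2], names(ann_list))))

  adjacency <- stats::setNames(vector("list", length(proteins)), proteins)
  for (p in proteins) adjacency[[p]] <- character(0)
  if (nrow(edges)) {
    nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    adjacency[names(nb)] <- lapply(nb, function(x) sort(unique(x)))
  }

  ddi <- if (is.null(ddi)) matrix(character(0), ncol = 2) else as_two_col(ddi, "ddi")
  ddi_keys <- unique(ddi_key(ddi[, 1], ddi[, 2]))

  mutation_counts <- mutation_counts %||% stats::setNames(numeric(0), character(0))
  if (length(mutation_counts) && (is.null(names(mutation_counts)) ||
                                  any(!nzchar(names(mutation_counts))))) {
    stop("mutation_counts must be a named vector (names are domain ids)")
  }
  if (any(mutation_counts < 0)) stop("mutation_counts must be non-negative")

  structure(
    list(
      proteins = proteins,
      edges = edges,
      adjacency = adjacency,
      annotation = ann_list,
      ddi_keys = ddi_keys,
      mutation_counts = mutation_counts
    ),
    class = "caerus_bundle"
  )
}

#' @export
print.caerus_bundle <- function(x, ...) {
  cat(sprintf(
    "<caerus_bundle> %d proteins, %d PPI edges, %d annotated proteins, %d DDI pairs, %d mutated domains\n",
    length(x$proteins), nrow(x$edges), length(x$annotation),
    length(x$ddi_keys), sum(x$mutation_counts > 0)
  ))
  invisible(x)
}

#' Neighbors of a protein in the PPI graph
#'
#' @param bundle a `caerus_bundle`.
#' @param protein protein identifier.
#' @return Character vector of neighboring protein ids (possibly empty).
#' @export
neighbors <- function(bundle, protein) {
  assert_protein(bundle, protein)
  bundle$adjacency[[protein]] %||% character(0)
}

#' Annotated domains of a protein
#'
#' @inheritParams neighbors
#' @return Character vector of domain ids; empty if the protein has no
#'   annotation (not an error: domain coverage of real proteomes is
#'   incomplete).
#' @export
protein_domains <- function(bundle, protein) {
  assert_protein(bundle, protein)
  bundle$annotation[[protein]] %||% character(0)
}

#' Somatic mutation count of a domain
#'
#' @param bundle a `caerus_bundle`.
#' @param domain domain identifier(s).
#' @return Numeric vector of counts, 0 for domains with no record.
#' @export
mutation_count <- function(bundle, domain) {
  out <- bundle$mutation_counts[domain]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), domain)
}

# canonical order-independent key for a domain pair
ddi_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

has_ddi <- function(bundle, a, b) {
  ddi_key(a, b) %in% bundle$ddi_keys
}

assert_protein <- function(bundle, protein) {
  if (length(protein) != 1L || !is.character(protein)) {
    stop("protein must be a single character id")
  }
  if (!protein %in% bundle$proteins) {
    stop(sprintf("unknown protein: '%s'", protein))
  }
  invisible(TRUE)
}

as_two_col <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0)) {
    return(matrix(character(0), ncol = 2))
  }
  if (!is.matrix(x) || ncol(x) != 2) {
    stop(sprintf("%s must be a two-column matrix or data.frame", what))
  }
  storage.mode(x) <- "character"
  dimnames(x) <- NULL
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
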