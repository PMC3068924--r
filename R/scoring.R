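#' Scoring configuration
#'
#' Parameters of the domain index score. `weight_base` is the base of the
#' exponential weight applied to a domain's DDI engagement count (2 by
#' default, so a domain engaged in k neighbor-domain interactions
#' contributes `2^k`). `threshold_c` is the signature-selection cutoff.
#' `mutation_mode` controls how per-domain somatic mutation counts enter the
#' mutation-weighted score: `"multiplicative"` multiplies each domain term by
#' `1 + NumSMs(d)`, `"additive"` adds `NumSMs(d)` to the plain score, and
#' `"off"` ignores mutations. Domains with zero realized DDIs contribute
#' nothing in every mode.
#'
#' @param weight_base exponential base, must be > 1.
#' @param threshold_c non-negative selection threshold.
#' @param mutation_mode one of "multiplicative", "additive", "off".
#' @param strict if `TRUE` (default) a protein is selected when its score is
#'   strictly greater than `threshold_c`; if `FALSE`, `>=` is used.
#' @param count_distinct if `TRUE`, a domain's DDI count is the number of
#'   distinct (neighbor-domain-type) partners rather than the default
#'   per-neighbor-per-domain instance count.
#' @return A list of class `caerus_score_config`.
#' @export
score_config <- function(weight_base = 2, threshold_c = 50,
                         mutation_mode = c("multiplicative", "additive", "off"),
                         strict = TRUE, count_distinct = FALSE) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(is.numeric(weight_base), length(weight_base) == 1, weight_base > 1)
  stopifnot(is.numeric(threshold_c), length(threshold_c) == 1, threshold_c >= 0)
  structure(
    list(
      weight_base = weight_base, threshold_c = threshold_c,
      mutation_mode = mutation_mode, strict = isTRUE(strict),
      count_distinct = isTRUE(count_distinct)
    ),
    class = "caerus_score_config"
  )
}

#' Per-domain DDI engagement counts of a protein
#'
#' For each annotated domain d of the protein, counts the neighbor-domain
#' instances that realize a cataloged DDI with d: the sum over PPI neighbors
#' p, and over domains d' of p, of the indicator that (d, d') is in the DDI
#' catalog. Counting is per instance, so the same DDI type realized with 5
#' neighbors contributes 5 (this is what makes singlish-interface hubs score
#' high). With `count_distinct = TRUE` in the config, distinct (d, d') types
#' are counted once instead.
#'
#' @param protein protein id (must exist in the bundle).
#' @param bundle a `caerus_bundle`.
#' @param count_distinct count distinct DDI types instead of instances.
#' @return Named numeric vector, one entry per domain of the protein
#'   (0 when nothing is realized); zero-length for unannotated proteins.
#' @export
count_domain_ddis <- function(protein, bundle, count_distinct = FALSE) {
  assert_protein(bundle, protein)
  doms <- protein_domains(bundle, protein)
  if (!length(doms)) return(stats::setNames(numeric(0), character(0)))
  nb <- neighbors(bundle, protein)
  counts <- stats::setNames(numeric(length(doms)), doms)
  if (!length(nb)) return(counts)
  nb_dom <- unlist(lapply(nb, function(p) bundle$annotation[[p]] %||% character(0)),
                   use.names = FALSE)
  if (!length(nb_dom)) return(counts)
  for (d in doms) {
    hit <- has_ddi(bundle, d, nb_dom)
    counts[[d]] <- if (count_distinct) length(unique(nb_dom[hit])) else sum(hit)
  }
  counts
}

#' Domain index score of a protein
#'
#' Computes the plain and the mutation-weighted domain index score. The
#' plain score sums, over the protein's domains with at least one realized
#' DDI, `weight_base ^ NumDDIs(d)`; domains with zero engagement contribute
#' nothing. In multiplicative mutation mode each term is additionally
#' multiplied by `1 + NumSMs(d)`; in additive mode the raw mutation counts
#' of engaged domains are added to the plain score; with mode "off" both
#' scores coincide. For non-negative mutation counts the mutation-weighted
#' score is therefore never below the plain one.
#'
#' @inheritParams count_domain_ddis
#' @param cfg a [score_config()].
#' @return A list of class `caerus_domain_report`: `protein`, `ddi_counts`,
#'   `score_plain`, `score_mutation`, `interface_class`.
#' @export
domain_index_score <- function(protein, bundle, cfg = score_config()) {
  stopifnot(inherits(cfg, "caerus_score_config"))
  counts <- count_domain_ddis(protein, bundle, cfg$count_distinct)
  engaged <- counts[counts >= 1]
  w <- cfg$weight_base ^ engaged
  score_plain <- sum(w)
  sms <- mutation_count(bundle, names(engaged))
  score_mutation <- switch(cfg$mutation_mode,
    multiplicative = sum(w * (1 + sms)),
    additive = score_plain + sum(sms),
    off = score_plain
  )
  structure(
    list(
      protein = protein,
      ddi_counts = counts,
      score_plain = score_plain,
      score_mutation = score_mutation,
      interface_class = classify_interface(protein, bundle)
    ),
    class = "caerus_domain_report"
  )
}

#' Score every protein of a bundle
#'
#' @param bundle a `caerus_bundle`.
#' @param cfg a [score_config()].
#' @return Named list of `caerus_domain_report` objects, one per protein.
#' @export
score_all <- function(bundle, cfg = score_config()) {
  stats::setNames(
    lapply(bundle$proteins, domain_index_score, bundle = bundle, cfg = cfg),
    bundle$proteins
  )
}

#' Select gene signatures by score threshold
#'
#' A protein becomes a gene signature when its chosen domain index score
#' exceeds the preset threshold c. The comparison is strict by default
#' (`score > c`); set `strict = FALSE` in the config for `>=`.
#'
#' @param reports list of `caerus_domain_report` (e.g. from [score_all()]).
#' @param cfg a [score_config()] supplying `threshold_c` and `strict`.
#' @param use_mutations select on the mutation-weighted score instead of the
#'   plain score.
#' @return Sorted character vector of signature protein ids.
#' @export
select_signatures <- function(reports, cfg = score_config(),
                              use_mutations = FALSE) {
  scores <- vapply(
    reports,
    function(r) if (use_mutations) r$score_mutation else r$score_plain,
    numeric(1)
  )
  keep <- if (cfg$strict) scores > cfg$threshold_c else scores >= cfg$threshold_c
  sort(vapply(reports[keep], `[[`, character(1), "protein"))
}

#' Interface class of a protein
#'
#' Collects the set of DDI types (d, d') realized between the protein's
#' domains and its neighbors' domains. A protein is `"singlish"` when
#' exactly one DDI type is realized and that type is realized with at least
#' two distinct neighbors -- its interactions go through a single interface
#' and are mutually exclusive. It is `"multiple"` when two or more distinct
#' DDI types are realized (simultaneous interactions possible), and
#' `"none"` otherwise.
#'
#' @inheritParams count_domain_ddis
#' @return One of "singlish", "multiple", "none".
#' @export
classify_interface <- function(protein, bundle) {
  assert_protein(bundle, protein)
  doms <- protein_domains(bundle, protein)
  nb <- neighbors(bundle, protein)
  if (!length(doms) || !length(nb)) return("none")
  types <- character(0)
  nb_with_type <- character(0)
  for (p in nb) {
    pd <- bundle$annotation[[p]] %||% character(0)
    if (!length(pd)) next
    pairs <- expand.grid(d = doms, dp = pd, stringsAsFactors = FALSE)
    hit <- has_ddi(bundle, pairs$d, pairs$dp)
    if (any(hit)) {
      types <- c(types, ddi_key(pairs$d[hit], pairs$dp[hit]))
      nb_with_type <- c(nb_with_type, p)
    }
  }
  types <- unique(types)
  if (length(types) == 0) return("none")
  if (length(types) >= 2) return("multiple")
  if (length(unique(nb_with_type)) >= 2) "singlish" else "none"
}

#' Domain over-representation among signature proteins
#'
#' For every domain annotated on a signature protein, compares the domain's
#' share of realized DDI instances within the signature set against its
#' genome-wide share with a one-proportion Z-test (normal approximation,
#' two-sided). Instances are counted exactly as in [count_domain_ddis()],
#' summed over the proteins of each set.
#'
#' @param signatures character vector of signature protein ids (subset of
#'   the bundle's proteins).
#' @param bundle a `caerus_bundle`.
#' @return A data.frame with columns `domain`, `count_in_signatures`,
#'   `count_genome`, `z_score`, `p_value`, sorted by ascending p-value with
#'   ties broken by domain id; zero rows for an empty signature set.
#' @export
domain_overrepresentation <- function(signatures, bundle) {
  if (!all(signatures %in% bundle$proteins)) {
    stop("signatures must be a subset of the bundle's proteins")
  }
  if (!length(signatures)) {
    return(data.frame(
      domain = character(0), count_in_signatures = numeric(0),
      count_genome = numeric(0), z_score = numeric(0), p_value = numeric(0)
    ))
  }
  tally <- function(prots) {
    acc <- new.env(parent = emptyenv())
    for (p in prots) {
      cnt <- count_domain_ddis(p, bundle)
      for (d in names(cnt)) {
        assign(d, (get0(d, envir = acc) %||% 0) + cnt[[d]], envir = acc)
      }
    }
    vals <- mget(ls(acc), envir = acc)
    stats::setNames(as.numeric(unlist(vals)), names(vals))
  }
  genome <- tally(bundle$proteins)
  sig <- tally(signatures)
  total_genome <- sum(genome)
  if (total_genome == 0) stop("no realized DDI instances in the bundle")
  total_sig <- sum(sig)

  doms <- sort(unique(unlist(bundle$annotation[signatures], use.names = FALSE)))
  rows <- lapply(doms, function(d) {
    k_sig <- sig[d]; if (is.na(k_sig)) k_sig <- 0
    k_gen <- genome[d]; if (is.na(k_gen)) k_gen <- 0
    p0 <- k_gen / total_genome
    phat <- if (total_sig > 0) k_sig / total_sig else 0
    if (total_sig == 0 || phat == p0) {
      z <- 0; p <- 1
    } else if (p0 <= 0 || p0 >= 1) {
      z <- sign(phat - p0) * Inf; p <- 0
    } else {
      z <- (phat - p0) / sqrt(p0 * (1 - p0) / total_sig)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(
      domain = d, count_in_signatures = as.numeric(k_sig),
      count_genome = as.numeric(k_gen), z_score = z, p_value = p
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabular per-protein scoring report
#'
#' One row per (protein, domain) pair plus a row for unannotated proteins,
#' suitable for writing with [write_report()].
#'
#' @param bundle a `caerus_bundle`.
#' @param cfg a [score_config()].
#' @param use_mutations which score drives the `is_signature` column.
#' @return data.frame with columns protein, domain, num_ddis, score_plain,
#'   score_mutation, interface_class, is_signature.
#' @export
score_report <- function(bundle, cfg = score_config(), use_mutations = FALSE) {
  reports <- score_all(bundle, cfg)
  sigs <- select_signatures(reports, cfg, use_mutations)
  rows <- lapply(reports, function(r) {
    doms <- names(r$ddi_counts)
    if (!length(doms)) { doms <- NA_character_; cnt <- NA_real_ }
    else cnt <- as.numeric(r$ddi_counts)
    data.frame(
      protein = r$protein, domain = doms, num_ddis = cnt,
      score_plain = r$score_plain, score_mutation = r$score_mutation,
      interface_class = r$interface_class,
      is_signature = r$protein %in% sigs
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
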