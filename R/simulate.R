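#' Simulation configuration
#'
#' Parameters of the seeded interactome/cohort simulator. The generator
#' plants `n_singlish_hubs` star-shaped hub proteins, each interacting with
#' `hub_degree` partner proteins through one dedicated DDI type, on top of
#' an Erdos-Renyi background with random domain annotation. Defaults give
#' 5 hubs of degree 8 among 200 proteins, so each planted hub's single
#' engaged domain realizes 8 DDI instances and scores 2^8 = 256 -- well
#' above the canonical selection threshold of 50 -- while background
#' proteins stay low-scoring with high probability.
#'
#' Cohort defaults (60 good, 40 poor patients, coupling attenuation
#' `effect_delta = 1`, `noise_sigma = 0.2`) plant a strong class-dependent
#' co-expression difference between each hub and its partners;
#' `effect_delta = 0` defines the null cohort with exchangeable classes.
#'
#' @param n_proteins,n_domains pool sizes.
#' @param domains_per_protein mean of the per-protein annotation count
#'   (Poisson, truncated at >= 1).
#' @param n_singlish_hubs number of planted hubs.
#' @param hub_degree partners per hub (>= 2).
#' @param background_edge_prob Erdos-Renyi edge probability.
#' @param ddi_density probability a random background domain pair enters
#'   the DDI catalog.
#' @param mutation_rate Poisson mean of somatic mutation counts on hub
#'   domains.
#' @param n_patients_good,n_patients_poor cohort class sizes.
#' @param effect_delta attenuation of hub-partner coupling in poor
#'   patients, in [0, 1]-ish (0 = null).
#' @param noise_sigma Gaussian noise SD around the coupled signal.
#' @param seed integer seed; all generation is deterministic given it.
#' @return A list of class `caerus_sim_config`.
#' @export
sim_config <- function(n_proteins = 200L, n_domains = 60L,
                       domains_per_protein = 2, n_singlish_hubs = 5L,
                       hub_degree = 8L, background_edge_prob = 0.01,
                       ddi_density = 0.005, mutation_rate = 2,
                       n_patients_good = 60L, n_patients_poor = 40L,
                       effect_delta = 1, noise_sigma = 0.2, seed = 1L) {
  stopifnot(
    n_proteins >= 1, n_domains >= 1, hub_degree >= 2,
    n_singlish_hubs >= 0, domains_per_protein >= 0,
    background_edge_prob >= 0, background_edge_prob <= 1,
    ddi_density >= 0, ddi_density <= 1, mutation_rate >= 0,
    effect_delta >= 0, noise_sigma > 0
  )
  structure(as.list(environment()), class = "caerus_sim_config")
}

#' Simulate an interactome bundle with planted singlish-interface hubs
#'
#' Each planted hub gets a dedicated hub domain and a dedicated partner
#' domain: the hub is annotated with the hub domain only, its `hub_degree`
#' partner proteins carry the partner domain, and the (hub, partner) pair
#' is entered into the DDI catalog. All of a hub's realized DDIs therefore
#' go through one interface (interface class "singlish") and the hub
#' domain's DDI count equals at least `hub_degree`. Background proteins
#' are annotated from a disjoint domain pool, wired by Erdos-Renyi edges
#' and a sparse random background DDI catalog. Hub domains receive
#' Poisson(`mutation_rate`) somatic mutation counts; background domains 0.
#'
#' @param cfg a [sim_config()].
#' @return A list with `bundle` (a `caerus_bundle`) and `truth` (list with
#'   `planted_signatures`, `hub_partners`, `hub_domains`).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "caerus_sim_config"))
  n_hub <- cfg$n_singlish_hubs
  if (n_hub > 0 && cfg$hub_degree >= cfg$n_proteins) {
    stop("hub_degree must be smaller than n_proteins")
  }
  if (n_hub * (1 + cfg$hub_degree) > cfg$n_proteins) {
    stop("not enough proteins for the requested hubs")
  }
  if (2 * n_hub > cfg$n_domains) {
    stop("not enough domains for the requested hubs")
  }
  with_seed(cfg$seed, {
    proteins <- sprintf("P%03d", seq_len(cfg$n_proteins))
    domains <- sprintf("D%03d", seq_len(cfg$n_domains))
    hub_ids <- proteins[seq_len(n_hub)]
    hub_dom <- domains[seq_len(n_hub)]
    partner_dom <- domains[n_hub + seq_len(n_hub)]
    bg_dom <- domains[-seq_len(2 * n_hub)]

    partner_pool <- proteins[-seq_len(n_hub)]
    ann <- list()
    edges <- list()
    ddi <- list()
    hub_partners <- list()
    for (i in seq_len(n_hub)) {
      partners <- partner_pool[(i - 1) * cfg$hub_degree + seq_len(cfg$hub_degree)]
      hub_partners[[hub_ids[i]]] <- partners
      edges[[i]] <- cbind(hub_ids[i], partners)
      ddi[[i]] <- c(hub_dom[i], partner_dom[i])
      ann[[length(ann) + 1L]] <- cbind(hub_ids[i], hub_dom[i])
      ann[[length(ann) + 1L]] <- cbind(partners, partner_dom[i])
    }

    # background domain annotation over non-hub proteins
    bg_prots <- setdiff(proteins, hub_ids)
    if (length(bg_dom) && cfg$domains_per_protein > 0) {
      for (p in bg_prots) {
        k <- max(1L, stats::rpois(1, cfg$domains_per_protein))
        ann[[length(ann) + 1L]] <-
          cbind(p, sample(bg_dom, min(k, length(bg_dom))))
      }
    }

    # Erdos-Renyi background edges over all proteins
    if (cfg$background_edge_prob > 0 && cfg$n_proteins >= 2) {
      pairs <- utils::combn(proteins, 2)
      keep <- stats::runif(ncol(pairs)) < cfg$background_edge_prob
      if (any(keep)) edges[[length(edges) + 1L]] <- t(pairs[, keep, drop = FALSE])
    }

    # sparse background DDI catalog (background domains only, so planted
    # hubs stay the only guaranteed high scorers)
    if (length(bg_dom) >= 2 && cfg$ddi_density > 0) {
      dpairs <- utils::combn(bg_dom, 2)
      keep <- stats::runif(ncol(dpairs)) < cfg$ddi_density
      for (j in which(keep)) ddi[[length(ddi) + 1L]] <- dpairs[, j]
    }

    mut <- stats::setNames(stats::rpois(n_hub, cfg$mutation_rate), hub_dom)
    bundle <- interactome_bundle(
      edges = do.call(rbind, edges),
      annotation = do.call(rbind, ann),
      ddi = do.call(rbind, lapply(ddi, function(x) matrix(x, ncol = 2))),
      mutation_counts = mut
    )
    list(
      bundle = bundle,
      truth = list(
        planted_signatures = hub_ids,
        hub_partners = hub_partners,
        hub_domains = stats::setNames(hub_dom, hub_ids),
        partner_domains = stats::setNames(partner_dom, hub_ids)
      )
    )
  })
}

#' Simulate a patient cohort with class-dependent hub co-expression
#'
#' Every gene is a protein of the simulated bundle. Per patient, each
#' planted hub's expression is a standard-normal signal; the expression of
#' its partners is `signal + N(0, noise_sigma)` in good-outcome patients
#' and `(1 - effect_delta) * signal + N(0, noise_sigma)` in poor-outcome
#' patients, so `effect_delta` attenuates the hub-partner coupling in the
#' poor class (at 0 the classes are exchangeable). All other genes are
#' independent standard-normal noise.
#'
#' The cohort seed is derived from `cfg$seed` so that bundle and cohort
#' generation are independently reproducible.
#'
#' @param sim result of [simulate_bundle()] (bundle plus ground truth).
#' @param cfg the same [sim_config()].
#' @return A `caerus_cohort`.
#' @export
simulate_cohort <- function(sim, cfg = sim_config()) {
  stopifnot(inherits(cfg, "caerus_sim_config"))
  n_good <- cfg$n_patients_good
  n_poor <- cfg$n_patients_poor
  if (n_good < 1 || n_poor < 1) stop("each class needs at least one patient")
  bundle <- sim$bundle
  truth <- sim$truth
  with_seed(cfg$seed + 104729L, {  # offset keeps bundle/cohort streams apart
    patients <- c(sprintf("G%03d", seq_len(n_good)),
                  sprintf("B%03d", seq_len(n_poor)))
    labels <- stats::setNames(rep(c("good", "poor"), c(n_good, n_poor)),
                              patients)
    genes <- bundle$proteins
    n_pat <- length(patients)
    values <- matrix(stats::rnorm(length(genes) * n_pat),
                     nrow = length(genes),
                     dimnames = list(genes, patients))
    for (hub in truth$planted_signatures) {
      signal <- values[hub, ]
      coupling <- ifelse(labels == "good", 1, 1 - cfg$effect_delta)
      for (p in truth$hub_partners[[hub]]) {
        values[p, ] <- coupling * signal +
          stats::rnorm(n_pat, sd = cfg$noise_sigma)
      }
    }
    patient_cohort(values, labels)
  })
}
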