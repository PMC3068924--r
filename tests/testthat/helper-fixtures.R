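# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as naive loops over raw sets so they share no code
# path with the package implementation.

# small hand-built bundle: A-{d1} with neighbors B-{d2,d3}, C-{d2};
# catalog (d1,d2), (d1,d3)
toy_bundle <- function(mutations = NULL) {
  interactome_bundle(
    edges = cbind(c("A", "A"), c("B", "C")),
    annotation = cbind(c("A", "B", "B", "C"), c("d1", "d2", "d3", "d2")),
    ddi = cbind(c("d1", "d1"), c("d2", "d3")),
    mutation_counts = mutations
  )
}

# star bundle: one hub H-{dh} with n leaves L1..Ln each carrying dp,
# single catalog pair (dh, dp)
star_bundle <- function(n) {
  leaves <- paste0("L", seq_len(n))
  interactome_bundle(
    edges = cbind("H", leaves),
    annotation = rbind(cbind("H", "dh"), cbind(leaves, "dp")),
    ddi = cbind("dh", "dp")
  )
}

# random bundle over <= n_prot proteins / <= n_dom domains for oracle sweeps
random_bundle <- function(n_prot, n_dom, edge_p = 0.4, ann_p = 0.5,
                          ddi_p = 0.3, mut_max = 3) {
  prots <- paste0("p", seq_len(n_prot))
  doms <- paste0("d", seq_len(n_dom))
  pairs <- t(combn(prots, 2))
  edges <- pairs[runif(nrow(pairs)) < edge_p, , drop = FALSE]
  ann <- do.call(rbind, lapply(prots, function(p) {
    d <- doms[runif(n_dom) < ann_p]
    if (length(d)) cbind(p, d)
  }))
  dpairs <- t(combn(doms, 2))
  ddi <- dpairs[runif(nrow(dpairs)) < ddi_p, , drop = FALSE]
  mut <- setNames(sample(0:mut_max, n_dom, replace = TRUE), doms)
  # ensure at least one edge so the bundle is non-trivial
  if (!nrow(edges)) edges <- pairs[1, , drop = FALSE]
  interactome_bundle(edges, ann, ddi, mut)
}

# oracle: triple loop over (domain of x, neighbor, domain of neighbor)
brute_count_ddis <- function(protein, bundle) {
  doms <- bundle$annotation[[protein]]
  if (is.null(doms)) doms <- character(0)
  out <- setNames(numeric(length(doms)), doms)
  edge_list <- bundle$edges
  nbrs <- character(0)
  for (i in seq_len(nrow(edge_list))) {
    if (edge_list[i, 1] == protein) nbrs <- c(nbrs, edge_list[i, 2])
    if (edge_list[i, 2] == protein) nbrs <- c(nbrs, edge_list[i, 1])
  }
  catalog <- bundle$ddi_keys
  for (d in doms) {
    for (p in unique(nbrs)) {
      pd <- bundle$annotation[[p]]
      if (is.null(pd)) next
      for (dp in pd) {
        key <- paste(min(d, dp), max(d, dp), sep = "|")
        if (key %in% catalog) out[[d]] <- out[[d]] + 1
      }
    }
  }
  out
}

# oracle: score from brute-force counts, multiplicative mutation weighting
brute_scores <- function(protein, bundle, base = 2) {
  cnt <- brute_count_ddis(protein, bundle)
  plain <- 0; mutated <- 0
  for (d in names(cnt)) {
    if (cnt[[d]] >= 1) {
      w <- base ^ cnt[[d]]
      sm <- unname(bundle$mutation_counts[d])
      if (length(sm) == 0 || is.na(sm)) sm <- 0
      plain <- plain + w
      mutated <- mutated + w * (1 + sm)
    }
  }
  c(plain = plain, mutated = mutated)
}

# oracle: direct P(x|C)P(C) evaluation of the binned naive Bayes rule;
# `x` is the patient's feature vector in the column order of train_feat
brute_nb_posteriors <- function(train_feat, train_lab, x, alpha, n_bins = 20) {
  classes <- c("good", "poor")
  bin_of <- function(v) min(floor(v * n_bins), n_bins - 1)
  x <- as.numeric(x)
  unnorm <- sapply(classes, function(cl) {
    idx <- which(train_lab == cl)
    prior <- length(idx) / length(train_lab)
    lik <- 1
    for (j in seq_len(ncol(train_feat))) {
      b <- bin_of(x[j])
      n_in_bin <- sum(sapply(idx, function(i) bin_of(train_feat[i, j]) == b))
      lik <- lik * (n_in_bin + alpha) / (length(idx) + n_bins * alpha)
    }
    prior * lik
  })
  if (sum(unnorm) == 0) return(c(good = 0.5, poor = 0.5))
  unnorm / sum(unnorm)
}

# seeded cohort for expression tests: g genes x n patients of N(0,1) noise
random_cohort <- function(genes, n_good, n_poor) {
  patients <- c(paste0("g", seq_len(n_good)), paste0("b", seq_len(n_poor)))
  labels <- setNames(rep(c("good", "poor"), c(n_good, n_poor)), patients)
  values <- matrix(rnorm(length(genes) * length(patients)),
                   nrow = length(genes),
                   dimnames = list(genes, patients))
  patient_cohort(values, labels)
}
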