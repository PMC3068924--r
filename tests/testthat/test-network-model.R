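test_that("bundle construction canonicalizes edges and drops self-loops", {
  b <- interactome_bundle(
    edges = cbind(c("A", "B", "A", "C"), c("B", "A", "A", "A")),
    annotation = cbind("Z", "d9")
  )
  expect_equal(nrow(b$edges), 2)  # A-B deduped, A-A dropped, A-C kept
  expect_true(all(b$edges[, 1] < b$edges[, 2]))
  expect_setequal(neighbors(b, "A"), c("B", "C"))
  # annotation-only protein retained as isolated node
  expect_true("Z" %in% b$proteins)
  expect_equal(neighbors(b, "Z"), character(0))
  expect_equal(protein_domains(b, "Z"), "d9")
  expect_error(neighbors(b, "nope"), "unknown protein")
})

test_that("count_domain_ddis counts per neighbor-domain instance", {
  b <- toy_bundle()
  # A sees d2 (from B), d3 (from B), d2 (from C): three instances for d1
  expect_equal(count_domain_ddis("A", b), c(d1 = 3))
  # a domain with no catalog match maps to 0
  b2 <- interactome_bundle(
    edges = cbind(c("A", "A"), c("B", "C")),
    annotation = cbind(c("A", "A", "B", "B", "C"), c("d1", "d4", "d2", "d3", "d2")),
    ddi = cbind(c("d1", "d1"), c("d2", "d3"))
  )
  expect_equal(count_domain_ddis("A", b2), c(d1 = 3, d4 = 0))
  # neighbor-less protein: all domains 0
  iso <- interactome_bundle(edges = cbind("X", "Y"),
                            annotation = cbind("Z", "d1"),
                            ddi = cbind("d1", "d2"))
  expect_equal(count_domain_ddis("Z", iso), c(d1 = 0))
  # unannotated protein: empty map, not an error
  expect_length(count_domain_ddis("X", iso), 0)
  # distinct-type mode collapses repeated instances of the same DDI type
  expect_equal(count_domain_ddis("A", b, count_distinct = TRUE), c(d1 = 2))
})

test_that("domain index score applies exponential weights and mutation modes", {
  b <- star_bundle(3)  # NumDDIs(dh) = 3
  r <- domain_index_score("H", b)
  expect_equal(r$score_plain, 8)
  expect_equal(r$score_mutation, 8)  # no mutations recorded

  b2 <- interactome_bundle(
    edges = cbind("H", c("L1", "L2", "L3")),
    annotation = rbind(cbind("H", "dh"), cbind(c("L1", "L2", "L3"), "dp")),
    ddi = cbind("dh", "dp"),
    mutation_counts = c(dh = 2)
  )
  expect_equal(domain_index_score("H", b2)$score_mutation, 8 * 3)
  expect_equal(
    domain_index_score("H", b2, score_config(mutation_mode = "additive"))$score_mutation,
    8 + 2
  )
  expect_equal(
    domain_index_score("H", b2, score_config(mutation_mode = "off"))$score_mutation,
    8
  )
  # zero-DDI domains contribute nothing (not 2^0)
  b3 <- interactome_bundle(
    edges = cbind("H", c("L1", "L2", "L3", "L4")),
    annotation = rbind(cbind("H", c("dh", "dx")),
                       cbind(c("L1", "L2", "L3", "L4"), "dp")),
    ddi = cbind("dh", "dp")
  )
  expect_equal(domain_index_score("H", b3)$score_plain, 16)
  # unannotated protein scores 0
  expect_equal(domain_index_score("L1", star_bundle(2))$score_plain, 2)
  empty <- interactome_bundle(edges = cbind("X", "Y"))
  expect_equal(domain_index_score("X", empty)$score_plain, 0)
})

test_that("scoring matches the brute-force oracle on random bundles", {
  set.seed(42)
  for (rep in 1:60) {
    b <- random_bundle(sample(3:10, 1), sample(2:6, 1))
    cfg <- score_config()
    for (p in b$proteins) {
      expect_equal(count_domain_ddis(p, b), brute_count_ddis(p, b))
      r <- domain_index_score(p, b, cfg)
      o <- brute_scores(p, b)
      expect_equal(r$score_plain, unname(o["plain"]))
      expect_equal(r$score_mutation, unname(o["mutated"]))
      expect_gte(r$score_mutation, r$score_plain)
    }
  }
})

test_that("adding a DDI-realizing neighbor never decreases the plain score", {
  set.seed(11)
  for (rep in 1:20) {
    b <- random_bundle(6, 4)
    p <- sample(b$proteins, 1)
    before <- domain_index_score(p, b)$score_plain
    # graft a new neighbor carrying a domain guaranteed to pair with one of p's
    doms <- protein_domains(b, p)
    if (!length(doms)) next
    newdom <- "dnew"
    b2 <- interactome_bundle(
      edges = rbind(b$edges, c(p, "pnew")),
      annotation = rbind(
        do.call(rbind, lapply(names(b$annotation),
                              function(q) cbind(q, b$annotation[[q]]))),
        cbind("pnew", newdom)
      ),
      ddi = rbind(do.call(rbind, strsplit(b$ddi_keys, "|", fixed = TRUE)),
                  c(doms[1], newdom)),
      mutation_counts = b$mutation_counts
    )
    expect_gte(domain_index_score(p, b2)$score_plain, before)
  }
})

test_that("signature selection is strict and monotone in the threshold", {
  reports <- list(
    list(protein = "A", score_plain = 64, score_mutation = 64),
    list(protein = "B", score_plain = 50, score_mutation = 50),
    list(protein = "C", score_plain = 8, score_mutation = 8)
  )
  expect_equal(select_signatures(reports, score_config(threshold_c = 50)), "A")
  expect_equal(select_signatures(reports, score_config(threshold_c = 7.9)),
               c("A", "B", "C"))
  expect_equal(
    select_signatures(reports, score_config(threshold_c = 50, strict = FALSE)),
    c("A", "B")
  )
  # nothing exceeds 0 strictly when all scores are 0
  zero <- list(list(protein = "Z", score_plain = 0, score_mutation = 0))
  expect_length(select_signatures(zero, score_config(threshold_c = 0)), 0)
  # monotone: raising c never adds a protein
  cs <- sort(runif(10, 0, 100))
  sets <- lapply(cs, function(ci)
    select_signatures(reports, score_config(threshold_c = ci)))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("interface classification distinguishes singlish, multiple, none", {
  for (n in 2:20) {
    expect_equal(classify_interface("H", star_bundle(n)), "singlish")
  }
  multi <- interactome_bundle(
    edges = cbind("A", c("B", "C")),
    annotation = rbind(cbind("A", c("d1", "d4")), c("B", "d2"), c("C", "d5")),
    ddi = rbind(c("d1", "d2"), c("d4", "d5"))
  )
  expect_equal(classify_interface("A", multi), "multiple")
  # single DDI type realized with a single neighbor is not singlish
  expect_equal(classify_interface("H", star_bundle(2)), "singlish")
  one <- interactome_bundle(
    edges = cbind("A", "B"),
    annotation = rbind(c("A", "d1"), c("B", "d2")),
    ddi = cbind("d1", "d2")
  )
  expect_equal(classify_interface("A", one), "none")
  iso <- interactome_bundle(edges = cbind("X", "Y"),
                            annotation = cbind("Z", "d1"))
  expect_equal(classify_interface("Z", iso), "none")
})

test_that("domain over-representation z-test behaves at its fixed points", {
  b <- star_bundle(6)
  # signatures = all proteins: every domain sits exactly at its null share
  res_all <- domain_overrepresentation(b$proteins, b)
  expect_true(all(res_all$z_score == 0))
  expect_true(all(res_all$p_value == 1))
  # hub-only signature set concentrates dh instances
  res <- domain_overrepresentation("H", b)
  row <- res[res$domain == "dh", ]
  expect_equal(row$count_in_signatures, 6)
  expect_equal(row$count_genome, 6)
  expect_gt(row$z_score, 0)
  expect_lt(row$p_value, 0.05)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$count_in_signatures <= res$count_genome))
  # empty signature set and degenerate bundle
  expect_equal(nrow(domain_overrepresentation(character(0), b)), 0)
  noddi <- interactome_bundle(edges = cbind("X", "Y"),
                              annotation = cbind("X", "d1"))
  expect_error(domain_overrepresentation("X", noddi), "no realized DDI")
})
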