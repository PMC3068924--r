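test_that("confusion metrics follow the printed formulas, poor as positive", {
  mk <- function(pred, truth) {
    ids <- paste0("p", seq_along(pred))
    list(pred = data.frame(patient = ids, predicted = pred),
         lab = setNames(truth, ids))
  }
  x <- mk(c("poor", "poor", "good", "good", "good", "poor"),
          c("poor", "poor", "good", "good", "good", "good"))
  m <- confusion(x$pred, x$lab)
  expect_equal(m$tp, 2); expect_equal(m$tn, 3)
  expect_equal(m$fp, 1); expect_equal(m$fn, 0)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.75)
  # perfect classifier
  y <- mk(c("poor", "good"), c("poor", "good"))
  my <- confusion(y$pred, y$lab)
  expect_equal(c(my$accuracy, my$sensitivity, my$specificity), c(1, 1, 1))
  # empty positive class: sensitivity undefined, not 0
  z <- mk(c("good", "good"), c("good", "good"))
  expect_true(is.na(confusion(z$pred, z$lab)$sensitivity))
  expect_error(confusion(data.frame(patient = character(0),
                                    predicted = character(0)), c()),
               "no predictions")
})

test_that("confusion matches hand-computed values on all small matrices", {
  for (tp in 0:2) for (fp in 0:2) for (tn in 0:2) for (fn in 0:2) {
    n <- tp + fp + tn + fn
    if (n == 0) next
    truth <- rep(c("poor", "good", "good", "poor"), c(tp, fp, tn, fn))
    pred <- rep(c("poor", "poor", "good", "good"), c(tp, fp, tn, fn))
    ids <- paste0("p", seq_len(n))
    m <- confusion(data.frame(patient = ids, predicted = pred),
                   setNames(truth, ids))
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    expect_equal(m$accuracy, (tp + tn) / n)
    expect_equal(m$sensitivity,
                 if (tp + fn == 0) NA_real_ else tp / (tp + fn))
    expect_equal(m$specificity,
                 if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  }
})

test_that("ROC sweep and trapezoidal AUC behave on known configurations", {
  # perfectly separated posteriors
  s <- setNames(c(0.9, 0.8, 0.2, 0.1), paste0("p", 1:4))
  lab <- setNames(c("poor", "poor", "good", "good"), names(s))
  r <- roc_auc(s, lab)
  expect_equal(r$auc, 1.0)
  # hand-ranked sweep
  s2 <- setNames(c(0.9, 0.8, 0.3), paste0("q", 1:3))
  lab2 <- setNames(c("poor", "good", "good"), names(s2))
  expect_equal(roc_auc(s2, lab2)$auc, 1.0)
  # reversed scores give AUC 0
  expect_equal(roc_auc(1 - s, lab)$auc, 0)
  expect_error(roc_auc(s, setNames(rep("good", 4), names(s))), "both classes")
  # random labels: AUC near 0.5 within 3 SE
  set.seed(21)
  n <- 400
  sc <- setNames(runif(n), paste0("r", 1:n))
  lr <- setNames(sample(c("good", "poor"), n, replace = TRUE), names(sc))
  n1 <- sum(lr == "poor"); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(sc, lr)$auc - 0.5), 3 * se)
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(plogis(5 * sc), lr)$auc, roc_auc(sc, lr)$auc)
})

test_that("roc_auc agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    sc <- setNames(round(runif(n), 2), paste0("p", 1:n))  # rounded: ties occur
    lab <- setNames(sample(c("good", "poor"), n, replace = TRUE), names(sc))
    if (length(unique(lab)) < 2) next
    ours <- roc_auc(sc, lab)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                     levels = c("good", "poor"),
                                     direction = "<")))
    )
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("loocv pooled confusion matches manual fold enumeration", {
  sim <- simulate_bundle(sim_config(n_proteins = 30, n_domains = 12,
                                    n_singlish_hubs = 1, hub_degree = 4,
                                    background_edge_prob = 0.02,
                                    n_patients_good = 4, n_patients_poor = 4,
                                    noise_sigma = 0.3, seed = 5))
  coh <- simulate_cohort(sim, sim_config(n_proteins = 30, n_domains = 12,
                                         n_singlish_hubs = 1, hub_degree = 4,
                                         background_edge_prob = 0.02,
                                         n_patients_good = 4,
                                         n_patients_poor = 4,
                                         noise_sigma = 0.3, seed = 5))
  c_grid <- 10  # single threshold: inner tuning is forced, folds are manual
  res <- loocv(sim$bundle, coh, c_grid = c_grid, seed = 1)
  sigs <- select_signatures(score_all(sim$bundle),
                            score_config(threshold_c = 10))
  feats <- suppressWarnings(patient_features(sigs, sim$bundle, coh))
  manual <- sapply(coh$patients, function(p) {
    model <- nb_fit(feats[setdiff(coh$patients, p), , drop = FALSE],
                    coh$labels)
    nb_predict(model, feats[p, , drop = FALSE])$predicted
  })
  expect_equal(setNames(res$predictions$predicted, res$predictions$patient),
               manual[res$predictions$patient])
  expect_equal(res$pooled$accuracy,
               mean(manual == coh$labels[names(manual)]))
})

test_that("nested_cv is deterministic per seed and near-perfect on planted signal", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_bundle(cfg)
  coh <- simulate_cohort(sim, cfg)
  cv1 <- nested_cv(sim$bundle, coh, seed = 4)
  cv2 <- nested_cv(sim$bundle, coh, seed = 4)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$auc, cv2$auc)
  cv3 <- nested_cv(sim$bundle, coh, seed = 5)
  expect_false(identical(cv1$predictions$patient, cv3$predictions$patient))
  # strong planted effect: high pooled accuracy
  expect_gt(cv1$pooled$accuracy, 0.9)
  # outer folds partition the cohort exactly once
  expect_setequal(cv1$predictions$patient, coh$patients)
  expect_equal(anyDuplicated(cv1$predictions$patient), 0)
})

test_that("null labels drive nested_cv to the majority-class rate", {
  cfg <- sim_config(effect_delta = 0, seed = 23)
  sim <- simulate_bundle(cfg)
  coh <- simulate_cohort(sim, cfg)
  cv <- nested_cv(sim$bundle, coh, seed = 2)
  maj <- max(table(coh$labels)) / length(coh$patients)
  se <- sqrt(maj * (1 - maj) / length(coh$patients))
  expect_lt(abs(cv$pooled$accuracy - maj), 3 * se + 1e-9)
})

test_that("test patients never enter the fitted model's training data", {
  # instrument nb_fit through a wrapper protocol run replicated here:
  # fold assignment and tune/predict use the same seeded split, so we
  # re-derive the folds and assert disjointness of train and test ids
  cfg <- sim_config(seed = 29, n_patients_good = 12, n_patients_poor = 8)
  sim <- simulate_bundle(cfg)
  coh <- simulate_cohort(sim, cfg)
  folds <- caerus:::stratified_folds(coh$labels, 5L, seed = 9)
  expect_setequal(names(folds), coh$patients)
  for (k in 1:5) {
    test_ids <- names(folds)[folds == k]
    train_ids <- names(folds)[folds != k]
    expect_length(intersect(test_ids, train_ids), 0)
    expect_setequal(c(test_ids, train_ids), coh$patients)
  }
  # and the same seed regenerates the same folds (what nested_cv relies on)
  expect_identical(folds, caerus:::stratified_folds(coh$labels, 5L, seed = 9))
})
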