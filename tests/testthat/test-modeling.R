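# Grouped cross-validation, subject aggregation and SHAP ranking

test_that("group folds deal subjects into near-equal folds deterministically", {
  ids <- sprintf("s%02d", 1:44)
  folds <- make_group_folds(ids, k = 5, seed = 3)
  expect_equal(sort(unname(table(folds$fold)), decreasing = TRUE),
               c(9, 9, 9, 9, 8), ignore_attr = TRUE)
  expect_setequal(folds$subject_id, ids)
  expect_equal(anyDuplicated(folds$subject_id), 0L)
  expect_identical(folds, make_group_folds(ids, k = 5, seed = 3))
  expect_false(identical(folds$subject_id,
                         make_group_folds(ids, k = 5, seed = 4)$subject_id))
  expect_error(make_group_folds(ids[1:3], k = 5), "fewer subjects")
})

test_that("cross-validation emits one in-range probability per epoch with no leakage", {
  res <- classification_result()
  cv <- res$cv
  expect_false(anyNA(cv$prob))
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  expect_equal(length(cv$prob), sum(complete.cases(
    variable_features()[, feature_names()])))
  for (f in sort(unique(cv$fold))) {
    expect_length(intersect(cv$subject_id[cv$fold == f],
                            cv$subject_id[cv$fold != f]), 0)
  }
  # separable presets: propofol epochs lean to the positive class
  expect_gt(mean(cv$prob[cv$group == "propofol"]), 0.5)
  expect_lt(mean(cv$prob[cv$group == "sevoflurane"]), 0.5)
})

test_that("single-class training folds are rejected by name", {
  feat <- variable_features()
  one <- feat[feat$group == "propofol", ]
  expect_error(crossval_predict(one, make_group_folds(one$subject_id, 5, 1)),
               "single class")
})

test_that("subject aggregation averages, thresholds and counts correctly", {
  mk <- function(prob, subject_id, group) {
    list(prob = prob, subject_id = subject_id, group = group)
  }
  one <- aggregate_subjects(mk(c(0.6, 0.8), c("a", "a"),
                               c("propofol", "propofol")))
  expect_equal(one$subjects$mean_prob, 0.7)
  expect_equal(one$subjects$predicted, "propofol")
  # exact 0.5 resolves to propofol
  tie <- aggregate_subjects(mk(0.5, "a", "sevoflurane"))
  expect_equal(tie$subjects$predicted, "propofol")
  # counting example: truth/pred (P,P),(P,S),(S,S),(S,S)
  cm <- aggregate_subjects(mk(c(0.9, 0.1, 0.2, 0.3), letters[1:4],
                              c("propofol", "propofol", "sevoflurane",
                                "sevoflurane")))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(unclass(cm$confusion),
               matrix(c(1, 0, 1, 2), 2,
                      dimnames = list(truth = c("propofol", "sevoflurane"),
                                      predicted = c("propofol", "sevoflurane"))),
               ignore_attr = TRUE)
  # epoch order is irrelevant
  perm <- c(3, 1, 4, 2)
  cm2 <- aggregate_subjects(mk(c(0.9, 0.1, 0.2, 0.3)[perm],
                               letters[1:4][perm],
                               c("propofol", "propofol", "sevoflurane",
                                 "sevoflurane")[perm]))
  expect_equal(cm2$accuracy, cm$accuracy)
  expect_equal(cm2$confusion, cm$confusion)
})

test_that("SHAP values are exactly additive and zero for constant features", {
  res <- classification_result()
  phi <- attr(res$importance, "shap")
  expect_lt(max(abs(rowSums(phi) - res$cv$prob)), 1e-6)
  expect_equal(sort(res$importance$rank), 1:17)
  # a constant feature cannot earn importance
  feat <- variable_features()
  feat$SpecEn <- 1 # degenerate column
  res0 <- classify_cohort(feat, seed = 5)
  imp <- res0$importance
  expect_equal(imp$mean_abs_shap[imp$feature == "SpecEn"], 0)
})

test_that("cohorts differing only in theta-peak power rank theta features first", {
  # identical backgrounds and peaks except the theta bump's absolute power
  mk_params <- function(theta_power) {
    list(aperiodic = aperiodic_params(1, 2.2),
         peaks = list(peak_spec(1.2, 0.6, 2), peak_spec(6, 1, theta_power),
                      peak_spec(10, 1.2, 4), peak_spec(18, 3, 2)))
  }
  rows <- list()
  for (g in c("propofol", "sevoflurane")) {
    pars <- mk_params(if (g == "propofol") 1 else 4)
    for (s in 1:6) {
      for (e in 1:8) {
        sig <- synth_epoch_signal(pars, seed = 10000 + s * 100 + e +
                                    (g == "sevoflurane") * 50000)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = paste0(g, "_", s), group = g, epoch_index = e,
          t(extract_feature_vector(sig, 250)), stringsAsFactors = FALSE)
      }
    }
  }
  feat <- do.call(rbind, rows)
  class(feat) <- c("cohort_features", "data.frame")
  res <- classify_cohort(feat, seed = 2)
  imp <- res$importance
  theta_feats <- c("Theta_Rel", "Theta_Alpha_Ratio", "Theta_Delta_Ratio")
  # theta dynamics dominate: all three theta features sit in the top tier,
  # and together they outweigh any single competing feature (the injected
  # signal's credit is shared across the correlated theta trio)
  expect_true(all(imp$rank[imp$feature %in% theta_feats] <= 4))
  expect_gt(sum(imp$mean_abs_shap[imp$feature %in% theta_feats]),
            max(imp$mean_abs_shap[!imp$feature %in% theta_feats]))
  expect_equal(res$subjects$accuracy, 1)
})

test_that("subject-level label permutation collapses accuracy to chance", {
  feat <- variable_features()
  ids <- unique(feat$subject_id)
  perm_groups <- with_seed_local(31, sample(
    vapply(ids, function(s) feat$group[feat$subject_id == s][1],
           character(1))))
  names(perm_groups) <- ids
  feat$group <- unname(perm_groups[feat$subject_id])
  res <- classify_cohort(feat, seed = 13)
  # 3 binomial SDs around 0.5 for 40 subjects
  expect_lt(abs(res$subjects$accuracy - 0.5), 3 * sqrt(0.25 / length(ids)))
})
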