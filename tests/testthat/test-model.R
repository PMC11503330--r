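test_that("AUC equals pairwise concordance", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  s <- c(0.9, 0.8, 0.4, 0.3); l <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(auc(s, !l), 1 - auc(s, l))
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "negative")
  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("model fit is reproducible and memorizes separable data", {
  tr <- small_training()
  m1 <- validation_model(tr, seed = 99)
  m2 <- validation_model(tr, seed = 99)
  ft <- small_features()
  p1 <- predict(m1, ft)
  p2 <- predict(m2, ft)
  expect_identical(p1, p2)
  ## training peptides scored by their own model: probabilities in [0,1]
  ptr <- predict(m1, tr)
  expect_true(all(ptr$p_cor >= 0 & ptr$p_cor <= 1))
  ## linearly separable labels are memorized (training-set AUC 1)
  sep <- tr
  sep$pass_cor <- sep$fold > stats::median(sep$fold)
  ms <- validation_model(sep, outcomes = "cor", seed = 1)
  expect_equal(auc(predict(ms, sep)$p_cor, sep$pass_cor), 1)
})

test_that("degenerate training sets and schemas are rejected informatively", {
  tr <- small_training()
  bad <- tr
  bad$pass_fold <- TRUE
  expect_error(validation_model(bad), "fold")
  m <- validation_model(tr, seed = 1)
  expect_error(predict(m, tr[, -which(names(tr) == "locfdr")]), "locfdr")
})

test_that("constant feature rows get identical probabilities", {
  tr <- small_training()
  m <- validation_model(tr, seed = 5)
  const <- tr[rep(1, 6), ]
  const$peptide_id <- paste0("c", 1:6)
  p <- predict(m, const)
  expect_equal(length(unique(p$p_cor)), 1)
  expect_equal(length(unique(p$p_fold)), 1)
  expect_equal(length(unique(p$p_pval)), 1)
})

test_that("cross-validation is reproducible and detects real signal", {
  tr <- small_training()
  cv1 <- cross_validate(tr, n_repeats = 10, seed = 8, feature_aucs = TRUE,
                        n_trees = 200)
  cv2 <- cross_validate(tr, n_repeats = 10, seed = 8, feature_aucs = TRUE,
                        n_trees = 200)
  expect_identical(cv1$repeat_auc, cv2$repeat_auc)
  expect_identical(cv1$feature_auc, cv2$feature_auc)
  ## planted signal is easy: strong AUC for every outcome
  expect_true(all(cv1$mean_auc > 0.85))
  ## the full panel is not dominated by any single feature
  expect_true(all(cv1$mean_auc >= apply(cv1$feature_auc, 2, max) - 0.05))
})

test_that("permuted labels drive cross-validated AUC to chance", {
  tr <- small_training()
  set.seed(52)
  aucs <- replicate(3, {
    trp <- tr
    trp[c("pass_cor", "pass_fold", "pass_p")] <-
      lapply(tr[c("pass_cor", "pass_fold", "pass_p")], sample)
    cross_validate(trp, n_repeats = 10, seed = 9,
                   feature_aucs = FALSE, n_trees = 200)$mean_auc
  })
  expect_true(all(rowMeans(aucs) > 0.3 & rowMeans(aucs) < 0.7))
})

test_that("repeat-level AUC standard error shrinks with more repeats", {
  tr <- small_training()
  cv50 <- cross_validate(tr, n_repeats = 50, seed = 10, feature_aucs = FALSE,
                         n_trees = 100)
  cv500 <- cross_validate(tr, n_repeats = 500, seed = 10,
                          feature_aucs = FALSE, n_trees = 100)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  ## judged on the p-value outcome, whose held-out AUC genuinely varies
  ## across repeats (the cor/fold outcomes can sit at a degenerate 1.0)
  expect_lt(sem(cv500$repeat_auc[, "pval"]), sem(cv50$repeat_auc[, "pval"]))
})

test_that("raw-feature AUC mode honors feature orientation", {
  tr <- small_training()
  cv <- cross_validate(tr, n_repeats = 5, seed = 11, feature_aucs = TRUE,
                       feature_auc_mode = "raw", n_trees = 50)
  ## on planted data, fold and locfdr should both score well above chance
  ## once oriented (low locfdr = strong evidence)
  expect_gt(cv$feature_auc["fold", "cor"], 0.7)
  expect_gt(cv$feature_auc["locfdr", "cor"], 0.7)
})

test_that("selection rules reproduce the worked examples", {
  covid <- validation_panel("covid")
  sel <- select_peptides(covid, selection_rule("all_exceed", 0.5))
  expect_setequal(sel$peptide_id, c("surf-1253", "mem-8", "nucl-390"))
  lupus <- validation_panel("lupus")
  expect_equal(nrow(select_peptides(lupus,
                                    selection_rule("mean_exceeds", 0.75))), 5)
  spa <- validation_panel("spa")
  sel_spa <- select_peptides(spa, selection_rule("mean_exceeds", 0.75))
  expect_equal(nrow(sel_spa), 3)
  q13 <- sel_spa[sel_spa$peptide_id == "Q13330-195", ]
  expect_equal(q13$mean_p, mean(c(0.756, 0.828, 0.844)))

  ones <- data.frame(peptide_id = "x", p_cor = 1, p_fold = 1, p_pval = 1)
  zeros <- data.frame(peptide_id = "x", p_cor = 0, p_fold = 0, p_pval = 0)
  for (rule in list(selection_rule("all_exceed", 0.5),
                    selection_rule("mean_exceeds", 0.75))) {
    expect_equal(nrow(select_peptides(ones, rule)), 1)
    expect_equal(nrow(select_peptides(zeros, rule)), 0)
  }
})

test_that("selection is monotone in the threshold and all_exceed is stricter", {
  set.seed(53)
  probs <- data.frame(peptide_id = sprintf("p%03d", 1:200),
                      p_cor = runif(200), p_fold = runif(200),
                      p_pval = runif(200))
  for (mode in c("all_exceed", "mean_exceeds")) {
    lo <- select_peptides(probs, selection_rule(mode, 0.3))$peptide_id
    hi <- select_peptides(probs, selection_rule(mode, 0.6))$peptide_id
    expect_true(all(hi %in% lo))
  }
  for (t in c(0.25, 0.5, 0.75)) {
    strict <- select_peptides(probs, selection_rule("all_exceed", t))
    loose <- select_peptides(probs, selection_rule("mean_exceeds", t))
    expect_true(all(strict$peptide_id %in% loose$peptide_id))
  }
})

test_that("enrichment report reproduces printed-count arithmetic", {
  ## a library shaped like the seropositive validation selection:
  ## 1813 selected, 1797 citrulline-containing
  n <- 2400
  recs <- data.frame(
    peptide_id = sprintf("p%04d", 1:n),
    sequence = c(rep("ABKAGBSAGGSAGGSA", 1797),
                 rep("ACDEFGHILMNPQSTV", n - 1797)),
    protein_id = sprintf("pr%04d", 1:n),
    start = 1,
    modification = c(rep("citrullinated", 1797), rep("native", n - 1797)),
    stringsAsFactors = FALSE)
  lib <- peptide_library(recs)
  selected <- sprintf("p%04d", 1:1813)
  er <- enrichment_report(selected, lib)
  expect_equal(er$n_selected, 1813)
  expect_equal(er$n_selected_citrulline, 1797)
  expect_equal(round(100 * er$selected_citrulline, 1), 99.1)

  ## no citrulline anywhere: both fractions zero
  lib0 <- tiny_library()
  er0 <- enrichment_report(lib0$records$peptide_id[1], lib0)
  expect_equal(er0$selected_citrulline, 0)
  expect_equal(er0$library_citrulline, 0)

  ## empty selection is flagged, not an error
  er_empty <- enrichment_report(character(0), lib0)
  expect_true(er_empty$empty)
  expect_true(is.na(er_empty$selected_citrulline))
})
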