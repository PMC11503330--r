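test_that("rank-sum test matches the classical exact values", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3)), 0.1)
  ## identical multisets sit at the center of the null distribution
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "exact"), 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact p-values agree with the enumeration oracle, and are symmetric", {
  set.seed(41)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    pr <- random_tiefree_pair(n1, n2)
    p <- mann_whitney(pr$a, pr$b, mode = "exact")
    expect_equal(p, oracle_ranksum_p(pr$a, pr$b))
    expect_equal(p, mann_whitney(pr$b, pr$a, mode = "exact"))
  }
  ## ties: enumeration handles them exactly too
  a <- c(1, 1, 2, 5); b <- c(2, 3, 3, 4)
  expect_equal(mann_whitney(a, b, mode = "exact"), oracle_ranksum_p(a, b))
})

test_that("normal approximation tracks the exact test for n = 8 vs 8", {
  set.seed(42)
  for (i in 1:20) {
    pr <- random_tiefree_pair(8, 8)
    pe <- mann_whitney(pr$a, pr$b, mode = "exact")
    pn <- mann_whitney(pr$a, pr$b, mode = "normal")
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Spearman correlation handles monotone, reversed, tied and constant input", {
  x <- c(3, 9, 27, 81, 150)
  expect_equal(spearman(x, log(x)), 1)
  expect_equal(spearman(x, rev(x)), -1)
  ## mid-rank oracle on tied data
  set.seed(43)
  for (i in 1:10) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    ra <- rank(a); rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(spearman(a, b), oracle)
  }
  expect_warning(res <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res))
  expect_error(spearman(1:3, 1:4), "unequal")
})

test_that("ELISA summaries match an independent recomputation", {
  st <- small_study()
  id <- st$training_ids[1]
  sub <- st$elisa[st$elisa$peptide_id == id, ]
  absorb <- stats::setNames(sub$absorbance, sub$subject_id)
  arr <- st$experiment$intensity[id, ]
  s <- summarize_elisa(absorb, st$design, arr)
  exp_sub <- names(st$design$groups)[st$design$groups == "disease"]
  con_sub <- names(st$design$groups)[st$design$groups == "control"]
  expect_equal(s$e_fold,
               mean(absorb[exp_sub]) / max(mean(absorb[con_sub]), 0.001),
               tolerance = 1e-12)
  expect_equal(s$e_cor,
               stats::cor(arr[c(exp_sub, con_sub)],
                          absorb[c(exp_sub, con_sub)], method = "spearman"),
               tolerance = 1e-12)
  ## on a contrast small enough for full enumeration, the p-value matches
  ## the enumeration oracle exactly
  keep <- c(exp_sub[1:4], con_sub[1:4])
  d2 <- group_design(st$design$groups[keep], "disease", "control")
  s2 <- summarize_elisa(absorb[keep], d2, arr[keep], p_mode = "exact")
  expect_equal(s2$e_p, oracle_ranksum_p(absorb[exp_sub[1:4]],
                                        absorb[con_sub[1:4]]),
               tolerance = 1e-12)
})

test_that("degenerate ELISA configurations behave as expected", {
  groups <- stats::setNames(rep(c("d", "c"), each = 4),
                            c(paste0("e", 1:4), paste0("c", 1:4)))
  d <- group_design(groups, "d", "c")
  arr <- stats::setNames(c(100, 200, 300, 400, 50, 60, 70, 80), names(groups))
  ## absorbance a monotone function of array signal: perfect correlation
  s <- summarize_elisa(arr / 100, d, arr)
  expect_equal(s$e_cor, 1)
  ## identical group distributions: fold 1, p at the top of its range
  ab <- stats::setNames(c(1, 2, 3, 4, 1, 2, 3, 4), names(groups))
  s2 <- summarize_elisa(ab, d, arr)
  expect_equal(s2$e_fold, 1)
  expect_gt(s2$e_p, 0.8)
  ## subject mismatch is an integrity error
  expect_error(summarize_elisa(ab[-1], d, arr[-(1:2)]), "mismatch")
})

test_that("criteria evaluation reproduces the worked-example patterns", {
  crit <- criteria_config()
  check <- function(e_cor, e_fold, e_p, expected) {
    lab <- evaluate_criteria(list(e_cor = e_cor, e_fold = e_fold, e_p = e_p),
                             crit)
    expect_equal(unlist(lab), c(pass_cor = expected[1],
                                pass_fold = expected[2],
                                pass_p = expected[3]))
  }
  check(0.83, 8.75, 2.3e-9, c(TRUE, TRUE, TRUE))    # surf-1253
  check(0.59, 1.98, 6.0e-5, c(FALSE, FALSE, TRUE))  # surf-814
  check(0.44, 9.3, 0.013, c(FALSE, TRUE, TRUE))     # Q9Y468-515
  check(0.6, 5.0, 0.1, c(FALSE, TRUE, TRUE))        # strict vs inclusive
  ## undefined correlation fails the correlation criterion
  check(NA_real_, 8, 0.01, c(FALSE, TRUE, TRUE))
})

test_that("training labels join features to outcomes and are recomputable", {
  st <- small_study()
  tr <- small_training()
  expect_equal(nrow(tr), length(st$training_ids))
  expect_setequal(tr$peptide_id, st$training_ids)
  expect_true(all(c("pass_cor", "pass_fold", "pass_p") %in% names(tr)))
  ## labels recomputed independently for a few peptides
  crit <- criteria_config()
  set.seed(44)
  for (id in sample(st$training_ids, 3)) {
    sub <- st$elisa[st$elisa$peptide_id == id, ]
    s <- summarize_elisa(stats::setNames(sub$absorbance, sub$subject_id),
                         st$design, st$experiment$intensity[id, ])
    row <- tr[tr$peptide_id == id, ]
    expect_equal(row$pass_cor, isTRUE(s$e_cor > crit$cor_threshold))
    expect_equal(row$pass_fold, isTRUE(s$e_fold >= crit$fold_threshold))
    expect_equal(row$pass_p, isTRUE(s$e_p <= crit$p_threshold))
  }
  ## unjoinable peptides are an integrity error
  rogue <- data.frame(peptide_id = "nope", subject_id = "e1",
                      absorbance = 0.5)
  expect_error(make_training_labels(rbind(st$elisa, rogue), small_features(),
                                    st$experiment, st$design), "nope")
})
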