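make_stats <- function(effect, se, df = 14) {
  data.frame(peptide_id = sprintf("p%04d", seq_along(effect)),
             effect = effect, se = se, z = effect / se, df = df,
             stringsAsFactors = FALSE)
}

test_that("Welch statistics match an independent t.test recomputation", {
  st <- small_study()
  stats <- peptide_test_statistics(st$experiment, st$design)
  x <- log2(st$experiment$intensity + 1)
  exp_sub <- names(st$design$groups)[st$design$groups == "disease"]
  con_sub <- names(st$design$groups)[st$design$groups == "control"]
  floor_val <- stats::quantile(
    vapply(rownames(x), function(id) {
      sqrt(stats::var(x[id, exp_sub]) / length(exp_sub) +
             stats::var(x[id, con_sub]) / length(con_sub))
    }, numeric(1)), 0.01, names = FALSE)
  set.seed(21)
  for (id in sample(rownames(x), 10)) {
    tt <- stats::t.test(x[id, exp_sub], x[id, con_sub])
    row <- stats[stats$peptide_id == id, ]
    expect_equal(row$effect, unname(diff(rev(tt$estimate))))
    if (row$se > floor_val + 1e-12) {
      expect_equal(row$se, unname(tt$stderr))
      expect_equal(row$df, unname(tt$parameter))
      expect_equal(row$z, unname(tt$statistic))
    }
  }
})

test_that("identical groups give zero effects and small groups are rejected", {
  lib <- tiny_library()
  d <- group_design(c(e1 = "d", e2 = "d", c1 = "c", c2 = "c"), "d", "c")
  ## arms with identical value patterns: every effect is exactly zero
  m0 <- matrix(rep(c(5, 7, 5, 7), each = 4), nrow = 4,
               dimnames = list(lib$records$peptide_id,
                               c("e1", "e2", "c1", "c2")))
  s0 <- peptide_test_statistics(array_experiment(m0, lib), d)
  expect_equal(s0$effect, rep(0, 4))

  ## separated arms reproduce the hand-computed log2 effect
  m <- matrix(rep(c(8, 9, 2, 3), each = 4), nrow = 4,
              dimnames = dimnames(m0))
  s <- peptide_test_statistics(array_experiment(m, lib), d)
  expect_equal(s$effect, rep(mean(log2(c(9, 10))) - mean(log2(c(3, 4))), 4))
  expect_true(all(s$se > 0))

  d1 <- group_design(c(e1 = "d", e2 = "c", c1 = "c", c2 = "c"), "d", "c")
  expect_error(peptide_test_statistics(array_experiment(m, lib), d1), ">= 2")
})

test_that("degenerate zero-variance rows are floored, not infinite", {
  set.seed(3)
  lib <- peptide_library(tile_protein("pp", paste(
    sample(c("A", "C", "D", "G"), 150, replace = TRUE), collapse = "")))
  n <- nrow(lib$records)
  m <- matrix(rlnorm(n * 8, 5, 0.5), n, 8,
              dimnames = list(lib$records$peptide_id,
                              c(paste0("e", 1:4), paste0("c", 1:4))))
  m[1, ] <- rep(c(8, 2), each = 4)   # zero within-group variance
  d <- group_design(stats::setNames(rep(c("d", "c"), each = 4), colnames(m)),
                    "d", "c")
  s <- peptide_test_statistics(array_experiment(m, lib), d)
  expect_true(all(is.finite(s$z)))
  expect_true(all(s$se > 0))
  expect_equal(s$effect[1], log2(9) - log2(3))
})

test_that("EM log-likelihood is monotone and weights normalize", {
  set.seed(31)
  s <- make_stats(rnorm(300, 0, 0.6), sqrt(0.25 * rchisq(300, 14) / 14))
  mx <- estimate_locfdr(s)
  expect_true(all(diff(mx$loglik) >= -1e-8))
  expect_equal(sum(mx$effect_weights), 1)
  expect_equal(sum(mx$var_weights), 1)
  expect_true(all(mx$effect_weights >= 0) && all(mx$var_weights >= 0))
  expect_true(all(mx$locfdr >= 0 & mx$locfdr <= 1))
  expect_true(0 %in% mx$effect_grid)
})

test_that("pure-null arrays yield dominant null mass", {
  spec <- signal_spec(n_proteins = 8, protein_length = c(150, 170),
                      n_exp = 8, n_con = 8, n_antigens = 0,
                      modified_fraction = 0)
  st <- generate_experiment(generate_proteome(spec, 42), spec, 42)
  mx <- estimate_locfdr(peptide_test_statistics(st$experiment, st$design))
  expect_gte(mean(mx$locfdr), 0.9)
})

test_that("locFDR ranks true signals ahead of nulls in a two-point mixture", {
  set.seed(33)
  n <- 1000
  nonnull <- rbinom(n, 1, 0.1) == 1
  e <- rnorm(n, ifelse(nonnull, 3, 0), 0.5)
  s <- make_stats(e, sqrt(0.25 * rchisq(n, 14) / 14))
  mx <- estimate_locfdr(s)
  top <- order(mx$locfdr)[seq_len(n / 10)]
  enrichment <- mean(nonnull[top]) / mean(nonnull)
  expect_gte(enrichment, 5)
})

test_that("locFDR and r-values are invariant to peptide ordering", {
  set.seed(34)
  s <- make_stats(rnorm(200, 0, 1), runif(200, 0.2, 0.6))
  perm <- sample(nrow(s))
  mx1 <- estimate_locfdr(s)
  mx2 <- estimate_locfdr(s[perm, ])
  expect_equal(mx2$locfdr[names(mx1$locfdr)], mx1$locfdr, tolerance = 1e-6)
  r1 <- compute_rvalues(s)
  r2 <- compute_rvalues(s[perm, ])
  expect_equal(r2$rvalue[names(r1$rvalue)], r1$rvalue, tolerance = 1e-9)
})

test_that("r-values rank by effect under equal standard errors", {
  set.seed(35)
  e <- rnorm(100, 0, 1)
  s <- make_stats(e, rep(0.4, 100))
  rv <- compute_rvalues(s)$rvalue
  ## sorted by decreasing effect, r-values are non-decreasing
  expect_true(all(diff(rv[order(-e)]) >= 0))
  expect_gt(stats::cor(rv, -e, method = "spearman"), 0.999)
})

test_that("a noisy estimate is shrunk toward weak evidence", {
  set.seed(36)
  e <- c(rnorm(98, 0, 0.8), 2.5, 2.5)
  se <- c(runif(98, 0.3, 0.5), 0.2, 5)
  s <- make_stats(e, se)
  rv <- compute_rvalues(s)$rvalue
  expect_gt(rv[100], rv[99])   # same effect, much larger se
  ## dense-grid oracle for the precise peptide: smallest alpha satisfying
  ## the posterior tail condition, computed directly
  fit <- compute_rvalues(s)
  dense <- seq(0.001, 0.999, by = 0.001)
  post_var <- 1 / (1 / fit$tau2 + 1 / se[99]^2)
  post_mean <- post_var * (fit$m / fit$tau2 + e[99] / se[99]^2)
  ok <- stats::pnorm(stats::qnorm(1 - dense, fit$m, sqrt(fit$tau2)),
                     post_mean, sqrt(post_var), lower.tail = FALSE) >=
    1 - dense
  expect_equal(unname(rv[99]), min(dense[ok]))
})

test_that("all-null r-values avoid the strong-evidence end of the grid", {
  set.seed(37)
  s <- make_stats(rnorm(500, 0, 0.45), rep(0.45, 500))
  rv <- compute_rvalues(s)$rvalue
  expect_true(all(rv > 0 & rv <= 1))
  expect_lte(mean(rv <= 0.1), 0.02)
  expect_gte(stats::median(rv), 0.4)
})

test_that("inference requires enough peptides to borrow strength", {
  s <- make_stats(rnorm(20), runif(20, 0.2, 0.4))
  expect_error(estimate_locfdr(s), ">= 50")
  expect_error(compute_rvalues(s), ">= 50")
})
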