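#' Per-peptide two-group test statistics
#'
#' Welch two-sample statistics on log2(intensity + 1): effect = difference of
#' group means (experimental minus control), standard error from the Welch
#' formula, Welch-Satterthwaite degrees of freedom. Standard errors below the
#' 1st percentile of all standard errors are raised to that percentile so
#' that degenerate rows (zero within-group variance) do not produce infinite
#' z-values.
#'
#' @param experiment An \code{\link{array_experiment}}.
#' @param design A \code{\link{group_design}}; each contrast arm needs at
#'   least two subjects.
#' @return A data frame of class \code{"peptide_stats"}: columns
#'   \code{peptide_id}, \code{effect}, \code{se}, \code{z}, \code{df}.
#' @export
peptide_test_statistics <- function(experiment, design) {
  stopifnot(inherits(experiment, "array_experiment"),
            inherits(design, "group_design"))
  x <- log2(experiment$intensity + 1)
  arms <- contrast_subjects(design, colnames(x))
  n1 <- length(arms$exp); n2 <- length(arms$con)
  if (n1 < 2L || n2 < 2L)
    stop("peptide_test_statistics: each contrast arm needs >= 2 subjects")
  xe <- x[, arms$exp, drop = FALSE]
  xc <- x[, arms$con, drop = FALSE]
  m1 <- rowMeans(xe); m2 <- rowMeans(xc)
  v1 <- rowSums((xe - m1)^2) / (n1 - 1)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1)
  a1 <- v1 / n1; a2 <- v2 / n2
  se <- sqrt(a1 + a2)
  df <- (a1 + a2)^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  df[!is.finite(df)] <- n1 + n2 - 2          # zero-variance rows
  se_floor <- stats::quantile(se, 0.01, names = FALSE)
  if (se_floor <= 0) {
    pos <- se[se > 0]
    se_floor <- if (length(pos) > 0L) min(pos) else 1e-8
  }
  se <- pmax(se, se_floor)
  out <- data.frame(peptide_id = rownames(x),
                    effect = unname(m1 - m2),
                    se = unname(se),
                    z = unname((m1 - m2) / se),
                    df = unname(df),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("peptide_stats", "data.frame")
  out
}

#' Empirical-Bayes local false discovery rate by grid NPMLE
#'
#' Fits a nonparametric mixture to the per-peptide (effect, se^2) pairs under
#' the sampling model effect_i | theta, sigma2 ~ N(theta, sigma2) and
#' se_i^2 | sigma2 ~ sigma2 * chi2(df_i) / df_i. The mixing distribution is a
#' product of a symmetric effect grid (with a dedicated point at exactly 0
#' carrying the null mass) and a log-spaced variance grid; weights are the
#' maximum-likelihood estimates found by EM. The local false discovery rate
#' of peptide i is the posterior probability that its true effect is 0.
#'
#' @param stats A \code{"peptide_stats"} data frame
#'   (\code{\link{peptide_test_statistics}}); at least 50 peptides.
#' @param effect_grid_size,var_grid_size Grid resolutions (effect grid size
#'   is forced odd so 0 is a grid point).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter EM iteration cap; non-convergence warns and returns the
#'   best iterate.
#' @return An object of class \code{"mixing_estimate"}: effect/variance grids
#'   and weights, per-peptide \code{locfdr}, the log-likelihood trace,
#'   convergence flag.
#' @export
estimate_locfdr <- function(stats, effect_grid_size = 15L,
                            var_grid_size = 15L, tol = 1e-8,
                            max_iter = 5000L) {
  stats <- check_peptide_stats(stats)
  n <- nrow(stats)
  if (n < 50L)
    stop("estimate_locfdr: need >= 50 peptides for empirical-Bayes borrowing")
  e <- stats$effect
  s2 <- stats$se^2
  df <- stats$df
  if (any(!is.finite(e)) || any(!is.finite(s2)) || any(s2 <= 0))
    stop("estimate_locfdr: degenerate statistics (non-finite or zero se)")

  J <- as.integer(effect_grid_size)
  if (J %% 2L == 0L) J <- J + 1L
  K <- as.integer(var_grid_size)
  M <- max(abs(e))
  if (M <= 0) M <- 1e-6
  ## nonzero effect magnitudes are log-spaced from a noise floor (about
  ## twice the typical standard error) up to the largest observed effect:
  ## effects below the noise floor are not resolvable from zero and would
  ## only siphon mass off the null point
  delta_min <- max(2 * stats::median(stats$se), M / 100)
  half <- (J - 1L) %/% 2L
  mags <- if (delta_min >= M) rep(M, half) else
    exp(seq(log(delta_min), log(M), length.out = half))
  mags <- unique(mags)
  theta <- c(-rev(mags), 0, mags)
  J <- length(theta)
  v_lo <- max(min(s2), 1e-12)
  v_hi <- max(s2)
  vgrid <- if (v_hi / v_lo < 1 + 1e-9) rep(v_lo, 1L) else
    exp(seq(log(v_lo), log(v_hi), length.out = K))
  K <- length(vgrid)

  ## likelihood matrix, column (k-1)*J + j  <->  (theta_j, v_k)
  L <- matrix(0, n, J * K)
  for (k in seq_len(K)) {
    vk <- vgrid[k]
    g <- stats::dchisq(df * s2 / vk, df) * df / vk
    sdk <- sqrt(vk)
    for (j in seq_len(J))
      L[, (k - 1L) * J + j] <- stats::dnorm(e, theta[j], sdk) * g
  }
  L <- pmax(L, 1e-300)

  u <- rep(1 / J, J)
  v <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- as.vector(outer(u, v))            # column-major: j fastest
    lik <- as.vector(L %*% w)
    ll <- sum(log(lik))
    ll_trace <- c(ll_trace, ll)
    if (it > 1L &&
        (ll - ll_trace[it - 1L]) <= tol * (abs(ll_trace[it - 1L]) + 1e-12)) {
      converged <- TRUE
      break
    }
    cjk <- w * as.vector(crossprod(L, 1 / lik))
    Cm <- matrix(cjk, J, K)
    u <- rowSums(Cm) / n
    v <- colSums(Cm) / n
    u <- u / sum(u); v <- v / sum(v)
  }
  if (!converged)
    warning("estimate_locfdr: EM did not converge in ", max_iter,
            " iterations; returning best iterate")

  j0 <- which(theta == 0)
  w <- as.vector(outer(u, v))
  lik <- as.vector(L %*% w)
  null_cols <- (seq_len(K) - 1L) * J + j0
  locfdr <- as.vector(L[, null_cols, drop = FALSE] %*% (u[j0] * v)) / lik
  locfdr <- pmin(pmax(locfdr, 0), 1)

  structure(list(effect_grid = theta, effect_weights = u,
                 var_grid = vgrid, var_weights = v,
                 locfdr = stats::setNames(locfdr, stats$peptide_id),
                 loglik = ll_trace, converged = converged,
                 n_iter = length(ll_trace)),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat("Grid-NPMLE mixing estimate:", length(x$locfdr), "peptides,",
      length(x$effect_grid), "x", length(x$var_grid), "grid\n")
  cat(sprintf("  null mass %.3f; EM %s after %d iterations\n",
              x$effect_weights[x$effect_grid == 0],
              if (x$converged) "converged" else "did not converge",
              x$n_iter))
  invisible(x)
}

check_peptide_stats <- function(stats) {
  need <- c("peptide_id", "effect", "se", "df")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop("expected a peptide_stats data frame with columns: ",
         paste(need, collapse = ", "))
  stats
}

#' Empirical-Bayes r-values for ranking effect sizes
#'
#' Fits a normal-normal hierarchical model (theta_i ~ N(m, tau^2), observed
#' effect_i ~ N(theta_i, se_i^2)) by marginal maximum likelihood, then ranks
#' peptides by how confidently their posterior effect sits in the upper tail
#' of the fitted effect distribution: rvalue_i is the smallest alpha on the
#' grid such that P(theta_i > q_{1-alpha}) >= 1 - alpha, where q_{1-alpha} is
#' the (1-alpha) quantile of N(m, tau^2). Small r-values mean strong evidence
#' of a large effect; precision feeds in through the posterior, so noisy
#' estimates are shrunk toward 1.
#'
#' @param stats A \code{"peptide_stats"} data frame; at least 50 peptides.
#' @param alpha_grid Grid of candidate alpha levels in (0, 1).
#' @return An object of class \code{"rvalue_estimate"}: the named
#'   \code{rvalue} vector plus the fitted \code{m} and \code{tau2}.
#' @export
compute_rvalues <- function(stats, alpha_grid = seq(0.001, 0.999, by = 0.001)) {
  stats <- check_peptide_stats(stats)
  if (nrow(stats) < 50L)
    stop("compute_rvalues: need >= 50 peptides for empirical-Bayes borrowing")
  stopifnot(all(alpha_grid > 0), all(alpha_grid < 1))
  alpha_grid <- sort(alpha_grid)
  e <- stats$effect
  s2 <- stats$se^2

  nll <- function(par) {
    tau2 <- exp(par[2])
    -sum(stats::dnorm(e, par[1], sqrt(tau2 + s2), log = TRUE))
  }
  init <- c(mean(e), log(max(stats::var(e) - mean(s2), mean(s2) * 0.1, 1e-8)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  if (!is.finite(fit$value))
    stop("compute_rvalues: degenerate variance fit")
  m <- fit$par[1]
  tau2 <- exp(fit$par[2])
  tau2 <- max(tau2, 1e-10 * max(stats::var(e), 1e-12))

  post_var <- 1 / (1 / tau2 + 1 / s2)
  post_mean <- post_var * (m / tau2 + e / s2)
  post_sd <- sqrt(post_var)

  ## condition is monotone in alpha: bisect to the smallest qualifying index
  cond <- function(idx) {
    a <- alpha_grid[idx]
    q <- stats::qnorm(1 - a, m, sqrt(tau2))
    stats::pnorm(q, post_mean, post_sd, lower.tail = FALSE) >= 1 - a
  }
  nal <- length(alpha_grid)
  n <- length(e)
  lo <- rep(1L, n); hi <- rep(nal, n)
  top_ok <- cond(hi)
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    ok <- cond(mid)
    hi[ok] <- mid[ok]
    lo[!ok] <- mid[!ok] + 1L
  }
  rv <- alpha_grid[lo]
  rv[!top_ok] <- alpha_grid[nal]   # never qualifies: weakest possible rank

  structure(list(rvalue = stats::setNames(rv, stats$peptide_id),
                 m = m, tau2 = tau2),
            class = "rvalue_estimate")
}

#' Run the full empirical-Bayes inference layer for a contrast
#'
#' Convenience wrapper: Welch statistics on log2(intensity + 1), grid-NPMLE
#' locFDR, and r-values, bundled for \code{\link{compute_features}}.
#'
#' @param experiment An \code{\link{array_experiment}}.
#' @param design A \code{\link{group_design}}.
#' @param effect_grid_size,var_grid_size,tol,max_iter Passed to
#'   \code{\link{estimate_locfdr}}.
#' @param alpha_grid Passed to \code{\link{compute_rvalues}}.
#' @return An object of class \code{"peptide_inference"}: \code{stats},
#'   \code{locfdr}, \code{rvalue}, \code{mixing}, \code{rfit}.
#' @export
peptide_inference <- function(experiment, design,
                              effect_grid_size = 15L, var_grid_size = 15L,
                              tol = 1e-8, max_iter = 5000L,
                              alpha_grid = seq(0.001, 0.999, by = 0.001)) {
  stats <- peptide_test_statistics(experiment, design)
  mixing <- estimate_locfdr(stats, effect_grid_size = effect_grid_size,
                            var_grid_size = var_grid_size,
                            tol = tol, max_iter = max_iter)
  rfit <- compute_rvalues(stats, alpha_grid = alpha_grid)
  structure(list(stats = stats,
                 locfdr = mixing$locfdr,
                 rvalue = rfit$rvalue,
                 mixing = mixing, rfit = rfit),
            class = "peptide_inference")
}

#' @export
print.peptide_inference <- function(x, ...) {
  cat("Empirical-Bayes inference over", nrow(x$stats), "peptides\n")
  cat(sprintf("  locFDR <= 0.2: %d peptides; median r-value %.3f\n",
              sum(x$locfdr <= 0.2), stats::median(x$rvalue)))
  invisible(x)
}

#' Write inference results as TSV
#'
#' @param inference A \code{\link{peptide_inference}}.
#' @param path File path.
#' @export
write_inference <- function(inference, path) {
  stopifnot(inherits(inference, "peptide_inference"))
  df <- inference$stats
  df$locfdr <- unname(inference$locfdr[df$peptide_id])
  df$rvalue <- unname(inference$rvalue[df$peptide_id])
  write_tsv(df, path)
  invisible(path)
}
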