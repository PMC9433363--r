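test_that("bivariate normal cell probabilities match an independent oracle", {
  # rectangle probabilities computed independently with mvtnorm::pmvnorm
  ta <- c(-0.7, 0.4, 1.1); tb <- c(-0.3, 0.8)
  oracle <- list(
    `-0.85` = c(0.0029476719, 0.0793422292, 0.1596737512, 0.1000445388,
                0.2623386820, 0.0510748686, 0.1489861190, 0.0588340830,
                0.0010919955, 0.1301102482, 0.0055410295, 0.0000147833),
    `0.3` = c(0.1296197567, 0.0859086153, 0.0264352803, 0.1626347909,
              0.1721702089, 0.0786530896, 0.0615557858, 0.0908250529,
              0.0565313587, 0.0282782445, 0.0571521465, 0.0502356700),
    `0.95` = c(0.2364693983, 0.0054942278, 0.0000000262, 0.1450207677,
               0.2632421119, 0.0051952097, 0.0005982955, 0.1299408641,
               0.0783730378, 0.0000001163, 0.0073788198, 0.1282871248))
  for (r in names(oracle)) {
    P <- semfma:::cpp_bvn_cell_probs(ta, tb, as.numeric(r))
    expect_lt(max(abs(as.vector(t(P)) - oracle[[r]])), 1e-9)
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
})

test_that("thresholds are inverse normal cdf values of cumulative proportions", {
  # category probabilities 0.24, 0.41, 0.22, 0.10, 0.03
  tau <- design_thresholds("moderate")
  expect_equal(tau, c(-0.7063026, 0.3853205, 1.1263911, 1.8807936),
               tolerance = 1e-6)
  # five equiprobable categories: symmetric quantiles
  x <- rep(1:5, each = 20)
  t5 <- estimate_thresholds(x, 5)
  expect_equal(t5[1], -t5[4])
  expect_equal(t5[2], -t5[3])
  # large-sample threshold recovery
  set.seed(20260902)
  z <- rnorm(1e5)
  codes <- findInterval(z, tau) + 1L
  expect_lt(max(abs(estimate_thresholds(codes, 5) - tau)), 0.02)
})

test_that("pairwise correlation estimates are consistent", {
  set.seed(20260903)
  n <- 1e5
  tau1 <- design_thresholds("moderate")
  tau2 <- c(-0.5, 0.1, 0.9, 1.6)
  # independence
  x <- findInterval(rnorm(n), tau1) + 1L
  y <- findInterval(rnorm(n), tau2) + 1L
  f0 <- fit_polychoric_pair(x, y, estimate_thresholds(x, 5),
                            estimate_thresholds(y, 5))
  expect_lt(abs(f0$rho), 0.02)
  # rho = 0.5 with moderately asymmetric thresholds
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  x <- findInterval(z1, tau1) + 1L
  y <- findInterval(z2, tau2) + 1L
  f <- fit_polychoric_pair(x, y, estimate_thresholds(x, 5),
                           estimate_thresholds(y, 5))
  expect_equal(f$rho, 0.5, tolerance = 0.01)
  expect_false(f$boundary)
  # the score root agrees with a direct grid search of the likelihood
  grid <- seq(-0.99, 0.99, by = 1e-3)
  ll <- vapply(grid, function(r)
    semfma:::cpp_polychoric_loglik(f$table, estimate_thresholds(x, 5),
                                   estimate_thresholds(y, 5), r), 0)
  expect_lt(abs(f$rho - grid[which.max(ll)]), 1e-3)
})

test_that("the correlation matrix recovers the population and respects relabeling", {
  set.seed(20260904)
  d <- simulation_design(zeta = 0, n = 2e4, n_replications = 1, base_seed = 77)
  dat <- generate_dataset(d, 1, narrow_pop)
  pf <- polychoric(dat, upsilon = FALSE)
  expect_lt(max(abs(pf$rho_matrix - narrow_pop$Sigma)), 0.025)
  expect_true(all(abs(pf$rho) < 1))
  # permuting variables permutes the estimates consistently
  perm <- c(3, 1, 2, 4:12)
  datp <- ordinal_dataset(dat$values[, perm], dat$ncat[perm])
  pfp <- polychoric(datp, upsilon = FALSE)
  expect_equal(unname(pfp$rho_matrix), unname(pf$rho_matrix[perm, perm]),
               tolerance = 1e-10)
  # two variables: reduces to the pairwise estimator
  dat2 <- ordinal_dataset(dat$values[, 1:2], dat$ncat[1:2])
  pf2 <- polychoric(dat2, upsilon = FALSE)
  tau <- pf$thresholds
  fp <- fit_polychoric_pair(dat$values[, 2], dat$values[, 1],
                            tau[[2]], tau[[1]])
  expect_equal(unname(pf2$rho), fp$rho)
})

test_that("empty categories are collapsed and flagged", {
  x <- cbind(c(rep(1L, 40), rep(2L, 40), rep(5L, 20)),
             rep(1:5, 20))
  dat <- ordinal_dataset(x, ncat = c(5L, 5L))
  expect_true(dat$collapsed[1])
  expect_false(dat$collapsed[2])
  expect_equal(dat$ncat, c(3L, 5L))
  pf <- polychoric(dat, upsilon = TRUE)
  expect_true(is.finite(pf$rho))
})

test_that("the sandwich covariance is symmetric PSD and matches Monte Carlo", {
  p <- pipeline_state()
  ups <- p$pf$upsilon
  expect_true(isSymmetric(ups, tol = 1e-10))
  ev <- eigen(ups, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # Monte Carlo contract on a single pair: the empirical variance of
  # sqrt(n)(rho_hat - rho_true) matches the average sandwich estimate
  set.seed(20260905)
  rho_true <- 0.665
  tau <- design_thresholds("moderate")
  S <- matrix(c(1, rho_true, rho_true, 1), 2)
  R <- 300; n <- 500
  est <- numeric(R); ups1 <- numeric(R)
  for (r in 1:R) {
    z <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
    codes <- cbind(findInterval(z[, 1], tau) + 1L,
                   findInterval(z[, 2], tau) + 1L)
    pfr <- polychoric(ordinal_dataset(codes, c(5L, 5L)), upsilon = TRUE)
    est[r] <- pfr$rho; ups1[r] <- pfr$upsilon[1, 1]
  }
  emp <- stats::var(est) * n
  expect_equal(mean(ups1) / emp, 1, tolerance = 0.15)
  # centered at the truth within Monte Carlo error
  expect_lt(abs(mean(est) - rho_true), 3 * stats::sd(est) / sqrt(R))
})
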