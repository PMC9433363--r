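test_that("the full-model statistic is a plain weighted quadratic form", {
  p <- pipeline_state()
  fit <- p$fits$M4
  n <- p$design$n
  Tf <- t_full(p$pf$rho, fit$sigma_hat, p$weight$V, n)
  e <- p$pf$rho - fit$sigma_hat
  expect_equal(Tf, n * as.numeric(t(e) %*% p$weight$V %*% e))
  expect_gte(Tf, 0)
  expect_equal(t_full(fit$sigma_hat, fit$sigma_hat, p$weight$V, n), 0)
})

test_that("the averaged statistic reduces to the full statistic at a point mass", {
  p <- pipeline_state()
  n <- p$design$n
  fm_full <- fma_combine(p$fits, c(0, 0, 0, 1), p$asym, p$delta)
  Ta <- t_fma(p$pf$rho, fm_full, study$spec, p$weight$V, n)
  Tf <- t_full(p$pf$rho, p$fits$M4$sigma_hat, p$weight$V, n)
  expect_equal(Ta, Tf, tolerance = 1e-8)
  # direct recomputation of the adjusted quadratic form
  w <- c(0.4, 0.1, 0.2, 0.3)
  fm <- fma_combine(p$fits, w, p$asym, p$delta)
  Tm <- t_fma(p$pf$rho, fm, study$spec, p$weight$V, n)
  sb <- model_implied_correlation(study$spec, fm$mu_bar)$sigma
  e <- sqrt(n) * (p$pf$rho - sb) + as.vector(p$asym$Dsig %*% fm$u)
  expect_equal(Tm, as.numeric(t(e) %*% p$weight$V %*% e))
  # a focus narrower than beta is refused
  fm_bad <- fm
  fm_bad$mu_bar <- fm$mu_bar[1:3]
  expect_error(t_fma(p$pf$rho, fm_bad, study$spec, p$weight$V, n), "focus")
})

test_that("the scaling matrix calibrates fractional degrees of freedom", {
  p <- pipeline_state()
  xi <- xi_fma(p$asym)
  r <- length(p$pf$rho) - study$spec$n_par
  expect_equal(r, 48)   # 66 unique correlations minus 18 free parameters
  tr1 <- sum(diag(xi)); tr2 <- sum(xi * t(xi))
  expect_gt(tr1, 0)
  # Cauchy-Schwarz: adjusted df never exceed r, ratio at least 1
  expect_lte(tr1^2 / tr2, r + 1e-8)
  expect_gte(tr1^2 / tr2, 1)
  # product of two PSD matrices: eigenvalues are real and nonnegative
  ev <- eigen(xi, only.values = TRUE)$values
  expect_lt(max(abs(Im(ev))), 1e-8)
  expect_gt(min(Re(ev)), -1e-6 * max(Re(ev)))
  # identity scaling leaves the statistic untouched
  s <- scaled_statistics(10, diag(48), 48)
  expect_equal(s$T_scaled, 10)
  expect_equal(s$T_adjusted, 10)
  expect_equal(s$df_adjusted, 48)
  expect_equal(s$p_scaled, pchisq(10, 48, lower.tail = FALSE))
})

test_that("robust RMSEA floors at zero and vanishes for a perfect fit", {
  expect_equal(robust_rmsea(10, 20, 48, 600), 0)
  expect_equal(robust_rmsea(0, 0.5, 48, 600), 0)
  expect_gt(robust_rmsea(100, 48, 48, 600), 0)
  expect_error(robust_rmsea(10, 10, 0, 600), "saturated")
})

test_that("sequential selection walks the nested family in order", {
  expect_equal(sequential_model_selection(c(0.03, 0.1, 0.1, 0.1)), 1)
  expect_equal(sequential_model_selection(c(0.08, 0.06, 0.04, 0.02)), 3)
  expect_equal(sequential_model_selection(c(0.08, 0.07, 0.06, 0.055)), 4)
  # inadmissible candidates are skipped
  expect_equal(sequential_model_selection(c(NA, 0.06, 0.04, 0.02)), 3)
  expect_equal(sequential_model_selection(rep(NA_real_, 4)), NA_integer_)
  expect_error(sequential_model_selection(numeric(0)), "empty")
})

test_that("a well-fitting narrow truth keeps the narrow model selected", {
  # at zeta = 0 the narrow model is true: robust RMSEA should accept it
  d <- simulation_design(zeta = 0, n = 600, n_replications = 1,
                         base_seed = 515)
  rmseas <- numeric(8)
  for (r in 1:8) {
    dat <- generate_dataset(d, r, narrow_pop)
    pf <- polychoric(dat, upsilon = TRUE)
    w <- build_weight_matrix(pf$upsilon, "DWLS")
    fit <- fit_candidate(pf$rho, w, study$spec, study$cset$models[[1]], d$n)
    Ts <- t_full(pf$rho, fit$sigma_hat, w$V, d$n)
    xs <- sum(diag(semfma:::xi_single(fit, study$spec, w$V, pf$upsilon)))
    rmseas[r] <- robust_rmsea(Ts, xs, length(pf$rho) - length(fit$free), d$n)
  }
  expect_lte(median(rmseas), 0.05)
})
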