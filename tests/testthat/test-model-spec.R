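test_that("model-implied matrix is a correlation matrix with the published structure", {
  spec <- study$spec
  beta <- narrow_pop$beta
  mic <- model_implied_correlation(spec, beta)
  expect_equal(diag(mic$Sigma), setNames(rep(1, 12), spec$var_names))
  # covariance algebra on the population matrices: 1.0 * 0.95 * 0.7
  expect_equal(unname(mic$Sigma["x1", "x2"]), 0.665, tolerance = 1e-12)
  expect_true(isSymmetric(mic$Sigma))
  expect_false(mic$heywood)
  # unit diagonal holds across candidates and perturbed parameter values
  set.seed(4)
  for (r in 1:5) {
    b <- random_admissible_beta()
    for (cand in study$cset$models) {
      free <- semfma:::candidate_free_indices(spec, cand)
      bf <- restrict_to_candidate(spec, cand, b[free])
      expect_equal(max(abs(diag(model_implied_correlation(spec, bf)$Sigma) - 1)), 0)
    }
  }
})

test_that("zero loadings give an identity correlation matrix", {
  lx <- rbind(c("a1", 0), c("a2", 0), c(0, "a3"), c(0, "a4"))
  ly <- rbind(c("c1"), c("c2"))
  spec <- sem_model_spec(lx, ly, b = matrix("0", 1, 1), gamma = rbind(c("g1", "g2")),
                         phi = rbind(c("p1", 0), c(0, "p2")), psi = rbind("ps"),
                         gamma_params = "g2")
  beta <- setNames(numeric(spec$n_par), spec$labels)
  beta[c("p1", "p2", "ps")] <- 0.5
  mic <- model_implied_correlation(spec, beta)
  expect_equal(mic$Sigma, diag(6), ignore_attr = TRUE)
})

test_that("Monte Carlo latent responses reproduce the model-implied correlations", {
  set.seed(20260901)
  n <- 1e6
  S <- narrow_pop$Sigma
  z <- matrix(rnorm(n * 12), n, 12) %*% chol(S)
  expect_lt(max(abs(cor(z) - S)), 0.005)
})

test_that("analytic Jacobian matches central finite differences", {
  spec <- study$spec
  set.seed(7)
  for (r in 1:20) {
    beta <- random_admissible_beta()
    J <- sigma_jacobian(spec, beta)
    Jn <- sigma_jacobian(spec, beta, method = "numeric")
    expect_lt(max(abs(J - Jn)), 1e-5)
  }
})

test_that("Jacobian entries follow the bilinear structure", {
  spec <- study$spec
  J <- sigma_jacobian(spec, narrow_pop$beta)
  rn <- semfma:::lower_vec_names(spec$var_names)
  # d corr(x1, x2) / d lambda_x2 = lambda_x1 * phi_11 = 0.7
  expect_equal(unname(J[match("x2:x1", rn), "lx2"]), 0.7, tolerance = 1e-12)
  # structural zeros: a y-side residual variance never enters an x-x entry
  expect_equal(unname(J[match("x2:x1", rn), "psi1"]), 0)
  expect_equal(unname(J[match("x3:x2", rn), "ly5"]), 0)
})

test_that("candidate embedding fills excluded gamma components with their nulls", {
  spec <- study$spec
  beta <- narrow_pop$beta
  full <- study$cset$models[[4]]
  narrow <- study$cset$models[[1]]
  m2 <- study$cset$models[[2]]
  # full model: identity embedding
  expect_equal(restrict_to_candidate(spec, full, beta), beta)
  # narrow model: gamma forced to the null regardless of input
  bn <- restrict_to_candidate(spec, narrow, beta[spec$theta_idx])
  expect_equal(unname(bn[spec$gamma_idx]), unname(spec$gamma_null))
  expect_equal(bn[spec$theta_idx], beta[spec$theta_idx])
  # Model 2 frees g12 only: b21 and g21 are pinned at zero
  free2 <- semfma:::candidate_free_indices(spec, m2)
  b2 <- restrict_to_candidate(spec, m2, narrow_pop$beta[free2] + 0.1)
  expect_equal(unname(b2["b21"]), 0)
  expect_equal(unname(b2["g21"]), 0)
  expect_error(restrict_to_candidate(spec, m2, 1:3), "length")
})

test_that("selection matrices are proper and the set is nested", {
  cset <- study$cset
  expect_true(cset$models[[1]]$is_narrow)
  expect_true(cset$models[[4]]$is_full)
  expect_equal(nrow(cset$models[[1]]$pi), 0)
  expect_equal(cset$models[[4]]$pi, diag(3), ignore_attr = TRUE)
  for (m in cset$models) {
    if (nrow(m$pi) == 0) next
    expect_true(all(rowSums(m$pi) == 1))
    expect_equal(nrow(unique(m$pi)), nrow(m$pi))
    expect_true(all(m$retain %in% cset$models[[4]]$retain))
  }
  expect_error(candidate_set(study$spec, list(A = "g12", B = c("g12", "g21"))),
               "narrow")
})

test_that("a structural cycle that breaks invertibility is reported", {
  lx <- rbind(c(1, 0), c("a", 0), c(0, 1), c(0, "b"))
  ly <- rbind(c(1, 0), c("c", 0), c(0, 1), c(0, "d"))
  bmat <- rbind(c(0, "b12"), c("b21", 0))
  spec <- sem_model_spec(lx, ly, bmat, gamma = matrix("0", 2, 2),
                         phi = rbind(c("p1", 0), c(0, "p2")),
                         psi = rbind(c("q1", 0), c(0, "q2")),
                         gamma_params = character())
  beta <- setNames(rep(0.5, spec$n_par), spec$labels)
  beta[c("b12", "b21")] <- 1        # (I - B) singular
  expect_error(model_implied_correlation(spec, beta),
               class = "semfma_structural_singularity")
})

test_that("a loading pushing communality above one raises the Heywood flag", {
  beta <- narrow_pop$beta
  beta["lx2"] <- 1.5
  mic <- model_implied_correlation(study$spec, beta)
  expect_true(mic$heywood)
  expect_true(any(mic$error_var < 0))
})
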