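test_that("weight matrices realize the three weighting schemes", {
  p <- pipeline_state()
  ups <- p$pf$upsilon
  m <- nrow(ups)
  expect_equal(build_weight_matrix(ups, "ULS")$V, diag(m))
  dw <- build_weight_matrix(ups, "DWLS")
  expect_equal(dw$V, diag(1 / diag(ups)))
  wl <- build_weight_matrix(ups, "WLS")
  expect_lt(max(abs(wl$V %*% ups - diag(m))), 1e-8)
  # V_half is a proper square root in every scheme
  expect_lt(max(abs(crossprod(wl$V_half) - wl$V)), 1e-8)
  # with identity upsilon all three coincide
  expect_equal(build_weight_matrix(diag(m), "DWLS")$V,
               build_weight_matrix(diag(m), "WLS")$V)
})

test_that("a perfectly reproducible correlation vector is fit exactly", {
  spec <- study$spec
  sig0 <- model_implied_correlation(spec, narrow_pop$beta)$sigma
  w <- uls_fixture(length(sig0))
  # narrow truth lies in every candidate space (gamma = 0)
  for (cand in list(study$cset$models[[1]], study$cset$models[[4]])) {
    fit <- fit_candidate(sig0, w, spec, cand, n = 150)
    expect_true(fit$converged)
    expect_true(fit$admissible)
    expect_lt(fit$F_ls, 1e-12)
    expect_equal(unname(fit$beta_full), unname(narrow_pop$beta),
                 tolerance = 1e-4)
  }
})

test_that("the gradient is stationary at the optimum", {
  p <- pipeline_state()
  fit <- p$fits$M4
  expect_true(fit$converged)
  # numerical gradient of F_LS / n at the solution
  f <- function(b) {
    bf <- restrict_to_candidate(study$spec, fit$candidate, b)
    e <- p$pf$rho - model_implied_correlation(study$spec, bf)$sigma
    sum(e * (p$weight$V %*% e))
  }
  g <- numeric(length(fit$beta_hat))
  for (k in seq_along(g)) {
    up <- fit$beta_hat; up[k] <- up[k] + 1e-6
    dn <- fit$beta_hat; dn[k] <- dn[k] - 1e-6
    g[k] <- (f(up) - f(dn)) / 2e-6
  }
  expect_lt(sqrt(sum(g^2)), 1e-5)
})

test_that("admissibility screens Heywood and non-converged solutions", {
  p <- pipeline_state()
  fit <- p$fits$M4
  expect_true(check_admissibility(fit, study$spec))
  bad <- fit
  bad$error_var[1] <- -0.01             # negative derived error variance
  expect_false(check_admissibility(bad, study$spec))
  bad2 <- fit
  bad2$converged <- FALSE               # non-convergence always disqualifies
  expect_false(check_admissibility(bad2, study$spec))
  bad3 <- fit
  bad3$beta_full["psi1"] <- -0.05       # negative structural residual variance
  expect_false(check_admissibility(bad3, study$spec))
})

test_that("asymptotic quantities satisfy their algebraic identities", {
  p <- pipeline_state()
  a <- p$asym
  # Schur complement identity G J G' = K
  G <- cbind(-a$K %*% a$JtgtJtt, a$K)
  idx <- c(a$theta_idx, a$gamma_idx)
  Jr <- a$J[idx, idx]
  expect_lt(max(abs(G %*% Jr %*% t(G) - a$K)), 1e-8)
  # narrow and full projections
  expect_equal(a$Kup$M1, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_lt(max(abs(a$Kup$M4 - a$K)), 1e-10)
  # var(D) equals the G-sandwich of H
  Hr <- a$H[idx, idx]
  expect_lt(max(abs(G %*% Hr %*% t(G) - a$var_D)), 1e-8)
  # focus = beta: W is the stack of Jtt^-1 Jtg over theta rows and -I
  expect_equal(a$W[a$theta_idx, ], unname(a$Jtt_inv %*% a$Jtg),
               ignore_attr = TRUE)
  expect_equal(a$W[a$gamma_idx, ], -diag(3), ignore_attr = TRUE)
  # J and H are symmetric PSD
  for (M in list(a$J, a$H)) {
    expect_true(isSymmetric(M, tol = 1e-8))
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
  }
})

test_that("under WLS the score covariance equals the information", {
  p <- pipeline_state()
  wl <- build_weight_matrix(p$pf$upsilon, "WLS")
  aw <- compute_asymptotics(study$spec, p$fits$M4$beta_full, wl,
                            p$pf$upsilon, study$cset, n = p$design$n)
  expect_lt(max(abs(aw$H - aw$J)), 1e-8 * max(abs(aw$J)))
  # under DWLS they differ
  expect_gt(max(abs(p$asym$H - p$asym$J)), 1e-4)
})
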