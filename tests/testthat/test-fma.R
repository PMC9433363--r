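test_that("the local parameter estimate scales as designed", {
  gn <- study$spec$gamma_null
  expect_equal(unname(estimate_delta(gn, gn, 400)), rep(0, 3))
  g <- gn + c(0.1, -0.2, 0.05)
  expect_equal(estimate_delta(g, gn, 2 * 350),
               sqrt(2) * estimate_delta(g, gn, 350))
})

test_that("the outer-product correction reduces to K in the WLS limit", {
  p <- pipeline_state()
  wl <- build_weight_matrix(p$pf$upsilon, "WLS")
  aw <- compute_asymptotics(study$spec, p$fits$M4$beta_full, wl,
                            p$pf$upsilon, study$cset, n = p$design$n)
  d <- p$delta
  ord <- estimate_delta_outer(d, aw, "ordinal")
  cont <- estimate_delta_outer(d, aw, "continuous")
  expect_lt(max(abs(ord - cont)), 1e-8 * max(1, max(abs(cont))))
  expect_equal(cont, tcrossprod(d) - aw$K, ignore_attr = TRUE)
  expect_true(isSymmetric(estimate_delta_outer(d, p$asym, "ordinal")))
})

test_that("the risk criterion collapses to the continuous form under WLS", {
  p <- pipeline_state()
  wl <- build_weight_matrix(p$pf$upsilon, "WLS")
  aw <- compute_asymptotics(study$spec, p$fits$M4$beta_full, wl,
                            p$pf$upsilon, study$cset, n = p$design$n)
  dd <- estimate_delta_outer(p$delta, aw, "ordinal")
  qo <- build_Q(aw, dd, "ordinal")
  qc <- build_Q(aw, dd, "continuous")
  expect_lt(max(abs(qo$delta1 - qc$delta1)), 1e-8 * max(1, max(abs(qc$delta1))))
  expect_lt(max(abs(qo$delta2 - qc$delta2)), 1e-8 * max(1, max(abs(qc$delta2))))
  expect_lt(max(abs(qo$a - qc$a)), 1e-6)
  expect_lt(max(abs(qo$P - qc$P)), 1e-6)
})

test_that("the quadratic part is symmetric and consistent with vertex values", {
  p <- pipeline_state()
  dd <- estimate_delta_outer(p$delta, p$asym, "ordinal")
  q <- build_Q(p$asym, dd, "ordinal")
  expect_lt(max(abs(q$P - t(q$P))), 1e-10)
  for (s in 1:4) {
    e <- numeric(4); e[s] <- 1
    expect_equal(eval_Q(q, e) - q$a[[s]], 0.5 * q$P[s, s], tolerance = 1e-10)
  }
})

test_that("the simplex minimizer beats an exhaustive grid", {
  p <- pipeline_state()
  dd <- estimate_delta_outer(p$delta, p$asym, "ordinal")
  q <- build_Q(p$asym, dd, "ordinal")
  w <- minimize_weights(q)
  expect_equal(sum(w), 1, tolerance = 1e-8)
  expect_true(all(w >= -1e-10))
  # exhaustive grid over the 4-simplex at step 0.01
  step <- 0.01
  best <- Inf
  for (i in seq(0, 1, step)) for (j in seq(0, 1 - i, step))
    for (k in seq(0, 1 - i - j, step)) {
      val <- eval_Q(q, c(i, j, k, 1 - i - j - k))
      if (val < best) best <- val
    }
  expect_lt(eval_Q(q, w) - best, 1e-6)
  # every vertex is at least as costly as the minimizer
  for (s in 1:4) {
    e <- numeric(4); e[s] <- 1
    expect_lte(eval_Q(q, w), eval_Q(q, e) + 1e-10)
  }
  # duplicating a candidate cannot change the attainable minimum
  q2 <- structure(list(a = c(q$a, q$a[2]),
                       P = rbind(cbind(q$P, q$P[, 2]), c(q$P[2, ], q$P[2, 2]))),
                  class = "q_problem")
  w2 <- minimize_weights(q2)
  expect_equal(eval_Q(q2, w2), eval_Q(q, w), tolerance = 1e-6)
  # single candidate: all weight on it
  q1 <- structure(list(a = q$a[1], P = q$P[1, 1, drop = FALSE]),
                  class = "q_problem")
  expect_equal(unname(minimize_weights(q1)), 1)
})

test_that("degenerate point-mass weights recover the corner cases", {
  p <- pipeline_state()
  fits <- p$fits
  # all weight on the full model
  fm_full <- fma_combine(fits, c(0, 0, 0, 1), p$asym, p$delta)
  expect_equal(fm_full$mu_bar, fits$M4$mu_hat)
  expect_equal(fm_full$delta_tilde, unname(p$delta), tolerance = 1e-10)
  expect_equal(fm_full$u, rep(0, study$spec$n_par), tolerance = 1e-10)
  # all weight on the narrow model
  fm_nar <- fma_combine(fits, c(1, 0, 0, 0), p$asym, p$delta)
  expect_equal(fm_nar$delta_tilde, rep(0, 3))
  expect_equal(fm_nar$u, as.vector(p$asym$W %*% p$delta))
  # averaged estimate lies within the candidate envelope
  w <- c(0.2, 0.3, 0.4, 0.1)
  fm <- fma_combine(fits, w, p$asym, p$delta)
  mu_mat <- vapply(fits, `[[`, numeric(study$spec$n_par), "mu_hat")
  expect_true(all(fm$mu_bar >= apply(mu_mat, 1, min) - 1e-12))
  expect_true(all(fm$mu_bar <= apply(mu_mat, 1, max) + 1e-12))
  # averaging is refused when the narrow model is inadmissible
  broken <- fits
  broken$M1$admissible <- FALSE
  expect_error(fma_combine(broken, w, p$asym, p$delta),
               class = "semfma_fma_inadmissible")
})
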