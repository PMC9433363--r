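#' Estimate the local parameter from the full model
#'
#' \eqn{\hat\delta = \sqrt{n}(\hat\gamma_{full} - \gamma_0)}: unbiased for
#' the local parameter under the drifting-truth framework.
#'
#' @param gamma_full_hat full-model estimate of \eqn{\gamma}.
#' @param gamma_null null values \eqn{\gamma_0}.
#' @param n sample size.
#' @return numeric vector \eqn{\hat\delta}.
#' @export
estimate_delta <- function(gamma_full_hat, gamma_null, n) {
  sqrt(n) * (gamma_full_hat - gamma_null)
}

#' Bias-corrected estimate of the outer product of the local parameter
#'
#' \eqn{\hat\delta\hat\delta^T} overestimates \eqn{\delta\delta^T} by the
#' sampling covariance of \eqn{\hat\delta}; for ordinal data that
#' covariance is \eqn{G H G^T} (which reduces to \eqn{K} when
#' \eqn{H = J}, the continuous-data correction).  No positive-semidefinite
#' truncation is applied: the raw correction is what keeps the estimator
#' unbiased.
#'
#' @param delta_hat \eqn{\hat\delta}.
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @param correction \code{"ordinal"} (subtract \eqn{GHG^T}),
#'   \code{"continuous"} (subtract \eqn{K}) or \code{"none"}.
#' @return symmetric matrix estimate of \eqn{\delta\delta^T}.
#' @export
estimate_delta_outer <- function(delta_hat, asym,
                                 correction = c("ordinal", "continuous", "none")) {
  correction <- match.arg(correction)
  raw <- tcrossprod(delta_hat)
  adj <- switch(correction,
                ordinal = G_sandwich(asym, asym$Htt, asym$Htg, asym$Hgg),
                continuous = asym$K,
                none = 0)
  symmetrize(raw - adj)
}

#' Assemble the quadratic risk criterion over model weights
#'
#' The asymptotic mean squared error of the averaged focus estimator, as a
#' function of the weights, is \eqn{Q(c) = \sum_s c_s a_s + \tfrac12
#' \sum_{s,t} c_s c_t P_{st}} with \eqn{a_s =
#' \mathrm{tr}\{\Delta_1 K^{(s)} W^T\}} and \eqn{P_{st} =
#' \mathrm{tr}\{W K^{(s)} \Delta_2 K^{(t)} W^T\}}.  With ordinal data the
#' score covariance \eqn{H} differs from \eqn{J} under ULS/DWLS and
#' \eqn{\Delta_1,\Delta_2} carry correction terms in \eqn{H}; under WLS
#' (or with \code{variant = "continuous"}) they collapse to the
#' continuous-data forms \eqn{-W\delta\delta^T K^{-1}} and
#' \eqn{K^{-1} + K^{-1}\delta\delta^T K^{-1}}.
#'
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @param delta_outer estimate of \eqn{\delta\delta^T}.
#' @param variant \code{"ordinal"} or \code{"continuous"} (the latter
#'   treats \eqn{\mathrm{cov}(M, D^T) = 0}).
#' @return object of class \code{q_problem} with the linear part \code{a},
#'   quadratic part \code{P}, and \code{delta1}, \code{delta2}.
#' @export
build_Q <- function(asym, delta_outer, variant = c("ordinal", "continuous")) {
  variant <- match.arg(variant)
  W <- asym$W; K <- asym$K; Kinv <- asym$Kinv
  if (variant == "ordinal") {
    # Delta_1 = (dmu/dtheta') Jtt^-1 (Htt Jtt^-1 Jtg - Htg) - W dd' K^-1
    d1 <- asym$mu_jac$dtheta %*% asym$Jtt_inv %*%
      (asym$Htt %*% asym$Jtt_inv %*% asym$Jtg - asym$Htg) -
      W %*% delta_outer %*% Kinv
    # Delta_2 = K^-1 var(D) K^-1 + K^-1 dd' K^-1  (symmetrized bracket form)
    d2 <- Kinv %*% asym$var_D %*% Kinv + Kinv %*% delta_outer %*% Kinv
  } else {
    d1 <- -W %*% delta_outer %*% Kinv
    d2 <- Kinv + Kinv %*% delta_outer %*% Kinv
  }
  d2 <- symmetrize(d2)
  S <- length(asym$Kup)
  a <- vapply(asym$Kup, function(Kup_s) sum(diag(d1 %*% Kup_s %*% t(W))), 0)
  P <- matrix(0, S, S, dimnames = list(names(asym$Kup), names(asym$Kup)))
  WK <- lapply(asym$Kup, function(Kup_s) W %*% Kup_s)   # W K^(s)
  for (s in seq_len(S))
    for (t in s:S) {
      P[s, t] <- sum((WK[[s]] %*% d2) * WK[[t]])
      P[t, s] <- P[s, t]
    }
  structure(list(a = a, P = P, delta1 = d1, delta2 = d2, variant = variant),
            class = "q_problem")
}

#' Evaluate the risk criterion at a weight vector
#' @param q a \code{\link{build_Q}} result.
#' @param c_vec weight vector on the unit simplex.
#' @return scalar \eqn{Q(c)}.
#' @export
eval_Q <- function(q, c_vec) {
  sum(q$a * c_vec) + 0.5 * sum(c_vec * (q$P %*% c_vec))
}

#' Minimize the risk criterion over the unit simplex
#'
#' Quadratic program \eqn{\min_c Q(c)} subject to \eqn{\sum_s c_s = 1},
#' \eqn{c_s \ge 0}.  The quadratic part is symmetrized and its eigenvalues
#' floored at zero before solving; a projected-gradient fallback (fixed
#' step, tolerance \code{1e-10} on the objective) covers solver failures.
#'
#' @param q a \code{\link{build_Q}} result.
#' @return numeric weight vector summing to one.
#' @export
minimize_weights <- function(q) {
  S <- length(q$a)
  if (S == 1L) return(setNames(1, names(q$a)))
  P <- symmetrize(q$P)
  es <- eigen(P, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  P <- es$vectors %*% (ev * t(es$vectors))
  scale <- max(ev, 1)
  ridge <- 1e-9 * scale
  sol <- tryCatch({
    Amat <- cbind(rep(1, S), diag(S))
    qp <- quadprog::solve.QP(Dmat = P + ridge * diag(S), dvec = -q$a,
                             Amat = Amat, bvec = c(1, rep(0, S)), meq = 1)
    qp$solution
  }, error = function(e) NULL)
  if (is.null(sol)) sol <- projected_gradient_simplex(P, q$a)
  sol <- pmax(sol, 0)
  sol <- sol / sum(sol)
  setNames(sol, names(q$a))
}

projected_gradient_simplex <- function(P, a, maxit = 5000, tol = 1e-10) {
  S <- length(a)
  c_vec <- rep(1 / S, S)
  L <- max(eigen(P, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  obj <- function(x) sum(a * x) + 0.5 * sum(x * (P %*% x))
  f0 <- obj(c_vec)
  for (i in seq_len(maxit)) {
    g <- a + P %*% c_vec
    c_new <- project_simplex(c_vec - as.vector(g) / L)
    f1 <- obj(c_new)
    if (abs(f0 - f1) < tol) { c_vec <- c_new; break }
    c_vec <- c_new; f0 <- f1
  }
  c_vec
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

#' Combine candidate fits into the model-averaged estimate
#'
#' Forms \eqn{\bar\mu(\hat c) = \sum_s \hat c_s \hat\mu_s}, the shrunken
#' local parameter \eqn{\tilde\delta = \sum_s \hat c_s \hat K^{(s)}
#' \hat K^{-1} \hat\delta} and the interval adjustment
#' \eqn{\hat u = \hat W(\hat\delta - \tilde\delta)}.
#'
#' @param fits list of \code{ls_fit} objects (all candidates used in the
#'   weights, same order as the weight vector).
#' @param weights simplex weights from \code{\link{minimize_weights}}.
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @param delta_hat \eqn{\hat\delta}.
#' @return object of class \code{fma_result} with \code{weights},
#'   \code{mu_bar}, \code{delta_tilde}, \code{u}.
#' @export
fma_combine <- function(fits, weights, asym, delta_hat) {
  ids <- vapply(fits, `[[`, "", "id")
  stopifnot(length(weights) == length(fits))
  narrow <- vapply(fits, function(f) f$candidate$is_narrow, TRUE)
  full <- vapply(fits, function(f) f$candidate$is_full, TRUE)
  if (!any(narrow) || !any(full))
    stop_semfma("averaging requires both the narrow and the full model",
                "semfma_fma_inadmissible")
  if (!fits[[which(narrow)]]$admissible || !fits[[which(full)]]$admissible)
    stop_semfma("narrow or full model inadmissible: averaging not defined",
                "semfma_fma_inadmissible")
  mu_mat <- vapply(fits, `[[`, numeric(length(fits[[1]]$mu_hat)), "mu_hat")
  mu_bar <- as.vector(mu_mat %*% weights)
  names(mu_bar) <- names(fits[[1]]$mu_hat)
  shrink <- Reduce(`+`, Map(function(w, id) w * asym$Kup[[id]],
                            weights, ids))
  delta_tilde <- as.vector(shrink %*% asym$Kinv %*% delta_hat)
  u <- as.vector(asym$W %*% (delta_hat - delta_tilde))
  structure(list(weights = setNames(weights, ids), mu_bar = mu_bar,
                 delta_hat = delta_hat, delta_tilde = delta_tilde, u = u,
                 asym = asym),
            class = "fma_result")
}

#' @export
print.fma_result <- function(x, ...) {
  cat("Frequentist model averaging result\n  weights:\n")
  for (i in seq_along(x$weights))
    cat(sprintf("    %-8s %.4f\n", names(x$weights)[i], x$weights[i]))
  invisible(x)
}
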