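#' Build a least-squares weight matrix from the polychoric covariance
#'
#' @param upsilon estimated asymptotic covariance \eqn{\hat\Upsilon} of the
#'   stacked polychoric correlations (may be NULL for ULS).
#' @param method \code{"ULS"} (identity), \code{"DWLS"} (inverse of the
#'   diagonal of \eqn{\hat\Upsilon}) or \code{"WLS"}
#'   (\eqn{\hat\Upsilon^{-1}}).
#' @return object of class \code{weight_spec} with elements \code{method},
#'   \code{V} and \code{V_half} (a square root used by the least-squares
#'   optimizer).
#' @export
build_weight_matrix <- function(upsilon, method = c("DWLS", "ULS", "WLS")) {
  method <- match.arg(method)
  if (method == "ULS") {
    m <- if (is.null(upsilon)) NULL else nrow(upsilon)
    if (is.null(m)) stop("ULS without upsilon needs the problem size; pass upsilon")
    V <- diag(m); Vh <- diag(m)
  } else if (method == "DWLS") {
    d <- diag(upsilon)
    if (any(d <= 0)) stop("upsilon has non-positive diagonal entries")
    V <- diag(1 / d); Vh <- diag(1 / sqrt(d))
  } else {
    ch <- tryCatch(chol(symmetrize(upsilon)), error = function(e)
      stop("upsilon is singular; WLS is not available, consider DWLS"))
    V <- chol2inv(ch)
    Vh <- backsolve(ch, diag(nrow(upsilon)), transpose = TRUE)
  }
  structure(list(method = method, V = V, V_half = Vh), class = "weight_spec")
}

# ULS weights without an upsilon estimate
uls_weights <- function(m) {
  structure(list(method = "ULS", V = diag(m), V_half = diag(m)),
            class = "weight_spec")
}

default_start <- function(spec, free = seq_len(spec$n_par)) {
  beta <- numeric(spec$n_par)
  for (nm in names(spec$mats)) {
    m <- spec$mats[[nm]]
    sel <- m$par > 0L
    if (!any(sel)) next
    init <- if (nm %in% c("lx", "ly")) 1 else 0
    beta[m$par[sel]] <- init
  }
  # variances start away from zero
  for (nm in c("phi", "psi")) {
    m <- spec$mats[[nm]]
    dsel <- diag(m$par)
    beta[dsel[dsel > 0L]] <- 0.5
  }
  beta[free]
}

#' Fit one candidate model by weighted least squares
#'
#' Minimizes \eqn{F_{LS}(\beta) = n(\hat\rho - \sigma(\beta))^T V
#' (\hat\rho - \sigma(\beta))} over the candidate's free parameters by
#' Levenberg-Marquardt with the analytic Jacobian, followed by
#' Gauss-Newton polishing.  Convergence requires the gradient norm of
#' \eqn{F_{LS}/n} to fall below \code{1e-6}.
#'
#' @param rho_hat stacked polychoric correlations (canonical order).
#' @param weight a \code{\link{build_weight_matrix}} result.
#' @param spec a \code{\link{sem_model_spec}}.
#' @param candidate a \code{\link{candidate_model}}.
#' @param n sample size.
#' @param start optional start vector in the candidate's space.
#' @return object of class \code{ls_fit}: \code{beta_hat} (candidate
#'   space), \code{beta_full} (embedded via \eqn{\gamma_0} fill),
#'   \code{sigma_hat}, \code{F_ls}, \code{converged}, \code{admissible},
#'   \code{grad_norm}, \code{mu_hat}.
#' @export
fit_candidate <- function(rho_hat, weight, spec, candidate, n, start = NULL) {
  free <- candidate_free_indices(spec, candidate)
  if (is.null(start)) start <- default_start(spec, free)
  Vh <- weight$V_half
  V <- weight$V

  resid_fn <- function(b) {
    bf <- restrict_to_candidate(spec, candidate, b)
    sig <- tryCatch(model_implied_correlation(spec, bf)$sigma,
                    semfma_structural_singularity = function(e) NULL)
    if (is.null(sig)) return(rep(1e6, length(rho_hat)))
    Vh %*% (rho_hat - sig)
  }
  jac_fn <- function(b) {
    bf <- restrict_to_candidate(spec, candidate, b)
    J <- tryCatch(sigma_jacobian(spec, bf),
                  semfma_structural_singularity = function(e) NULL)
    if (is.null(J)) return(matrix(0, length(rho_hat), length(b)))
    -(Vh %*% J[, free, drop = FALSE])
  }

  lm <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
    error = function(e) NULL)
  beta <- if (!is.null(lm)) lm$par else start

  # Gauss-Newton polish with step halving (quadratic convergence near the
  # optimum; pushes the gradient below the convergence tolerance)
  obj <- function(b) { r <- resid_fn(b); sum(r * r) }
  fb <- obj(beta)
  for (it in 1:25) {
    bf <- restrict_to_candidate(spec, candidate, beta)
    sig <- tryCatch(model_implied_correlation(spec, bf)$sigma,
                    semfma_structural_singularity = function(e) NULL)
    if (is.null(sig)) break
    J <- sigma_jacobian(spec, bf)[, free, drop = FALSE]
    res <- rho_hat - sig
    g <- -2 * crossprod(J, V %*% res)
    if (sqrt(sum(g^2)) < 1e-8) break
    JVJ <- crossprod(J, V %*% J)
    step <- tryCatch(solve(JVJ + 1e-10 * diag(ncol(J)),
                           crossprod(J, V %*% res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- beta + lam * as.vector(step)
      fc <- obj(cand)
      if (fc <= fb || lam < 1e-4) break
      lam <- lam / 2
    }
    if (fc > fb) break
    beta <- cand; fb <- fc
  }

  bf <- restrict_to_candidate(spec, candidate, beta)
  mic <- model_implied_correlation(spec, bf)
  res <- rho_hat - mic$sigma
  J <- sigma_jacobian(spec, bf)[, free, drop = FALSE]
  grad_norm <- sqrt(sum((2 * crossprod(J, V %*% res))^2))
  converged <- is.finite(grad_norm) && grad_norm < 1e-6

  fit <- structure(list(
    id = candidate$id, candidate = candidate, free = free,
    beta_hat = setNames(beta, spec$labels[free]),
    beta_full = bf, sigma_hat = mic$sigma, error_var = mic$error_var,
    F_ls = n * sum(res * (V %*% res)), n = n,
    converged = converged, grad_norm = grad_norm,
    mu_hat = bf), class = "ls_fit")
  fit$admissible <- check_admissibility(fit, spec)
  fit
}

#' @export
print.ls_fit <- function(x, ...) {
  cat(sprintf("LS fit of candidate %s: F_LS = %.4f, %s, %s\n", x$id, x$F_ls,
              if (x$converged) "converged" else "NOT converged",
              if (x$admissible) "admissible" else "inadmissible"))
  invisible(x)
}

#' Admissibility of a fitted candidate model
#'
#' A solution is admissible if the optimizer converged and all model
#' covariance matrices are proper: the exogenous factor covariance and the
#' structural residual covariance are positive semidefinite and the
#' derived indicator error variances are nonnegative (no Heywood case).
#'
#' @param fit an \code{\link{fit_candidate}} result.
#' @param spec the model specification.
#' @return logical flag.
#' @export
check_admissibility <- function(fit, spec) {
  if (!isTRUE(fit$converged)) return(FALSE)
  mt <- realize_matrices(spec, fit$beta_full)
  is_psd(mt$phi, tol = 1e-8) && is_psd(mt$psi, tol = 1e-8) &&
    all(diag(mt$phi) >= -1e-10) && all(diag(mt$psi) >= -1e-10) &&
    all(fit$error_var >= -1e-10)
}

#' Fit every candidate in a set, warm-starting larger models
#'
#' Candidates are fitted in the given (narrow to full) order; each fit
#' starts from the embedded solution of the previous candidate.
#'
#' @inheritParams fit_candidate
#' @param cset a \code{\link{candidate_set}}.
#' @return list of \code{ls_fit} objects, named by candidate id.
#' @export
fit_candidate_set <- function(rho_hat, weight, spec, cset, n) {
  fits <- vector("list", length(cset$models))
  names(fits) <- vapply(cset$models, `[[`, "", "id")
  prev <- NULL
  for (i in seq_along(cset$models)) {
    cand <- cset$models[[i]]
    free <- candidate_free_indices(spec, cand)
    start <- if (is.null(prev)) NULL else {
      b <- prev$beta_full
      b[spec$gamma_idx] <- ifelse(spec$labels[spec$gamma_idx] %in% cand$retain,
                                  b[spec$gamma_idx], spec$gamma_null)
      b[free]
    }
    fits[[i]] <- fit_candidate(rho_hat, weight, spec, cand, n, start = start)
    if (fits[[i]]$converged) prev <- fits[[i]]
  }
  fits
}

#' Asymptotic building blocks evaluated at the full-model fit
#'
#' Assembles, at the full-model estimate, the Gauss-Newton information
#' \eqn{J = (\partial\sigma/\partial\beta^T)^T V
#' (\partial\sigma/\partial\beta^T)}, the score covariance
#' \eqn{H = (\partial\sigma/\partial\beta^T)^T V \Upsilon V
#' (\partial\sigma/\partial\beta^T)}, the Schur-complement inverse
#' \eqn{K}, the per-candidate \eqn{K_s} and \eqn{K^{(s)}}, the focus
#' sensitivity \eqn{W} and the local-parameter map \eqn{G}.  Under WLS
#' (\eqn{V = \Upsilon^{-1}}) \eqn{H = J} and the machinery reduces to its
#' continuous-data form.
#'
#' @param spec model specification.
#' @param beta_full_hat full-model parameter estimate (full space).
#' @param weight a \code{weight_spec}.
#' @param upsilon estimated \eqn{\hat\Upsilon}.
#' @param cset candidate set (for \eqn{K_s}, \eqn{K^{(s)}}).
#' @param mu_jac optional list with \code{dtheta} and \code{dgamma}, the
#'   Jacobians of the focus parameter with respect to \eqn{\theta} and
#'   \eqn{\gamma}; defaults to the focus being the whole of \eqn{\beta}.
#' @param n sample size carried along for inference.
#' @return object of class \code{fma_asymptotics}.
#' @export
compute_asymptotics <- function(spec, beta_full_hat, weight, upsilon, cset,
                                mu_jac = NULL, n = NULL) {
  D <- sigma_jacobian(spec, beta_full_hat)
  V <- weight$V
  VD <- V %*% D
  J <- crossprod(D, VD)
  H <- crossprod(VD, upsilon %*% VD)
  ti <- spec$theta_idx; gi <- spec$gamma_idx
  Jtt <- J[ti, ti, drop = FALSE]; Jtg <- J[ti, gi, drop = FALSE]
  Jgg <- J[gi, gi, drop = FALSE]
  Htt <- H[ti, ti, drop = FALSE]; Htg <- H[ti, gi, drop = FALSE]
  Hgg <- H[gi, gi, drop = FALSE]
  Jtt_inv <- tryCatch(solve(Jtt), error = function(e)
    stop_semfma("J_theta_theta is singular: model not identified",
                "semfma_identification"))
  Kinv <- Jgg - crossprod(Jtg, Jtt_inv %*% Jtg)
  K <- solve(Kinv)

  q <- length(gi)
  Ks <- lapply(cset$models, function(m) {
    if (m$is_narrow) return(matrix(0, 0, 0))
    solve(m$pi %*% Kinv %*% t(m$pi))
  })
  Kup <- lapply(seq_along(cset$models), function(i) {
    m <- cset$models[[i]]
    if (m$is_narrow) return(matrix(0, q, q))
    t(m$pi) %*% Ks[[i]] %*% m$pi
  })
  names(Ks) <- names(Kup) <- vapply(cset$models, `[[`, "", "id")

  if (is.null(mu_jac)) {
    p <- spec$n_par
    Mth <- matrix(0, p, length(ti)); Mth[cbind(ti, seq_along(ti))] <- 1
    Mga <- matrix(0, p, length(gi)); Mga[cbind(gi, seq_along(gi))] <- 1
    mu_jac <- list(dtheta = Mth, dgamma = Mga)
  }
  AJ <- mu_jac$dtheta %*% Jtt_inv                 # (dmu/dtheta') Jtt^-1
  W <- AJ %*% Jtg - mu_jac$dgamma
  # G maps the stacked (M, N) limit to the local-parameter error:
  # var(D) = G H G', and G J G' = K
  JtgtJtt <- crossprod(Jtg, Jtt_inv)              # Jtg' Jtt^-1
  var_D <- K %*% (JtgtJtt %*% Htt %*% t(JtgtJtt) - JtgtJtt %*% Htg -
                    crossprod(Htg, t(JtgtJtt)) + Hgg) %*% K

  structure(list(
    J = J, H = H, Jtt = Jtt, Jtg = Jtg, Jgg = Jgg,
    Htt = Htt, Htg = Htg, Hgg = Hgg,
    Jtt_inv = Jtt_inv, K = K, Kinv = Kinv, Ks = Ks, Kup = Kup,
    W = W, AJ = AJ, var_D = symmetrize(var_D), JtgtJtt = JtgtJtt,
    mu_jac = mu_jac, Dsig = D, V = V, upsilon = upsilon,
    theta_idx = ti, gamma_idx = gi, spec = spec,
    beta_full = beta_full_hat, n = n, method = weight$method
  ), class = "fma_asymptotics")
}

# G H G' for any H-like matrix given its blocks in (theta, gamma) order
G_sandwich <- function(asym, Btt, Btg, Bgg) {
  K <- asym$K; JtgtJtt <- asym$JtgtJtt
  K %*% (JtgtJtt %*% Btt %*% t(JtgtJtt) - JtgtJtt %*% Btg -
           crossprod(Btg, t(JtgtJtt)) + Bgg) %*% K
}
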