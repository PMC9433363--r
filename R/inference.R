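#' Covariance between the protected-score and local-error limits
#'
#' \eqn{\mathrm{cov}(M, D^T) = (H_{\theta\gamma} - H_{\theta\theta}
#' J_{\theta\theta}^{-1} J_{\theta\gamma}) K}; zero under WLS weighting
#' (where \eqn{H = J}) but generally nonzero under ULS or DWLS, which is
#' what makes the ordinal corrections necessary.
#'
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @return matrix of dimension \eqn{\dim\theta \times \dim\gamma}.
#' @export
cov_M_D <- function(asym) {
  (asym$Htg - asym$Htt %*% asym$Jtt_inv %*% asym$Jtg) %*% asym$K
}

#' Covariance of the limiting interval pivot
#'
#' Covariance matrix of \eqn{(\partial\mu_0/\partial\theta^T)
#' J_{\theta\theta}^{-1} M - W D}, whose diagonal gives the squared
#' half-width scale \eqn{\kappa_i^2} of both the model-averaging and the
#' full-model confidence intervals.  The \code{"ordinal"} variant uses the
#' score covariance \eqn{H} and \eqn{\mathrm{cov}(M, D^T)}; the
#' \code{"continuous"} variant is the continuous-data form
#' \eqn{(\partial\mu_0/\partial\theta^T) J_{\theta\theta}^{-1}
#' (\partial\mu_0/\partial\theta^T)^T + W K W^T}.
#'
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @param variant \code{"ordinal"} or \code{"continuous"}.
#' @return symmetric covariance matrix (focus dimension).
#' @export
kappa_covariance <- function(asym, variant = c("ordinal", "continuous")) {
  variant <- match.arg(variant)
  A <- asym$AJ                       # (dmu/dtheta') Jtt^-1
  W <- asym$W
  if (variant == "continuous")
    return(symmetrize(A %*% t(asym$mu_jac$dtheta) + W %*% asym$K %*% t(W)))
  cmd <- cov_M_D(asym)
  symmetrize(A %*% asym$Htt %*% t(A) - A %*% cmd %*% t(W) -
               W %*% t(cmd) %*% t(A) + W %*% asym$var_D %*% t(W))
}

interval_frame <- function(center, mu, u, kappa, n, alpha, method) {
  z <- qnorm(1 - alpha / 2)
  half <- z * kappa / sqrt(n)
  data.frame(parameter = names(mu) %||% paste0("mu", seq_along(mu)),
             estimate = unname(mu), adjustment = unname(u),
             lower = unname(center - half), upper = unname(center + half),
             kappa = unname(kappa), method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Model-averaging confidence interval
#'
#' \eqn{[\bar\mu_i - \hat u_i/\sqrt{n} \pm z_{1-\alpha/2}
#' \hat\kappa_i/\sqrt{n}]}: the averaged estimate is first de-shrunk by
#' the adjustment \eqn{\hat u = \hat W(\hat\delta - \tilde\delta)}, which
#' makes the interval asymptotically equivalent to the full-model one.
#'
#' @param fma a \code{\link{fma_combine}} result.
#' @param kappa_cov covariance from \code{\link{kappa_covariance}}.
#' @param n sample size.
#' @param alpha nominal error level (default 0.05).
#' @param method tag recorded in the output.
#' @return data frame with one row per focus component.
#' @export
fma_interval <- function(fma, kappa_cov, n, alpha = 0.05, method = "FMAord") {
  d <- diag(kappa_cov)
  if (any(d < -1e-8))
    stop("kappa covariance has negative diagonal entries")
  kappa <- sqrt(pmax(d, 0))
  center <- fma$mu_bar - fma$u / sqrt(n)
  interval_frame(center, fma$mu_bar, fma$u, kappa, n, alpha, method)
}

#' Full-model confidence interval
#'
#' Symmetric interval about the full-model estimate with the same
#' \eqn{\hat\kappa} scale as the model-averaging interval.
#'
#' @param mu_full_hat full-model focus estimate.
#' @param kappa_cov covariance from \code{\link{kappa_covariance}}.
#' @inheritParams fma_interval
#' @return data frame with one row per focus component.
#' @export
full_model_interval <- function(mu_full_hat, kappa_cov, n, alpha = 0.05,
                                method = "full") {
  d <- diag(kappa_cov)
  if (any(d < -1e-8))
    stop("kappa covariance has negative diagonal entries")
  kappa <- sqrt(pmax(d, 0))
  interval_frame(mu_full_hat, mu_full_hat, rep(0, length(mu_full_hat)),
                 kappa, n, alpha, method)
}

#' Naive single-candidate confidence interval
#'
#' Sandwich interval of one fitted candidate model, ignoring model
#' selection: \eqn{\hat\beta_s \pm z_{1-\alpha/2}\,\mathrm{se}} with
#' \eqn{\mathrm{se}} from \eqn{J_s^{-1} H_s J_s^{-1}/n} evaluated at the
#' candidate's own estimate.  Used as the post-selection comparator.
#'
#' @param fit an \code{ls_fit}.
#' @param spec model specification.
#' @param weight the \code{weight_spec} used for fitting.
#' @param upsilon estimated \eqn{\hat\Upsilon}.
#' @param alpha nominal error level.
#' @return data frame with one row per free parameter of the candidate.
#' @export
single_model_interval <- function(fit, spec, weight, upsilon, alpha = 0.05) {
  D <- sigma_jacobian(spec, fit$beta_full)[, fit$free, drop = FALSE]
  V <- weight$V
  VD <- V %*% D
  J <- crossprod(D, VD)
  H <- crossprod(VD, upsilon %*% VD)
  Ji <- solve(J)
  avar <- Ji %*% H %*% Ji
  se <- sqrt(pmax(diag(avar), 0) / fit$n)
  z <- qnorm(1 - alpha / 2)
  data.frame(parameter = names(fit$beta_hat), estimate = unname(fit$beta_hat),
             adjustment = 0, lower = unname(fit$beta_hat - z * se),
             upper = unname(fit$beta_hat + z * se), kappa = unname(se * sqrt(fit$n)),
             method = fit$id, row.names = NULL, stringsAsFactors = FALSE)
}
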