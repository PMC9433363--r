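#' Residual-based fit statistic of the full model
#'
#' \eqn{T_{full} = n(\hat\rho - \hat\sigma_{full})^T \hat V
#' (\hat\rho - \hat\sigma_{full})}.
#'
#' @param rho_hat stacked polychoric correlations.
#' @param sigma_hat model-implied correlations at the full-model estimate.
#' @param V least-squares weight matrix.
#' @param n sample size.
#' @return nonnegative scalar.
#' @export
t_full <- function(rho_hat, sigma_hat, V, n) {
  e <- rho_hat - sigma_hat
  n * sum(e * (V %*% e))
}

#' Residual-based fit statistic of the model-averaged solution
#'
#' Quadratic form in \eqn{\sqrt{n}(\hat\rho - \bar\sigma) +
#' (\partial\sigma(\hat\beta_{full})/\partial\beta^T)\,\hat W
#' (\hat\delta - \tilde\delta)} with weight \eqn{\hat V}, where
#' \eqn{\bar\sigma = \sigma(\bar\mu(\hat c))}.  Requires the focus
#' parameter to be the whole of \eqn{\beta} (the averaged estimate must be
#' a point in the parameter space of the correlation structure).
#'
#' @param rho_hat stacked polychoric correlations.
#' @param fma a \code{\link{fma_combine}} result (focus = beta).
#' @param spec model specification.
#' @param V least-squares weight matrix.
#' @param n sample size.
#' @return nonnegative scalar.
#' @export
t_fma <- function(rho_hat, fma, spec, V, n) {
  if (length(fma$mu_bar) != spec$n_par)
    stop("the averaged-model fit statistic requires focus = beta ",
         "(all free correlation-structure parameters)")
  sigma_bar <- model_implied_correlation(spec, fma$mu_bar)$sigma
  e <- sqrt(n) * (rho_hat - sigma_bar) + as.vector(fma$asym$Dsig %*% fma$u)
  sum(e * (V %*% e))
}

#' Scaling matrix of the averaged-model fit statistic
#'
#' \eqn{\Xi_{FMA} = (I - D_\sigma L V)^T V (I - D_\sigma L V)\,\Upsilon}
#' with \eqn{L = ((\partial\mu_0/\partial\theta^T) J_{\theta\theta}^{-1} +
#' W K J_{\theta\gamma}^T J_{\theta\theta}^{-1})
#' (\partial\sigma_0/\partial\theta^T)^T -
#' W K (\partial\sigma_0/\partial\gamma^T)^T}.  Its traces calibrate the
#' mean-scaled and mean-and-variance adjusted chi-square approximations.
#' When the focus is all of \eqn{\beta}, \eqn{L} coincides with
#' \eqn{J_{full}^{-1} D_\sigma^T} and the matrix equals the classical
#' Satorra-Bentler scaling matrix of the full model.
#'
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @return square matrix of the residual dimension.
#' @export
xi_fma <- function(asym) {
  Dth <- asym$Dsig[, asym$theta_idx, drop = FALSE]
  Dga <- asym$Dsig[, asym$gamma_idx, drop = FALSE]
  L <- (asym$AJ + asym$W %*% asym$K %*% asym$JtgtJtt) %*% t(Dth) -
    asym$W %*% asym$K %*% t(Dga)
  M <- diag(nrow(asym$Dsig)) - asym$Dsig %*% L %*% asym$V
  crossprod(M, asym$V %*% M) %*% asym$upsilon
}

# Satorra-Bentler scaling matrix of a single fitted candidate:
# L_s = J_s^-1 D_s', with the candidate's own Jacobian and information
xi_single <- function(fit, spec, V, upsilon) {
  D <- sigma_jacobian(spec, fit$beta_full)[, fit$free, drop = FALSE]
  J <- crossprod(D, V %*% D)
  M <- diag(nrow(D)) - D %*% solve(J, t(D) %*% V)
  crossprod(M, V %*% M) %*% upsilon
}

#' Mean-scaled and mean-and-variance adjusted statistics
#'
#' \eqn{T_m = r\,T/\mathrm{tr}(\Xi)} referred to a chi-square with
#' \eqn{r} degrees of freedom, and \eqn{T_{mv} =
#' \mathrm{tr}(\Xi)\,T/\mathrm{tr}(\Xi^2)} referred to a chi-square with
#' \eqn{[\mathrm{tr}(\Xi)]^2/\mathrm{tr}(\Xi^2)} (possibly fractional)
#' degrees of freedom.
#'
#' @param T_stat a fit statistic (\code{\link{t_full}} or
#'   \code{\link{t_fma}}).
#' @param xi the scaling matrix.
#' @param r residual degrees of freedom: number of unique correlations
#'   minus number of free parameters.
#' @return list with \code{T_scaled}, \code{df_scaled}, \code{p_scaled},
#'   \code{T_adjusted}, \code{df_adjusted}, \code{p_adjusted},
#'   \code{tr_xi}, \code{tr_xi2}.
#' @export
scaled_statistics <- function(T_stat, xi, r) {
  tr1 <- sum(diag(xi))
  tr2 <- sum(xi * t(xi))
  if (tr1 <= 0) stop("tr(Xi) must be positive")
  T_m <- r * T_stat / tr1
  T_mv <- tr1 * T_stat / tr2
  df_mv <- tr1^2 / tr2
  list(T_scaled = T_m, df_scaled = r,
       p_scaled = pchisq(T_m, df = r, lower.tail = FALSE),
       T_adjusted = T_mv, df_adjusted = df_mv,
       p_adjusted = pchisq(T_mv, df = df_mv, lower.tail = FALSE),
       tr_xi = tr1, tr_xi2 = tr2)
}

#' Robust RMSEA of a single fitted candidate
#'
#' Sample-corrected robust root-mean-square error of approximation for a
#' least-squares fit with a non-chi-square reference:
#' \eqn{\hat\varepsilon = \sqrt{\max(0, (T - \mathrm{tr}(\Xi)) / (n r))}},
#' where \eqn{\Xi} is the candidate's own Satorra-Bentler scaling matrix
#' and \eqn{r} its residual degrees of freedom.
#'
#' @param T_stat the candidate's fit statistic.
#' @param tr_xi trace of the candidate's scaling matrix.
#' @param r residual degrees of freedom (> 0).
#' @param n sample size.
#' @return nonnegative scalar.
#' @export
robust_rmsea <- function(T_stat, tr_xi, r, n) {
  if (r <= 0) stop("robust RMSEA undefined for a saturated model (r = 0)")
  sqrt(max(0, (T_stat - tr_xi) / (n * r)))
}

#' Sequential model selection by robust RMSEA
#'
#' Walks the candidate list from the most restrictive to the full model
#' and returns the first whose robust RMSEA does not exceed the cutoff;
#' if none qualifies the full model (last candidate) is chosen.
#'
#' @param rmsea numeric vector of robust RMSEA values, ordered narrow to
#'   full; NA entries (inadmissible candidates) are skipped.
#' @param cutoff acceptance threshold (default 0.05).
#' @return index of the chosen candidate, or NA if every entry is NA.
#' @export
sequential_model_selection <- function(rmsea, cutoff = 0.05) {
  if (length(rmsea) == 0L) stop("empty candidate list")
  ok <- which(!is.na(rmsea))
  if (length(ok) == 0L) return(NA_integer_)
  pass <- ok[rmsea[ok] <= cutoff]
  if (length(pass)) pass[1L] else ok[length(ok)]
}

#' Goodness of fit of the full and averaged models
#'
#' Convenience wrapper computing \eqn{T_{full}}, \eqn{T_{FMA}}, the
#' scaling matrix, and both scaled statistics for each.
#'
#' @param rho_hat stacked polychoric correlations.
#' @param full_fit the full model \code{ls_fit}.
#' @param fma a \code{\link{fma_combine}} result, or NULL for full-model
#'   output only.
#' @param asym a \code{\link{compute_asymptotics}} result.
#' @param n sample size.
#' @return object of class \code{gof_result}.
#' @export
gof_statistics <- function(rho_hat, full_fit, fma, asym, n) {
  spec <- asym$spec
  r <- length(rho_hat) - spec$n_par
  xi <- xi_fma(asym)
  Tf <- t_full(rho_hat, full_fit$sigma_hat, asym$V, n)
  out <- list(r = r, xi = xi,
              full = c(T = Tf, scaled_statistics(Tf, xi, r)))
  if (!is.null(fma)) {
    Ta <- t_fma(rho_hat, fma, spec, asym$V, n)
    out$fma <- c(T = Ta, scaled_statistics(Ta, xi, r))
  }
  structure(out, class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  fmt <- function(z, lab) cat(sprintf(
    "  %-10s T = %8.3f | mean-scaled %8.3f (df %5.1f, p %.4f) | mv-adjusted %8.3f (df %5.1f, p %.4f)\n",
    lab, z$T, z$T_scaled, z$df_scaled, z$p_scaled,
    z$T_adjusted, z$df_adjusted, z$p_adjusted))
  cat("Goodness of fit (r =", x$r, ")\n")
  fmt(x$full, "full")
  if (!is.null(x$fma)) fmt(x$fma, "averaged")
  invisible(x)
}
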