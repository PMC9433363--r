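#' Ordinal dataset container
#'
#' Stores an n-by-p table of integer category codes (1..K per column).
#' Categories that are empty in the sample are collapsed into their lower
#' neighbour and the collapse is flagged, so downstream threshold and
#' correlation estimation always sees consecutive observed codes.
#'
#' @param values integer matrix or data frame of category codes.
#' @param ncat optional vector of category counts per variable; defaults
#'   to the observed maxima.
#' @return object of class \code{ordinal_dataset} with elements
#'   \code{values}, \code{ncat} and \code{collapsed} (logical per column).
#' @export
ordinal_dataset <- function(values, ncat = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (any(is.na(values))) stop("missing codes must be removed first")
  if (any(values < 1L)) stop("category codes must be >= 1")
  p <- ncol(values)
  ncat <- as.integer(ncat %||% apply(values, 2L, max))
  if (any(values > rep(ncat, each = nrow(values))))
    stop("codes exceed the declared category counts")
  collapsed <- logical(p)
  for (j in seq_len(p)) {
    counts <- tabulate(values[, j], ncat[j])
    if (any(counts == 0L)) {
      collapsed[j] <- TRUE
      map <- cumsum(counts > 0L)
      values[, j] <- map[values[, j]]
      ncat[j] <- max(values[, j])
    }
  }
  if (any(ncat < 2L)) stop("every variable needs at least 2 observed categories")
  colnames(values) <- colnames(values) %||% paste0("v", seq_len(p))
  structure(list(values = values, ncat = ncat, collapsed = collapsed,
                 n = nrow(values)),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("Ordinal dataset: %d observations, %d variables (%s categories)\n",
              x$n, ncol(x$values), paste(unique(x$ncat), collapse = "/")))
  if (any(x$collapsed))
    cat("  empty categories collapsed in:",
        paste(colnames(x$values)[x$collapsed], collapse = ", "), "\n")
  invisible(x)
}

#' Read an ordinal data table from CSV
#'
#' @param path file with a header row and integer category codes.
#' @param na character token(s) treated as missing; rows containing any
#'   missing value are dropped (listwise deletion).
#' @return an \code{\link{ordinal_dataset}}.
#' @export
read_ordinal_csv <- function(path, na = c("NA", "")) {
  df <- utils::read.csv(path, na.strings = na)
  keep <- stats::complete.cases(df)
  ordinal_dataset(as.matrix(df[keep, , drop = FALSE]))
}

#' Estimate thresholds of one ordinal variable
#'
#' First step of the two-step estimator: each threshold is the standard
#' normal quantile of the cumulative proportion of the categories below it.
#'
#' @param column integer codes 1..K.
#' @param ncat number of categories.
#' @return numeric vector of K-1 strictly increasing interior thresholds.
#' @export
estimate_thresholds <- function(column, ncat = max(column)) {
  counts <- tabulate(column, ncat)
  if (sum(counts > 0L) < 2L) stop("need at least 2 observed categories")
  if (any(counts == 0L)) stop("collapse empty categories before estimation")
  cum <- cumsum(counts) / length(column)
  qnorm(cum[-ncat])
}

#' Polychoric correlation of one pair at fixed thresholds
#'
#' Second step of the two-step estimator: maximizes the contingency-table
#' log likelihood over the latent correlation, with cell probabilities
#' given by bivariate normal rectangle probabilities between consecutive
#' thresholds.
#'
#' @param col_i,col_j integer codes of the two variables.
#' @param tau_i,tau_j their interior thresholds.
#' @param bound search bound on the correlation (default 0.9995).
#' @return list with \code{rho}, \code{loglik}, \code{boundary} flag
#'   (|rho| > 0.999) and the contingency \code{table}.
#' @export
fit_polychoric_pair <- function(col_i, col_j, tau_i, tau_j, bound = 0.9995) {
  Ki <- length(tau_i) + 1L; Kj <- length(tau_j) + 1L
  tab <- matrix(tabulate((col_j - 1L) * Ki + col_i, Ki * Kj), Ki, Kj)
  if (sum(tab) == 0L) stop("empty contingency table")
  r0 <- suppressWarnings(cor(col_i, col_j))
  if (!is.finite(r0)) r0 <- 0
  rho <- cpp_fit_pair(tab, tau_i, tau_j, -bound, bound, 1e-9, r0)
  list(rho = rho, loglik = cpp_polychoric_loglik(tab, tau_i, tau_j, rho),
       boundary = abs(rho) > 0.999, table = tab)
}

#' Polychoric correlations and their asymptotic covariance
#'
#' Two-step estimation of all pairwise polychoric correlations of an
#' ordinal dataset and, optionally, of the asymptotic covariance matrix
#' \eqn{\Upsilon} of \eqn{\sqrt{n}(\hat\rho - \sigma)}.  \eqn{\Upsilon} is
#' the influence-function (sandwich) estimator of the two-step
#' pseudo-maximum-likelihood procedure, which propagates the sampling
#' error of the estimated thresholds into the correlation scores.
#'
#' @param data an \code{\link{ordinal_dataset}} (or coercible matrix).
#' @param upsilon logical; also estimate \eqn{\hat\Upsilon}.
#' @return object of class \code{polychoric_fit}: \code{rho} (stacked
#'   unique correlations, canonical column-major lower-triangle order),
#'   \code{rho_matrix}, \code{thresholds} (list), \code{upsilon} (or NULL),
#'   \code{n}, \code{boundary} flags.
#' @export
polychoric <- function(data, upsilon = TRUE) {
  if (!inherits(data, "ordinal_dataset")) data <- ordinal_dataset(data)
  x <- data$values; p <- ncol(x); n <- data$n
  if (p < 2L) stop("need at least two variables")
  tau <- lapply(seq_len(p), function(j) estimate_thresholds(x[, j], data$ncat[j]))
  names(tau) <- colnames(x)

  pairs <- which(lower.tri(diag(p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
  npair <- nrow(pairs)
  rho <- numeric(npair); boundary <- logical(npair)
  tabs <- vector("list", npair)
  for (q in seq_len(npair)) {
    i <- pairs[q, 1L]; j <- pairs[q, 2L]   # i > j; pair (row var i, col var j)
    fit <- fit_polychoric_pair(x[, i], x[, j], tau[[i]], tau[[j]])
    rho[q] <- fit$rho; boundary[q] <- fit$boundary; tabs[[q]] <- fit$table
  }
  names(rho) <- lower_vec_names(colnames(x))

  ups <- NULL
  if (upsilon)
    ups <- estimate_upsilon(data, tau, rho, pairs)

  structure(list(rho = rho, rho_matrix = vec_to_corr(rho, p),
                 thresholds = tau, upsilon = ups, n = n,
                 boundary = boundary, pairs = pairs),
            class = "polychoric_fit")
}

#' @export
print.polychoric_fit <- function(x, ...) {
  cat(sprintf("Polychoric correlations: %d variables, n = %d\n",
              ncol(x$rho_matrix), x$n))
  cat(sprintf("  range of estimates: [%.3f, %.3f]%s\n", min(x$rho), max(x$rho),
              if (any(x$boundary)) "  (boundary estimates present)" else ""))
  if (!is.null(x$upsilon))
    cat("  asymptotic covariance estimated (", nrow(x$upsilon), " x ",
        ncol(x$upsilon), ")\n", sep = "")
  invisible(x)
}

#' Asymptotic covariance of the stacked polychoric correlations
#'
#' Influence-function estimator for the two-step procedure.  For each pair
#' the correlation score is corrected for the estimation error of the
#' thresholds of both variables; \eqn{\hat\Upsilon} is the sample
#' covariance of the stacked per-observation influence contributions,
#' scaled to the \eqn{\sqrt{n}} convention.
#'
#' @param data an \code{\link{ordinal_dataset}}.
#' @param thresholds list of per-variable threshold vectors.
#' @param rho stacked correlations in canonical order.
#' @param pairs optional 2-column index matrix matching \code{rho}.
#' @return symmetric positive semidefinite matrix, one row per pair.
#' @export
estimate_upsilon <- function(data, thresholds, rho, pairs = NULL) {
  x <- data$values; p <- ncol(x); n <- data$n
  if (is.null(pairs)) {
    pairs <- which(lower.tri(diag(p)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
  }
  npair <- nrow(pairs)
  contrib <- matrix(0, n, npair)
  # threshold influence lookup per variable: psi_tau[[j]][u, k]
  psi_tau <- lapply(seq_len(p), function(j) {
    tj <- thresholds[[j]]; K <- length(tj) + 1L
    Fj <- pnorm(tj)
    out <- matrix(0, K, K - 1L)
    for (k in seq_len(K - 1L))
      out[, k] <- ((seq_len(K) <= k) - Fj[k]) / dnorm(tj[k])
    out
  })
  for (q in seq_len(npair)) {
    a <- pairs[q, 1L]; b <- pairs[q, 2L]
    d <- pair_score_pieces(thresholds[[a]], thresholds[[b]], rho[q])
    if (abs(d$H_rho) < 1e-12)
      stop_semfma(paste0("singular information for pair (",
                         colnames(x)[a], ", ", colnames(x)[b], ")"),
                  "semfma_singular_pair")
    # per-cell influence table, then per-observation lookup
    ca <- as.vector(psi_tau[[a]] %*% d$H_ta)   # by row code
    cb <- as.vector(psi_tau[[b]] %*% d$H_tb)   # by column code
    psi_tab <- -(t(t(d$s_tab + ca) + cb)) / d$H_rho
    contrib[, q] <- psi_tab[cbind(x[, a], x[, b])]
  }
  ups <- cov(contrib)
  dimnames(ups) <- list(names(rho), names(rho))
  ups
}

# score and expected-derivative pieces of one pair's pseudo-likelihood:
# s_tab      per-cell score d log P / d rho
# H_rho      E[d s / d rho]   = -sum (dP/drho)^2 / P
# H_ta, H_tb E[d s / d tau_k] for the thresholds of each variable
pair_score_pieces <- function(ta, tb, rho) {
  Ka <- length(ta) + 1L; Kb <- length(tb) + 1L
  P <- cpp_bvn_cell_probs(ta, tb, rho)
  P <- pmax(P, 1e-30)
  s <- sqrt(max(1 - rho^2, 1e-14))
  A <- c(-Inf, ta, Inf); B <- c(-Inf, tb, Inf)
  # dP/drho: second differences of the bivariate density at cell corners
  F2 <- matrix(cpp_bvn_pdf(rep(A, times = Kb + 1L), rep(B, each = Ka + 1L), rho),
               Ka + 1L, Kb + 1L)
  dP <- F2[-1, -1] - F2[-(Ka + 1L), -1] - F2[-1, -(Kb + 1L)] +
    F2[-(Ka + 1L), -(Kb + 1L)]
  s_tab <- dP / P

  H_rho <- -sum(dP^2 / P)

  # Da[k, j]: phi(ta_k) * P(col j | row boundary ta_k)
  Da <- matrix(0, Ka - 1L, Kb)
  for (k in seq_len(Ka - 1L))
    Da[k, ] <- dnorm(ta[k]) * diff(pnorm((B - rho * ta[k]) / s))
  Db <- matrix(0, Kb - 1L, Ka)
  for (k in seq_len(Kb - 1L))
    Db[k, ] <- dnorm(tb[k]) * diff(pnorm((A - rho * tb[k]) / s))

  H_ta <- numeric(Ka - 1L); H_tb <- numeric(Kb - 1L)
  for (k in seq_len(Ka - 1L))
    H_ta[k] <- -sum(Da[k, ] * (dP[k, ] / P[k, ] - dP[k + 1L, ] / P[k + 1L, ]))
  for (k in seq_len(Kb - 1L))
    H_tb[k] <- -sum(Db[k, ] * (dP[, k] / P[, k] - dP[, k + 1L] / P[, k + 1L]))

  # H_ta enters the influence table as a column-profile per row code:
  # reshape to (K x K-1) %*% H like lookup pieces
  list(P = P, s_tab = s_tab, H_rho = H_rho, H_ta = H_ta, H_tb = H_tb)
}
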