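#' Specify an ordinal structural equation model
#'
#' Builds the parameter map of a LISREL-type model
#' \deqn{x^* = \Lambda_x \xi + \delta_x, \quad y^* = \Lambda_y \eta + \delta_y,
#'       \quad \eta = B \eta + \Gamma \xi + \varepsilon,}
#' whose model-implied covariance of the latent responses is constrained to
#' be a correlation matrix: indicator error variances are not free
#' parameters but are derived from the unit-diagonal constraint
#' \eqn{\mathrm{diag}(\Sigma) = 1} (delta parameterization).
#'
#' Pattern matrices mix fixed numeric values and free parameters: any entry
#' that parses as a number is fixed at that value, any other string is a
#' free-parameter label.  A label used in several cells imposes an equality
#' constraint.  \code{phi} and \code{psi} are read from their lower
#' triangles and mirrored.
#'
#' The free parameters form the vector \eqn{\beta}, ordered by first
#' appearance while scanning \code{lambda_x}, \code{lambda_y}, \code{b},
#' \code{gamma}, \code{phi}, \code{psi}, \code{theta_xy} column-major.
#' \eqn{\beta} is partitioned into \eqn{\theta} (protected parameters,
#' present in every candidate model) and \eqn{\gamma} (the parameters that
#' candidate models may fix at their null value \eqn{\gamma_0}).
#'
#' @param lambda_x,lambda_y loading pattern matrices (indicators by
#'   factors); character or numeric.
#' @param b pattern matrix of directed effects among endogenous factors;
#'   must have a zero diagonal.
#' @param gamma pattern matrix of effects of exogenous on endogenous
#'   factors.
#' @param phi exogenous factor covariance pattern (symmetric).
#' @param psi structural residual covariance pattern (symmetric).
#' @param gamma_params character vector of labels making up \eqn{\gamma}.
#' @param gamma_null named numeric vector of null values \eqn{\gamma_0};
#'   defaults to 0 for every \eqn{\gamma} component.
#' @param theta_xy optional pattern matrix (\eqn{p_x \times p_y}) of error
#'   covariances between x- and y-indicators.
#' @param x_names,y_names optional indicator names.
#' @return an object of class \code{sem_model_spec}.
#' @export
sem_model_spec <- function(lambda_x, lambda_y, b, gamma, phi, psi,
                           gamma_params = character(), gamma_null = NULL,
                           theta_xy = NULL, x_names = NULL, y_names = NULL) {
  lx <- parse_pattern(lambda_x); ly <- parse_pattern(lambda_y)
  bm <- parse_pattern(b);        gm <- parse_pattern(gamma)
  ph <- parse_pattern(phi, symmetric = TRUE)
  ps <- parse_pattern(psi, symmetric = TRUE)
  tx <- if (!is.null(theta_xy)) parse_pattern(theta_xy) else NULL

  n_xi <- ncol(lx$val); n_eta <- ncol(ly$val)
  px <- nrow(lx$val); py <- nrow(ly$val)
  stopifnot(nrow(bm$val) == n_eta, ncol(bm$val) == n_eta,
            nrow(gm$val) == n_eta, ncol(gm$val) == n_xi,
            nrow(ph$val) == n_xi, nrow(ps$val) == n_eta)
  if (any(diag(bm$val) != 0) || any(!is.na(diag(bm$lab))))
    stop("b must have a fixed zero diagonal")
  if (!is.null(tx)) stopifnot(nrow(tx$val) == px, ncol(tx$val) == py)

  mats <- list(lx = lx, ly = ly, bm = bm, gm = gm, phi = ph, psi = ps)
  if (!is.null(tx)) mats$txy <- tx

  labels <- character()
  for (m in mats) labels <- c(labels, m$lab[!is.na(m$lab)])
  labels <- unique(labels)
  if (!all(gamma_params %in% labels))
    stop("gamma_params must be labels of free parameters")
  gamma_labels <- labels[labels %in% gamma_params]
  theta_labels <- setdiff(labels, gamma_labels)

  gn <- setNames(rep(0, length(gamma_labels)), gamma_labels)
  if (!is.null(gamma_null)) {
    stopifnot(!is.null(names(gamma_null)),
              all(names(gamma_null) %in% gamma_labels))
    gn[names(gamma_null)] <- gamma_null
  }

  # index matrices: position of each cell's parameter in beta (0 = fixed)
  for (nm in names(mats))
    mats[[nm]]$par <- matrix(match(mats[[nm]]$lab, labels, nomatch = 0L),
                             nrow(mats[[nm]]$lab))

  # static map parameter -> pattern cells, used by the analytic Jacobian
  param_cells <- vector("list", length(labels))
  for (nm in names(mats)) {
    par <- mats[[nm]]$par
    hits <- which(par > 0L, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1L]; j <- hits[h, 2L]
      if (nm %in% c("phi", "psi") && i < j) next  # lower cell carries both
      k <- par[i, j]
      param_cells[[k]] <- rbind(param_cells[[k]],
                                data.frame(nm = nm, i = i, j = j,
                                           stringsAsFactors = FALSE))
    }
  }

  structure(list(
    mats = mats, labels = labels, n_par = length(labels),
    param_cells = param_cells,
    theta_labels = theta_labels, gamma_labels = gamma_labels,
    theta_idx = match(theta_labels, labels),
    gamma_idx = match(gamma_labels, labels),
    gamma_null = gn,
    n_xi = n_xi, n_eta = n_eta, px = px, py = py,
    var_names = c(x_names %||% paste0("x", seq_len(px)),
                  y_names %||% paste0("y", seq_len(py)))
  ), class = "sem_model_spec")
}

parse_pattern <- function(m, symmetric = FALSE) {
  m <- as.matrix(m)
  chr <- matrix(as.character(m), nrow(m), ncol(m))
  num <- suppressWarnings(matrix(as.numeric(chr), nrow(m), ncol(m)))
  lab <- ifelse(is.na(num), chr, NA_character_)
  val <- ifelse(is.na(num), 0, num)
  if (symmetric) {
    if (nrow(m) != ncol(m)) stop("symmetric pattern must be square")
    low <- lower.tri(m, diag = TRUE)
    val[upper.tri(val)] <- t(val)[upper.tri(val)]
    lab[upper.tri(lab)] <- t(lab)[upper.tri(lab)]
  }
  list(val = val, lab = lab)
}

#' @export
print.sem_model_spec <- function(x, ...) {
  cat("Ordinal SEM specification\n")
  cat(sprintf("  indicators: %d x, %d y; factors: %d exogenous, %d endogenous\n",
              x$px, x$py, x$n_xi, x$n_eta))
  cat(sprintf("  free parameters: %d (theta: %d, gamma: %d)\n",
              x$n_par, length(x$theta_idx), length(x$gamma_idx)))
  if (length(x$gamma_idx))
    cat("  gamma:", paste(x$gamma_labels, collapse = ", "), "\n")
  invisible(x)
}

# realize all pattern matrices at a parameter vector
realize_matrices <- function(spec, beta) {
  stopifnot(length(beta) == spec$n_par)
  out <- lapply(spec$mats, function(m) {
    v <- m$val
    sel <- m$par > 0L
    v[sel] <- beta[m$par[sel]]
    v
  })
  out
}

#' Model-implied polychoric correlation structure
#'
#' Maps a free-parameter vector to the model-implied correlation matrix of
#' the latent responses.  Off-diagonal entries come from the factor
#' structure; indicator error variances are derived as one minus the
#' communality so the diagonal is exactly 1.
#'
#' @param spec a \code{\link{sem_model_spec}}.
#' @param beta numeric vector of length \code{spec$n_par}.
#' @return list with \code{Sigma} (correlation matrix), \code{sigma}
#'   (stacked unique lower-triangle entries in canonical column-major
#'   order), \code{error_var} (derived indicator error variances) and
#'   \code{heywood} (TRUE if any derived error variance is negative).
#' @export
model_implied_correlation <- function(spec, beta) {
  mt <- realize_matrices(spec, beta)
  ib <- diag(spec$n_eta) - mt$bm
  A <- tryCatch(solve(ib), error = function(e)
    stop_semfma("I - B is singular at the supplied parameter value",
                "semfma_structural_singularity"))
  lat <- latent_cov(mt, A)
  Lam <- block_diag(mt$lx, mt$ly)
  S <- Lam %*% lat %*% t(Lam)
  if (!is.null(mt$txy)) {
    ix <- seq_len(spec$px); iy <- spec$px + seq_len(spec$py)
    S[ix, iy] <- S[ix, iy] + mt$txy
    S[iy, ix] <- t(S[ix, iy])
  }
  ev <- 1 - diag(S)
  diag(S) <- 1
  dimnames(S) <- list(spec$var_names, spec$var_names)
  list(Sigma = S, sigma = lower_vec(S), error_var = ev,
       heywood = any(ev < 0))
}

# covariance matrix of the stacked latent vector (xi, eta)
latent_cov <- function(mt, A) {
  Phi <- mt$phi
  GPhi <- mt$gm %*% Phi
  Veta <- A %*% (GPhi %*% t(mt$gm) + mt$psi) %*% t(A)
  Cxe <- Phi %*% t(mt$gm) %*% t(A)
  rbind(cbind(Phi, Cxe), cbind(t(Cxe), Veta))
}

#' Jacobian of the model-implied correlations
#'
#' Derivative matrix \eqn{\partial\sigma/\partial\beta^T}: rows follow the
#' canonical order of the stacked unique correlations, columns the order of
#' \eqn{\beta}.  Because the derived error variances are diagonal, the
#' unit-diagonal constraint does not propagate into the off-diagonal
#' entries and the analytic form is exact.
#'
#' @inheritParams model_implied_correlation
#' @param method \code{"analytic"} (default) or \code{"numeric"} central
#'   finite differences with step \code{1e-6}.
#' @return numeric matrix, \code{choose(p,2)} rows by \code{spec$n_par}
#'   columns.
#' @export
sigma_jacobian <- function(spec, beta, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (method == "numeric") return(numeric_sigma_jacobian(spec, beta))
  mt <- realize_matrices(spec, beta)
  ib <- diag(spec$n_eta) - mt$bm
  A <- tryCatch(solve(ib), error = function(e)
    stop_semfma("I - B is singular at the supplied parameter value",
                "semfma_structural_singularity"))
  lat <- latent_cov(mt, A)
  Lam <- block_diag(mt$lx, mt$ly)
  LamLat <- Lam %*% lat
  S_eps <- mt$gm %*% mt$phi %*% t(mt$gm) + mt$psi
  ptot <- spec$px + spec$py
  nlow <- ptot * (ptot - 1) / 2
  Jc <- matrix(0, nlow, spec$n_par)

  add_dLat <- function(dlat) (Lam %*% dlat) %*% t(Lam)

  for (k in seq_len(spec$n_par)) {
    cells <- spec$param_cells[[k]]
    dS <- matrix(0, ptot, ptot)
    for (h in seq_len(nrow(cells)))
      dS <- dS + d_sigma_cell(spec, mt, A, lat, Lam, LamLat, S_eps,
                              cells$nm[h], cells$i[h], cells$j[h])
    Jc[, k] <- lower_vec(dS)
  }
  colnames(Jc) <- spec$labels
  Jc
}

# derivative of Lambda Vlat Lambda^T (+ cross error block) w.r.t. one cell
d_sigma_cell <- function(spec, mt, A, lat, Lam, LamLat, S_eps, nm, i, j) {
  n_xi <- spec$n_xi; n_eta <- spec$n_eta
  ptot <- spec$px + spec$py
  m <- n_xi + n_eta
  if (nm == "lx" || nm == "ly") {
    row <- if (nm == "lx") i else spec$px + i
    col <- if (nm == "lx") j else n_xi + j
    dS <- matrix(0, ptot, ptot)
    v <- LamLat[, col]           # Lambda lat e_col
    dS[row, ] <- dS[row, ] + v
    dS[, row] <- dS[, row] + v
    # diagonal double count is irrelevant (only off-diagonals are used)
    return(dS)
  }
  if (nm == "txy") {
    dS <- matrix(0, ptot, ptot)
    dS[i, spec$px + j] <- 1
    dS[spec$px + j, i] <- 1
    return(dS)
  }
  dlat <- matrix(0, m, m)
  ix <- seq_len(n_xi); ie <- n_xi + seq_len(n_eta)
  if (nm == "phi") {
    dP <- matrix(0, n_xi, n_xi); dP[i, j] <- 1; dP[j, i] <- 1
    AG <- A %*% mt$gm
    dlat[ix, ix] <- dP
    dlat[ix, ie] <- dP %*% t(AG)
    dlat[ie, ix] <- t(dlat[ix, ie])
    dlat[ie, ie] <- AG %*% dP %*% t(AG)
  } else if (nm == "psi") {
    dP <- matrix(0, n_eta, n_eta); dP[i, j] <- 1; dP[j, i] <- 1
    dlat[ie, ie] <- A %*% dP %*% t(A)
  } else if (nm == "gm") {
    dG <- matrix(0, n_eta, n_xi); dG[i, j] <- 1
    dCxe <- mt$phi %*% t(dG) %*% t(A)
    dVe <- A %*% (dG %*% mt$phi %*% t(mt$gm) +
                  mt$gm %*% mt$phi %*% t(dG)) %*% t(A)
    dlat[ix, ie] <- dCxe
    dlat[ie, ix] <- t(dCxe)
    dlat[ie, ie] <- dVe
  } else if (nm == "bm") {
    dB <- matrix(0, n_eta, n_eta); dB[i, j] <- 1
    dA <- A %*% dB %*% A
    dCxe <- mt$phi %*% t(mt$gm) %*% t(dA)
    dVe <- dA %*% S_eps %*% t(A) + A %*% S_eps %*% t(dA)
    dlat[ix, ie] <- dCxe
    dlat[ie, ix] <- t(dCxe)
    dlat[ie, ie] <- dVe
  }
  (Lam %*% dlat) %*% t(Lam)
}

numeric_sigma_jacobian <- function(spec, beta, step = 1e-6) {
  f <- function(b) model_implied_correlation(spec, b)$sigma
  base <- f(beta)
  J <- matrix(0, length(base), length(beta))
  for (k in seq_along(beta)) {
    up <- beta; up[k] <- up[k] + step
    dn <- beta; dn[k] <- dn[k] - step
    J[, k] <- (f(up) - f(dn)) / (2 * step)
  }
  colnames(J) <- spec$labels
  J
}

#' Define a candidate model by the gamma components it frees
#'
#' @param id character label.
#' @param retain character vector of \eqn{\gamma} labels freely estimated
#'   by this candidate (empty for the narrow model).
#' @param spec the parent \code{\link{sem_model_spec}}.
#' @return object of class \code{candidate_model} carrying the 0/1
#'   selection matrix \eqn{\pi_s} whose rows extract the retained
#'   components from \eqn{\gamma}.
#' @export
candidate_model <- function(id, retain, spec) {
  stopifnot(all(retain %in% spec$gamma_labels))
  retain <- spec$gamma_labels[spec$gamma_labels %in% retain]
  q <- length(spec$gamma_labels)
  pi_s <- matrix(0, length(retain), q,
                 dimnames = list(retain, spec$gamma_labels))
  pi_s[cbind(seq_along(retain), match(retain, spec$gamma_labels))] <- 1
  structure(list(id = id, retain = retain, pi = pi_s,
                 is_narrow = length(retain) == 0L,
                 is_full = length(retain) == q),
            class = "candidate_model")
}

#' Assemble an ordered candidate set
#'
#' The set must contain exactly one narrow model (no \eqn{\gamma}
#' components) and one full model (all of them), and every candidate's
#' retained set must be a subset of the full model's.
#'
#' @param spec a \code{\link{sem_model_spec}}.
#' @param retain_list named list; each element is the character vector of
#'   retained \eqn{\gamma} labels for one candidate, ordered from most
#'   restrictive to least.
#' @return object of class \code{candidate_set}.
#' @export
candidate_set <- function(spec, retain_list) {
  cands <- lapply(seq_along(retain_list), function(i)
    candidate_model(names(retain_list)[i] %||% paste0("M", i),
                    retain_list[[i]], spec))
  if (sum(vapply(cands, `[[`, TRUE, "is_narrow")) != 1L)
    stop("candidate set must contain exactly one narrow model")
  if (sum(vapply(cands, `[[`, TRUE, "is_full")) != 1L)
    stop("candidate set must contain exactly one full model")
  structure(list(models = cands, spec = spec), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set (", length(x$models), " models):\n", sep = "")
  for (m in x$models)
    cat(sprintf("  %-8s gamma freed: %s%s\n", m$id,
                if (length(m$retain)) paste(m$retain, collapse = ", ") else "(none)",
                if (m$is_narrow) "  [narrow]" else if (m$is_full) "  [full]" else ""))
  invisible(x)
}

# beta positions freely estimated by a candidate (theta plus retained gamma)
candidate_free_indices <- function(spec, candidate) {
  sort(c(spec$theta_idx, spec$gamma_idx[match(candidate$retain,
                                              spec$gamma_labels)]))
}

#' Embed a candidate-model parameter vector into the full parameter space
#'
#' Excluded \eqn{\gamma} components are filled with their null values
#' \eqn{\gamma_0}; the result can be passed to
#' \code{\link{model_implied_correlation}}.
#'
#' @param spec a \code{\link{sem_model_spec}}.
#' @param candidate a \code{\link{candidate_model}}.
#' @param beta_candidate parameter vector in the candidate's space
#'   (\eqn{\theta} plus retained \eqn{\gamma}, in \eqn{\beta} order).
#' @return full-length parameter vector.
#' @export
restrict_to_candidate <- function(spec, candidate, beta_candidate) {
  free <- candidate_free_indices(spec, candidate)
  if (length(beta_candidate) != length(free))
    stop("beta_candidate has length ", length(beta_candidate),
         ", expected ", length(free))
  beta <- numeric(spec$n_par)
  beta[spec$gamma_idx] <- spec$gamma_null
  beta[free] <- beta_candidate
  names(beta) <- spec$labels
  beta
}
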