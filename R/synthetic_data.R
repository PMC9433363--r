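#' Four-factor study model specification
#'
#' The two-exogenous/two-endogenous factor model used throughout the
#' simulation machinery: three indicators per factor with loadings
#' (1, free, free), free exogenous covariance matrix, diagonal structural
#' residual covariance, and structural coefficients
#' \eqn{\Gamma = \begin{pmatrix} g_{11} & g_{12} \\ g_{21} & g_{22}
#' \end{pmatrix}}, \eqn{B_{21} = b_{21}}.  The candidate family fixes or
#' frees \eqn{\gamma = (g_{12}, g_{21}, b_{21})} at \eqn{\gamma_0 = 0}:
#' the narrow model fixes all three, Model 2 frees \eqn{g_{12}}, Model 3
#' frees \eqn{g_{12}} and \eqn{g_{21}}, and the full model frees all
#' three.
#'
#' @return list with \code{spec} (a \code{\link{sem_model_spec}}) and
#'   \code{cset} (a \code{\link{candidate_set}} of the four models).
#' @export
simulation_model <- function() {
  lx <- rbind(c(1, 0), c("lx2", 0), c("lx3", 0),
              c(0, 1), c(0, "lx5"), c(0, "lx6"))
  ly <- rbind(c(1, 0), c("ly2", 0), c("ly3", 0),
              c(0, 1), c(0, "ly5"), c(0, "ly6"))
  b <- rbind(c(0, 0), c("b21", 0))
  g <- rbind(c("g11", "g12"), c("g21", "g22"))
  phi <- rbind(c("phi11", "phi21"), c("phi21", "phi22"))
  psi <- rbind(c("psi1", 0), c(0, "psi2"))
  spec <- sem_model_spec(lx, ly, b, g, phi, psi,
                         gamma_params = c("g12", "g21", "b21"),
                         x_names = paste0("x", 1:6),
                         y_names = paste0("y", 1:6))
  cset <- candidate_set(spec, list(
    M1 = character(), M2 = "g12", M3 = c("g12", "g21"),
    M4 = c("g12", "g21", "b21")))
  list(spec = spec, cset = cset)
}

#' Simulation design
#'
#' Conditions of one Monte Carlo cell: asymptotic framework, effect scale,
#' sample size, threshold asymmetry, replication count and seeding.
#' Under the local framework the structural effects drift with the sample
#' size, \eqn{g_{12} = \delta/\sqrt{n}}, \eqn{g_{21} = 0.75\delta/\sqrt{n}},
#' \eqn{b_{21} = 0.5\delta/\sqrt{n}} with \eqn{\delta = \sqrt{150}\,\zeta};
#' under the standard framework \eqn{g_{12} = \zeta},
#' \eqn{g_{21} = 0.75\zeta}, \eqn{b_{21} = 0.5\zeta}.  The two coincide at
#' \eqn{n = 150}.
#'
#' @param framework \code{"local"} or \code{"standard"}.
#' @param zeta effect scale, nonnegative (study grid: 0 to 0.30 by 0.05).
#' @param n sample size (study grid: 150, 350, 600).
#' @param thresholds \code{"moderate"} (category probabilities 0.24, 0.41,
#'   0.22, 0.10, 0.03) or \code{"extreme"} (0.52, 0.15, 0.13, 0.11, 0.09).
#' @param n_replications number of Monte Carlo replications.
#' @param base_seed integer; replication r uses seed \code{base_seed + r}.
#' @param ls_method least-squares weighting (default DWLS).
#' @param alpha nominal interval error level.
#' @param rmsea_cutoff robust RMSEA acceptance threshold for sequential
#'   selection.
#' @return object of class \code{simulation_design}.
#' @export
simulation_design <- function(framework = c("local", "standard"), zeta = 0,
                              n = 150, thresholds = c("moderate", "extreme"),
                              n_replications = 1000, base_seed = 1,
                              ls_method = "DWLS", alpha = 0.05,
                              rmsea_cutoff = 0.05) {
  framework <- match.arg(framework)
  thresholds <- match.arg(thresholds)
  stopifnot(zeta >= 0, n >= 10, n_replications >= 1)
  structure(list(framework = framework, zeta = zeta, n = as.integer(n),
                 thresholds = thresholds,
                 n_replications = as.integer(n_replications),
                 base_seed = as.integer(base_seed), ls_method = ls_method,
                 alpha = alpha, rmsea_cutoff = rmsea_cutoff),
            class = "simulation_design")
}

#' Category probabilities of the two threshold regimes
#' @param thresholds \code{"moderate"} or \code{"extreme"}.
#' @return numeric vector of five category probabilities.
#' @export
category_probabilities <- function(thresholds = c("moderate", "extreme")) {
  switch(match.arg(thresholds),
         moderate = c(0.24, 0.41, 0.22, 0.10, 0.03),
         extreme = c(0.52, 0.15, 0.13, 0.11, 0.09))
}

#' Discretization thresholds implied by the category probabilities
#' @inheritParams category_probabilities
#' @return four interior standard normal quantiles.
#' @export
design_thresholds <- function(thresholds = c("moderate", "extreme")) {
  p <- category_probabilities(thresholds)
  qnorm(cumsum(p)[-length(p)])
}

#' Population parameters of a simulation design
#'
#' Loadings (1, 0.95, 0.9) per factor, exogenous covariance 0.7/0.3,
#' protected structural effects 0.5 and 0.45, and structural effects
#' determined by the framework.  The structural residual variances solve
#' the reliability constraint: the endogenous factor variances are held at
#' their narrow-truth values (0.625 and 0.64175, at which the residual
#' variances are 0.45 and 0.5) for every effect scale, so discretization
#' thresholds keep the same meaning across conditions.  Indicator error
#' variances make every latent-response variance exactly 1.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param model optional \code{\link{simulation_model}} (rebuilt if
#'   missing).
#' @return list with \code{beta} (true parameter vector), \code{Sigma}
#'   (population correlation matrix), \code{tau} (discretization
#'   thresholds), \code{psi} (residual variances), \code{delta}
#'   (local parameter implied by the design).
#' @export
population_parameters <- function(design, model = simulation_model()) {
  spec <- model$spec
  zeta <- design$zeta
  if (design$framework == "local") {
    delta_scale <- sqrt(150) * zeta
    g12 <- delta_scale / sqrt(design$n)
  } else {
    delta_scale <- sqrt(design$n) * zeta
    g12 <- zeta
  }
  g21 <- 0.75 * g12
  b21 <- 0.5 * g12

  beta <- setNames(numeric(spec$n_par), spec$labels)
  beta[c("lx2", "ly2")] <- 0.95
  beta[c("lx3", "ly3")] <- 0.9
  beta[c("lx5", "ly5")] <- 0.95
  beta[c("lx6", "ly6")] <- 0.9
  beta[c("phi11", "phi22")] <- 0.7
  beta["phi21"] <- 0.3
  beta["g11"] <- 0.5
  beta["g22"] <- 0.45
  beta["g12"] <- g12
  beta["g21"] <- g21
  beta["b21"] <- b21

  # residual variances from the reliability constraint
  target <- c(0.5^2 * 0.7 + 0.45, 0.45^2 * 0.7 + 0.5)   # 0.625, 0.64175
  psi <- solve_psi(spec, beta, target)
  beta["psi1"] <- psi[1]; beta["psi2"] <- psi[2]

  mic <- model_implied_correlation(spec, beta)
  if (mic$heywood)
    stop("population is infeasible: negative indicator error variance")
  list(beta = beta, Sigma = mic$Sigma,
       tau = design_thresholds(design$thresholds), psi = psi,
       delta = c(g12 = g12, g21 = g21, b21 = b21) * sqrt(design$n),
       delta_scale = delta_scale)
}

# diagonal structural residual variances holding diag var(eta) at `target`;
# B strictly lower triangular makes the solve sequential
solve_psi <- function(spec, beta, target) {
  mt <- realize_matrices(spec, beta)
  n_eta <- spec$n_eta
  A <- solve(diag(n_eta) - mt$bm)
  base <- mt$gm %*% mt$phi %*% t(mt$gm)
  psi <- numeric(n_eta)
  for (k in seq_len(n_eta)) {
    Vk <- A %*% (base + diag(psi, n_eta)) %*% t(A)
    psi[k] <- target[k] - Vk[k, k]
    if (psi[k] < 0)
      stop("infeasible reliability constraint: negative residual variance")
  }
  psi
}

#' Generate one ordinal dataset from a simulation design
#'
#' Draws multivariate normal latent responses with the population
#' correlation structure and discretizes every variable at the design's
#' thresholds.  Deterministic given \code{(base_seed, replication)}.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param replication replication index (>= 1).
#' @param pop optional precomputed \code{\link{population_parameters}}.
#' @return an \code{\link{ordinal_dataset}} with attribute
#'   \code{"latent"} = NULL (latents are not retained).
#' @export
generate_dataset <- function(design, replication = 1,
                             pop = NULL) {
  pop <- pop %||% population_parameters(design)
  set.seed(design$base_seed + as.integer(replication))
  p <- ncol(pop$Sigma)
  z <- matrix(rnorm(design$n * p), design$n, p) %*% chol(pop$Sigma)
  codes <- matrix(0L, design$n, p)
  for (j in seq_len(p))
    codes[, j] <- findInterval(z[, j], pop$tau) + 1L
  colnames(codes) <- colnames(pop$Sigma)
  ordinal_dataset(codes, ncat = rep(length(pop$tau) + 1L, p))
}

#' Export a generated dataset to CSV
#' @param data an \code{\link{ordinal_dataset}}.
#' @param path output file.
#' @export
write_ordinal_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data$values), path, row.names = FALSE)
}
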