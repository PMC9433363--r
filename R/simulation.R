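#' Run one Monte Carlo replication
#'
#' Generates a dataset, estimates thresholds, polychoric correlations and
#' their asymptotic covariance, fits all candidate models by the design's
#' least-squares method, and evaluates four estimation strategies:
#' sequential robust-RMSEA model selection, the full model, frequentist
#' model averaging with the ordinal-data corrections (FMAord), and model
#' averaging with the continuous-data weight criterion and interval
#' (FMAordcont).  Candidate models that fail to converge or land in the
#' Heywood region are inadmissible; if the narrow or the full model is
#' inadmissible, the averaging strategies are recorded as missing for the
#' replication.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param replication replication index.
#' @param model a \code{\link{simulation_model}} (rebuilt if missing).
#' @param pop precomputed \code{\link{population_parameters}}.
#' @return list of per-replication records (see
#'   \code{\link{run_simulation}}).
#' @export
run_replication <- function(design, replication, model = simulation_model(),
                            pop = NULL) {
  pop <- pop %||% population_parameters(design, model)
  spec <- model$spec; cset <- model$cset
  n <- design$n
  ids <- vapply(cset$models, `[[`, "", "id")
  S <- length(ids)
  methods <- c("selection", "full", "FMAord", "FMAordcont")

  out <- list(replication = replication,
              admissible = setNames(rep(FALSE, S), ids),
              cand_sqerr = setNames(rep(NA_real_, S), ids),
              chosen = NA_character_, collapsed = FALSE,
              sqerr = setNames(rep(NA_real_, 4), methods),
              cover = setNames(rep(NA, 4), methods),
              err = setNames(vector("list", 4), methods),
              weights = NULL,
              reject = setNames(rep(NA, 6),
                                c("full_m", "full_mv", "FMAord_m", "FMAord_mv",
                                  "FMAordcont_m", "FMAordcont_mv")))

  data <- generate_dataset(design, replication, pop)
  out$collapsed <- any(data$collapsed)
  pf <- tryCatch(polychoric(data, upsilon = TRUE),
                 error = function(e) NULL)
  if (is.null(pf)) return(out)
  weight <- tryCatch(build_weight_matrix(pf$upsilon, design$ls_method),
                     error = function(e) NULL)
  if (is.null(weight)) return(out)

  fits <- fit_candidate_set(pf$rho, weight, spec, cset, n)
  adm <- vapply(fits, `[[`, TRUE, "admissible")
  out$admissible <- adm
  g11 <- which(spec$labels == "g11")
  truth <- pop$beta

  for (s in which(adm))
    out$cand_sqerr[s] <- sum((fits[[s]]$beta_full - truth)^2)

  # sequential model selection by robust RMSEA
  rmsea <- rep(NA_real_, S)
  for (s in which(adm)) {
    r_s <- length(pf$rho) - length(fits[[s]]$free)
    Ts <- t_full(pf$rho, fits[[s]]$sigma_hat, weight$V, n)
    tr_s <- sum(diag(xi_single(fits[[s]], spec, weight$V, pf$upsilon)))
    rmsea[s] <- robust_rmsea(Ts, tr_s, r_s, n)
  }
  sel <- sequential_model_selection(rmsea, design$rmsea_cutoff)
  if (!is.na(sel)) {
    out$chosen <- ids[sel]
    fit_s <- fits[[sel]]
    ci <- tryCatch(single_model_interval(fit_s, spec, weight, pf$upsilon,
                                         design$alpha),
                   error = function(e) NULL)
    out$err$selection <- fit_s$beta_full - truth
    out$sqerr["selection"] <- sum(out$err$selection^2)
    if (!is.null(ci)) {
      row <- ci[ci$parameter == "g11", ]
      out$cover["selection"] <- row$lower <= truth[g11] && truth[g11] <= row$upper
    }
  }

  full_idx <- which(vapply(cset$models, `[[`, TRUE, "is_full"))
  narrow_idx <- which(vapply(cset$models, `[[`, TRUE, "is_narrow"))
  if (!adm[full_idx] || !adm[narrow_idx]) return(out)
  full_fit <- fits[[full_idx]]

  res <- tryCatch({
    asym <- compute_asymptotics(spec, full_fit$beta_full, weight,
                                pf$upsilon, cset, n = n)
    kap_ord <- kappa_covariance(asym, "ordinal")
    kap_cont <- kappa_covariance(asym, "continuous")
    delta <- estimate_delta(full_fit$beta_full[spec$gamma_idx],
                            spec$gamma_null, n)

    avg_one <- function(variant, kap) {
      dd <- estimate_delta_outer(delta, asym,
                                 if (variant == "ordinal") "ordinal" else "continuous")
      q <- build_Q(asym, dd, variant)
      qa <- list(a = q$a[adm], P = q$P[adm, adm, drop = FALSE],
                 delta1 = q$delta1, delta2 = q$delta2)
      w <- minimize_weights(structure(qa, class = "q_problem"))
      fm <- fma_combine(fits[adm], w, asym, delta)
      ci <- fma_interval(fm, kap, n, design$alpha)
      list(fma = fm, ci = ci)
    }

    ord <- avg_one("ordinal", kap_ord)
    cont <- avg_one("continuous", kap_cont)

    ci_full <- full_model_interval(full_fit$mu_hat, kap_ord, n, design$alpha)

    # goodness of fit: full statistic plus both averaged statistics,
    # all calibrated by the same scaling matrix
    r_full <- length(pf$rho) - spec$n_par
    xi <- xi_fma(asym)
    Tf <- t_full(pf$rho, full_fit$sigma_hat, weight$V, n)
    To <- t_fma(pf$rho, ord$fma, spec, weight$V, n)
    Tc <- t_fma(pf$rho, cont$fma, spec, weight$V, n)
    sf <- scaled_statistics(Tf, xi, r_full)
    so <- scaled_statistics(To, xi, r_full)
    sc <- scaled_statistics(Tc, xi, r_full)

    list(asym = asym, ord = ord, cont = cont, ci_full = ci_full,
         sf = sf, so = so, sc = sc)
  }, error = function(e) NULL)
  if (is.null(res)) return(out)

  cover_of <- function(ci) {
    row <- ci[ci$parameter == "g11", ]
    row$lower <= truth[g11] && truth[g11] <= row$upper
  }
  out$err$full <- full_fit$beta_full - truth
  out$err$FMAord <- res$ord$fma$mu_bar - truth
  out$err$FMAordcont <- res$cont$fma$mu_bar - truth
  out$sqerr["full"] <- sum(out$err$full^2)
  out$sqerr["FMAord"] <- sum(out$err$FMAord^2)
  out$sqerr["FMAordcont"] <- sum(out$err$FMAordcont^2)
  out$cover["full"] <- cover_of(res$ci_full)
  out$cover["FMAord"] <- cover_of(res$ord$ci)
  out$cover["FMAordcont"] <- cover_of(res$cont$ci)
  out$weights <- res$ord$fma$weights
  alpha <- design$alpha
  out$reject <- c(full_m = res$sf$p_scaled < alpha,
                  full_mv = res$sf$p_adjusted < alpha,
                  FMAord_m = res$so$p_scaled < alpha,
                  FMAord_mv = res$so$p_adjusted < alpha,
                  FMAordcont_m = res$sc$p_scaled < alpha,
                  FMAordcont_mv = res$sc$p_adjusted < alpha)
  out
}

#' Run a Monte Carlo simulation cell
#'
#' Executes \code{design$n_replications} replications with per-replication
#' seeds \code{base_seed + r} and collects the outcome records.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param model a \code{\link{simulation_model}}.
#' @param progress print a dot every 50 replications.
#' @return object of class \code{simulation_result}: list of outcomes plus
#'   the design.
#' @export
run_simulation <- function(design, model = simulation_model(),
                           progress = FALSE) {
  pop <- population_parameters(design, model)
  outcomes <- vector("list", design$n_replications)
  for (r in seq_len(design$n_replications)) {
    outcomes[[r]] <- run_replication(design, r, model, pop)
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(outcomes = outcomes, design = design, pop = pop),
            class = "simulation_result")
}

#' Outlier screen on squared-error values
#'
#' Flags, per method, the replications whose squared-error sum exceeds
#' twice the 99th sample percentile of that method's values.
#'
#' @param sqerr numeric vector of per-replication squared-error sums (NA
#'   for replications where the method is undefined).
#' @return logical vector, TRUE = keep.
#' @export
outlier_filter <- function(sqerr) {
  keep <- !is.na(sqerr)
  if (sum(keep) == 0L) return(keep)
  cut <- 2 * quantile(sqerr[keep], 0.99, names = FALSE)
  keep & (sqerr <= cut)
}

#' Normalized mean squared error of one method
#'
#' Per replication, the method's squared-error sum divided by the minimum
#' squared-error sum among the admissible candidate models, averaged over
#' the replications that survive the outlier screen.
#'
#' @param sim a \code{\link{run_simulation}} result.
#' @param method one of \code{"selection"}, \code{"full"},
#'   \code{"FMAord"}, \code{"FMAordcont"}.
#' @return scalar.
#' @export
normalized_mse <- function(sim, method) {
  sq <- vapply(sim$outcomes, function(o) o$sqerr[[method]], 0)
  best <- vapply(sim$outcomes, function(o) {
    v <- o$cand_sqerr
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  }, 0)
  keep <- outlier_filter(sq) & !is.na(best) & best > 0
  mean(sq[keep] / best[keep])
}

#' Averaged absolute bias of one method
#'
#' Per parameter, the median over replications of the estimation error;
#' the absolute medians are then averaged over parameters.
#'
#' @inheritParams normalized_mse
#' @return scalar.
#' @export
averaged_absolute_bias <- function(sim, method) {
  sq <- vapply(sim$outcomes, function(o) o$sqerr[[method]], 0)
  keep <- outlier_filter(sq)
  errs <- lapply(sim$outcomes[keep], function(o) o$err[[method]])
  errs <- errs[!vapply(errs, is.null, TRUE)]
  if (length(errs) < 2L) return(NA_real_)
  em <- do.call(rbind, errs)
  mean(abs(apply(em, 2L, median)))
}

#' Summarize a simulation cell
#'
#' Coverage of the protected structural effect (true value 0.5), empirical
#' rejection rates of the scaled fit statistics at the design's alpha,
#' normalized MSE and averaged absolute bias per method, with binomial
#' Monte Carlo standard errors and replication bookkeeping.
#'
#' @param sim a \code{\link{run_simulation}} result.
#' @return list of data frames \code{coverage}, \code{rejection},
#'   \code{accuracy}, \code{counts}.
#' @export
summarize_simulation <- function(sim) {
  methods <- c("selection", "full", "FMAord", "FMAordcont")
  cov_rate <- function(m) {
    v <- vapply(sim$outcomes, function(o) o$cover[[m]], NA)
    v <- v[!is.na(v)]
    c(rate = mean(v), n = length(v),
      mc_se = sqrt(mean(v) * (1 - mean(v)) / max(length(v), 1)))
  }
  coverage <- do.call(rbind, lapply(methods, cov_rate))
  coverage <- data.frame(method = methods, coverage,
                         row.names = NULL, stringsAsFactors = FALSE)

  stats <- names(sim$outcomes[[1]]$reject)
  rej_rate <- function(s) {
    v <- vapply(sim$outcomes, function(o) o$reject[[s]], NA)
    v <- v[!is.na(v)]
    c(rate = mean(v), n = length(v),
      mc_se = sqrt(mean(v) * (1 - mean(v)) / max(length(v), 1)))
  }
  rejection <- do.call(rbind, lapply(stats, rej_rate))
  rejection <- data.frame(statistic = stats, rejection,
                          row.names = NULL, stringsAsFactors = FALSE)

  accuracy <- data.frame(
    method = methods,
    normalized_mse = vapply(methods, function(m) normalized_mse(sim, m), 0),
    averaged_abs_bias = vapply(methods, function(m)
      averaged_absolute_bias(sim, m), 0),
    row.names = NULL, stringsAsFactors = FALSE)

  adm <- t(vapply(sim$outcomes, `[[`, logical(length(sim$outcomes[[1]]$admissible)),
                  "admissible"))
  counts <- data.frame(
    requested = sim$design$n_replications,
    fma_defined = sum(vapply(sim$outcomes, function(o)
      !is.na(o$cover[["FMAord"]]), TRUE)),
    candidate_admissible = I(list(colSums(adm))))

  list(coverage = coverage, rejection = rejection, accuracy = accuracy,
       counts = counts)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation cell: %s framework, zeta = %.2f, n = %d, %s thresholds, R = %d\n",
              x$design$framework, x$design$zeta, x$design$n,
              x$design$thresholds, x$design$n_replications))
  s <- summarize_simulation(x)
  cat("Coverage of the protected structural effect (0.5):\n")
  print(s$coverage, digits = 3)
  cat("Fit-statistic rejection rates:\n")
  print(s$rejection, digits = 3)
  invisible(x)
}
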