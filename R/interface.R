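#' Read a model configuration file
#'
#' JSON or YAML description of an ordinal SEM and its candidate family.
#' Expected keys: \code{factors} (named list; each factor has
#' \code{indicators} and \code{exogenous} true/false), \code{loadings}
#' (optional fixed values; by default the first indicator per factor is
#' fixed at 1 and the rest are free), \code{structural_paths} (list of
#' \code{from}/\code{to} latent names, optionally \code{fixed} at a
#' value), \code{latent_covariances} (list of \code{v1}/\code{v2}
#' exogenous pairs estimated freely; variances are always free),
#' \code{gamma} (list of \code{from}/\code{to} paths forming the
#' local-misspecification block, optionally with \code{null} values) and
#' \code{candidates} (named list of retained-path subsets; \code{"all"}
#' retains everything).
#'
#' @param path a \code{.json}, \code{.yml} or \code{.yaml} file.
#' @return list with \code{spec} and \code{cset}.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::yaml.load_file(path)
  build_model_from_config(cfg)
}

build_model_from_config <- function(cfg) {
  facs <- cfg$factors
  fnames <- names(facs)
  exo <- vapply(facs, function(f) isTRUE(f$exogenous), TRUE)
  xi_names <- fnames[exo]; eta_names <- fnames[!exo]
  if (length(xi_names) == 0L || length(eta_names) == 0L)
    stop("config needs at least one exogenous and one endogenous factor")
  x_ind <- unlist(lapply(facs[exo], function(f) unlist(f$indicators)))
  y_ind <- unlist(lapply(facs[!exo], function(f) unlist(f$indicators)))

  make_lambda <- function(factor_names, indicators) {
    lam <- matrix("0", length(indicators), length(factor_names))
    row <- 0L
    for (k in seq_along(factor_names)) {
      ind <- unlist(facs[[factor_names[k]]]$indicators)
      for (i in seq_along(ind)) {
        row <- row + 1L
        lam[row, k] <- if (i == 1L) "1" else paste0("l_", ind[i])
      }
    }
    lam
  }
  lx <- make_lambda(xi_names, x_ind)
  ly <- make_lambda(eta_names, y_ind)

  path_label <- function(p) paste0(p$to, "~", p$from)
  b <- matrix("0", length(eta_names), length(eta_names))
  g <- matrix("0", length(eta_names), length(xi_names))
  gamma_params <- character(); gamma_null <- numeric()
  all_paths <- c(cfg$structural_paths, cfg$gamma)
  is_gamma <- c(rep(FALSE, length(cfg$structural_paths)),
                rep(TRUE, length(cfg$gamma)))
  for (i in seq_along(all_paths)) {
    p <- all_paths[[i]]
    lab <- if (!is.null(p$fixed)) as.character(p$fixed) else path_label(p)
    if (p$to %in% eta_names && p$from %in% eta_names)
      b[match(p$to, eta_names), match(p$from, eta_names)] <- lab
    else if (p$to %in% eta_names && p$from %in% xi_names)
      g[match(p$to, eta_names), match(p$from, xi_names)] <- lab
    else stop("path must point to an endogenous factor: ", path_label(p))
    if (is_gamma[i]) {
      gamma_params <- c(gamma_params, lab)
      gamma_null[lab] <- p$null %||% 0
    }
  }

  phi <- diag(length(xi_names))
  phi[] <- "0"
  for (k in seq_along(xi_names))
    phi[k, k] <- paste0("phi_", xi_names[k])
  for (pc in cfg$latent_covariances) {
    i <- match(pc$v1, xi_names); j <- match(pc$v2, xi_names)
    if (is.na(i) || is.na(j)) stop("latent covariance must join exogenous factors")
    phi[i, j] <- phi[j, i] <- paste0("phi_", pc$v1, "_", pc$v2)
  }
  psi <- diag(length(eta_names))
  psi[] <- "0"
  for (k in seq_along(eta_names))
    psi[k, k] <- paste0("psi_", eta_names[k])

  spec <- sem_model_spec(lx, ly, b, g, phi, psi,
                         gamma_params = gamma_params,
                         gamma_null = gamma_null,
                         x_names = x_ind, y_names = y_ind)
  retain <- lapply(cfg$candidates, function(r) {
    r <- unlist(r)
    if (length(r) == 1L && identical(r, "all")) gamma_params
    else if (length(r) == 1L && identical(r, "none")) character()
    else as.character(r)
  })
  list(spec = spec, cset = candidate_set(spec, retain))
}

#' Full model-averaging pipeline on one dataset
#'
#' Polychoric estimation, candidate fitting, weight estimation with the
#' ordinal-data risk criterion, confidence intervals and fit statistics.
#'
#' @param data an \code{\link{ordinal_dataset}} (or coercible matrix).
#' @param spec a \code{\link{sem_model_spec}}.
#' @param cset a \code{\link{candidate_set}}.
#' @param method least-squares weighting: DWLS (default), ULS or WLS.
#' @param alpha interval error level.
#' @param variant \code{"ordinal"} for the corrected criterion and
#'   interval scale, \code{"continuous"} for the continuous-data forms.
#' @return object of class \code{fma_sem}: polychoric fit, candidate
#'   fits, weights, averaged estimate, intervals (averaged and full
#'   model) and fit statistics.
#' @export
fma_sem <- function(data, spec, cset, method = "DWLS", alpha = 0.05,
                    variant = c("ordinal", "continuous")) {
  variant <- match.arg(variant)
  if (!inherits(data, "ordinal_dataset")) data <- ordinal_dataset(data)
  n <- data$n
  pf <- polychoric(data, upsilon = TRUE)
  weight <- build_weight_matrix(pf$upsilon, method)
  fits <- fit_candidate_set(pf$rho, weight, spec, cset, n)
  adm <- vapply(fits, `[[`, TRUE, "admissible")
  full_idx <- which(vapply(cset$models, `[[`, TRUE, "is_full"))
  narrow_idx <- which(vapply(cset$models, `[[`, TRUE, "is_narrow"))
  if (!adm[full_idx] || !adm[narrow_idx])
    stop_semfma("narrow or full model inadmissible: averaging not defined",
                "semfma_fma_inadmissible")
  full_fit <- fits[[full_idx]]
  asym <- compute_asymptotics(spec, full_fit$beta_full, weight, pf$upsilon,
                              cset, n = n)
  delta <- estimate_delta(full_fit$beta_full[spec$gamma_idx],
                          spec$gamma_null, n)
  dd <- estimate_delta_outer(delta, asym,
                             if (variant == "ordinal") "ordinal" else "continuous")
  q <- build_Q(asym, dd, variant)
  qa <- structure(list(a = q$a[adm], P = q$P[adm, adm, drop = FALSE]),
                  class = "q_problem")
  w <- minimize_weights(qa)
  fm <- fma_combine(fits[adm], w, asym, delta)
  kap <- kappa_covariance(asym, variant)
  intervals <- rbind(fma_interval(fm, kap, n, alpha,
                                  if (variant == "ordinal") "FMAord" else "FMAordcont"),
                     full_model_interval(full_fit$mu_hat, kap, n, alpha))
  gof <- gof_statistics(pf$rho, full_fit, fm, asym, n)
  structure(list(polychoric = pf, fits = fits, weights = fm$weights,
                 fma = fm, intervals = intervals, gof = gof,
                 asym = asym, method = method, variant = variant,
                 n = n),
            class = "fma_sem")
}

#' @export
print.fma_sem <- function(x, ...) {
  cat(sprintf("Model-averaged ordinal SEM (%s, %s criterion), n = %d\n",
              x$method, x$variant, x$n))
  cat("  weights:",
      paste(sprintf("%s = %.3f", names(x$weights), x$weights), collapse = ", "),
      "\n")
  cat("  intervals (averaged estimator):\n")
  print(x$intervals[x$intervals$method != "full", ], digits = 4)
  print(x$gof)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: \code{fit} (per-candidate estimates and fit statistics),
#' \code{average} (weights, averaged estimates and intervals), \code{gof}
#' (fit statistics only) and \code{simulate} (a Monte Carlo cell).  All
#' results are written as JSON; numeric output uses six significant
#' digits.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (invisibly); artifacts are written to
#'   \code{--out}.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) {
    cat("usage: semfma <fit|average|gof|simulate> [options]\n")
    return(invisible(1L))
  }
  cmd <- argv[1L]
  opts <- parse_cli_options(argv[-1L])
  seed <- as.integer(opts$seed %||% 1)
  out_path <- opts$out %||% "semfma_out.json"
  status <- tryCatch({
    if (cmd == "simulate") {
      design <- simulation_design(
        framework = opts$framework %||% "local",
        zeta = as.numeric(opts$zeta %||% 0),
        n = as.integer(opts$n %||% 150),
        thresholds = opts$thresholds %||% "moderate",
        n_replications = as.integer(opts$reps %||% 100),
        base_seed = seed,
        ls_method = opts$method %||% "DWLS",
        alpha = as.numeric(opts$alpha %||% 0.05))
      sim <- run_simulation(design)
      s <- summarize_simulation(sim)
      payload <- list(schema = "semfma/simulate/v1", seed = seed,
                      design = unclass(design),
                      coverage = s$coverage, rejection = s$rejection,
                      accuracy = s$accuracy)
      jsonlite::write_json(payload, out_path, auto_unbox = TRUE,
                           digits = 6, dataframe = "rows")
      if (!is.null(opts$csv))
        utils::write.csv(s$coverage, opts$csv, row.names = FALSE)
      0L
    } else {
      if (is.null(opts$data) || is.null(opts$model))
        stop("commands fit/average/gof need --data and --model")
      data <- read_ordinal_csv(opts$data)
      mdl <- read_model_config(opts$model)
      set.seed(seed)
      if (cmd == "fit") {
        pf <- polychoric(data, upsilon = TRUE)
        weight <- build_weight_matrix(pf$upsilon, opts$method %||% "DWLS")
        fits <- fit_candidate_set(pf$rho, weight, mdl$spec, mdl$cset, data$n)
        payload <- list(schema = "semfma/fit/v1", seed = seed,
                        n = data$n,
                        candidates = lapply(fits, function(f) {
                          r <- length(pf$rho) - length(f$free)
                          xs <- sum(diag(xi_single(f, mdl$spec, weight$V,
                                                   pf$upsilon)))
                          Ts <- t_full(pf$rho, f$sigma_hat, weight$V, data$n)
                          list(id = f$id, estimates = as.list(f$beta_hat),
                               F_ls = f$F_ls, converged = f$converged,
                               admissible = f$admissible,
                               T_stat = Ts,
                               robust_rmsea = robust_rmsea(Ts, xs, r, data$n))
                        }))
        jsonlite::write_json(payload, out_path, auto_unbox = TRUE, digits = 6)
        0L
      } else {
        variant <- if (identical(opts$variant, "continuous-assumption"))
          "continuous" else "ordinal"
        res <- fma_sem(data, mdl$spec, mdl$cset,
                       method = opts$method %||% "DWLS",
                       alpha = as.numeric(opts$alpha %||% 0.05),
                       variant = variant)
        payload <- list(schema = paste0("semfma/", cmd, "/v1"), seed = seed,
                        n = data$n, weights = as.list(res$weights))
        if (cmd == "average") {
          payload$mu_bar <- as.list(res$fma$mu_bar)
          payload$intervals <- res$intervals
        }
        payload$gof <- list(
          r = res$gof$r,
          full = res$gof$full[c("T", "T_scaled", "p_scaled",
                                "T_adjusted", "df_adjusted", "p_adjusted")],
          averaged = res$gof$fma[c("T", "T_scaled", "p_scaled",
                                   "T_adjusted", "df_adjusted", "p_adjusted")])
        jsonlite::write_json(payload, out_path, auto_unbox = TRUE,
                             digits = 6, dataframe = "rows")
        0L
      }
    }
  }, semfma_fma_inadmissible = function(e) {
    message("error: ", conditionMessage(e)); 2L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}
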