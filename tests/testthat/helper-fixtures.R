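# Shared fixtures for the test suite.  Everything is generated in code;
# expensive simulation cells are cached so several tests can reuse them.

study <- simulation_model()

study_design <- function(...) simulation_design(...)

# population at the narrow truth (zeta = 0, n = 150, moderate thresholds)
narrow_pop <- population_parameters(
  simulation_design(zeta = 0, n = 150, n_replications = 1), study)

# a small, admissible full pipeline state shared by fma/inference/gof tests
pipeline_state <- local({
  cache <- NULL
  function(method = "DWLS") {
    key <- method
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    d <- simulation_design(zeta = 0.15, n = 600, n_replications = 1,
                           base_seed = 31400)
    pop <- population_parameters(d, study)
    dat <- generate_dataset(d, 1, pop)
    pf <- polychoric(dat, upsilon = TRUE)
    weight <- build_weight_matrix(pf$upsilon, method)
    fits <- fit_candidate_set(pf$rho, weight, study$spec, study$cset, d$n)
    asym <- compute_asymptotics(study$spec, fits$M4$beta_full, weight,
                                pf$upsilon, study$cset, n = d$n)
    delta <- estimate_delta(fits$M4$beta_full[study$spec$gamma_idx],
                            study$spec$gamma_null, d$n)
    value <- list(design = d, pop = pop, data = dat, pf = pf,
                  weight = weight, fits = fits, asym = asym, delta = delta)
    cache <<- list(key = key, value = value)
    value
  }
})

# Monte Carlo cells used by the acceptance tests; cached across test files
sim_cell <- local({
  cache <- new.env(parent = emptyenv())
  function(.key, ...) {
    if (!is.null(cache[[.key]])) return(cache[[.key]])
    design <- simulation_design(...)
    cache[[.key]] <- run_simulation(design, study)
    cache[[.key]]
  }
})

uls_fixture <- function(m) build_weight_matrix(diag(m), "ULS")

# draw a random admissible parameter vector near the study population
random_admissible_beta <- function(pop = narrow_pop) {
  beta <- pop$beta
  beta <- beta + runif(length(beta), -0.05, 0.05)
  beta
}
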