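# Dose-allocation engines.  All four designs share the allocation criterion
# argmin_k |Rhat(d_k) - theta| and differ only in how Rhat is formed:
#   pocrm_select - plug-in curve under the maximum-posterior ordering
#   bma_pocrm    - mean of the mixture posterior of the toxicity probability
#   bma_zhang    - posterior-weighted average of per-ordering point estimates
#                  (provably identical to bma_pocrm; kept as an independent
#                  code path so the equivalence can be tested)
#   bma_wages    - model-averages the per-ordering recommended doses instead
#                  of the estimates; it produces no averaged toxicity curve.

#' Design configuration
#'
#' @param design one of `"pocrm_select"`, `"bma_pocrm"`, `"bma_zhang"`,
#'   `"bma_wages"`.
#' @param theta target toxicity rate in (0, 1).
#' @param cohort_size patients per cohort.
#' @param n_cohorts number of cohorts (no other stopping rule is applied).
#' @param start_dose first administered dose; defaults to dose 1.
#' @param allow_skipping if `FALSE`, an allocation may be at most one untried
#'   level above the highest tried level in each drug margin (requires the
#'   spec to carry a [dose_grid()]).  The default `TRUE` applies the pure
#'   allocation criterion.
#' @param tie_break ordering-selection tie-break passed to
#'   [pocrm_point_estimates()].
#' @return object of class `design_config`.
#' @export
design_config <- function(design = c("pocrm_select", "bma_pocrm",
                                     "bma_zhang", "bma_wages"),
                          theta, cohort_size = 1L, n_cohorts = 20L,
                          start_dose = 1L, allow_skipping = TRUE,
                          tie_break = "last") {
  design <- match.arg(design)
  stopifnot(theta > 0, theta < 1, cohort_size >= 1, n_cohorts >= 1,
            start_dose >= 1)
  structure(list(design = design, theta = theta,
                 cohort_size = as.integer(cohort_size),
                 n_cohorts = as.integer(n_cohorts),
                 start_dose = as.integer(start_dose),
                 allow_skipping = isTRUE(allow_skipping),
                 tie_break = tie_break),
            class = "design_config")
}

#' Allocate the next dose
#'
#' Minimises the absolute distance between the estimated toxicity
#' probabilities and the target rate.  Ties go to the lower dose index (the
#' more conservative combination).  When `tried` and `grid` are supplied and
#' `allow_skipping = FALSE`, candidate doses are restricted to at most one
#' level above the highest tried level in each drug margin.
#'
#' @param estimates per-dose toxicity estimates in (0, 1).
#' @param theta target toxicity rate.
#' @param grid optional [dose_grid()] (needed for the no-skipping rule).
#' @param tried optional integer vector of doses already administered.
#' @param allow_skipping see [design_config()].
#' @return dose index.
#' @export
allocate_next_dose <- function(estimates, theta, grid = NULL, tried = NULL,
                               allow_skipping = TRUE) {
  if (length(estimates) == 0) stop("empty estimate vector")
  candidates <- seq_along(estimates)
  if (!allow_skipping) {
    if (is.null(grid)) stop("no-skipping rule requires a dose_grid")
    xy <- dose_coords(grid)
    rmax <- if (length(tried)) max(xy$row[tried]) else 0L
    cmax <- if (length(tried)) max(xy$col[tried]) else 0L
    ok <- xy$row <= rmax + 1L & xy$col <= cmax + 1L
    candidates <- candidates[ok]
  }
  dist <- abs(estimates[candidates] - theta)
  candidates[which.min(dist)]   # which.min takes the first = lowest dose
}

#' One design update: estimates (when defined) and the next dose
#'
#' Runs the inference appropriate to the configured design on the current
#' data and applies the allocation criterion.
#'
#' @param design a [design_config()].
#' @param data a [trial_data()].
#' @param spec a [partial_order_spec()].
#' @param skeleton monotone skeleton vector.
#' @param config a [working_model_config()].
#' @return list with elements `estimates` (per-dose toxicity estimates, or
#'   `NULL` for `bma_wages`, which has none), `next_dose`, `ordering_post`,
#'   `selected_m` (POCRM only), and for `bma_wages` the recommendation
#'   probabilities `pi`.
#' @export
recommend <- function(design, data, spec, skeleton, config) {
  stopifnot(inherits(design, "design_config"))
  grid <- spec$grid
  tried <- which(data$n > 0)
  alloc <- function(est) allocate_next_dose(est, design$theta, grid, tried,
                                            design$allow_skipping)
  switch(design$design,
    pocrm_select = {
      fit <- pocrm_point_estimates(data, spec, skeleton, config,
                                   tie_break = design$tie_break)
      list(estimates = fit$estimates, next_dose = alloc(fit$estimates),
           ordering_post = fit$ordering_post, selected_m = fit$selected_m)
    },
    bma_pocrm = {
      q <- posterior_quantities(data, spec, skeleton, config)
      est <- as.vector(q$ordering_post %*% q$est)
      list(estimates = est, next_dose = alloc(est),
           ordering_post = q$ordering_post, selected_m = NULL)
    },
    bma_zhang = {
      # average the per-ordering point estimates (independent route)
      q <- posterior_quantities(data, spec, skeleton, config)
      est <- numeric(spec$K)
      for (m in seq_len(spec$M))
        est <- est + q$ordering_post[m] * q$est[m, ]
      list(estimates = est, next_dose = alloc(est),
           ordering_post = q$ordering_post, selected_m = NULL)
    },
    bma_wages = {
      q <- posterior_quantities(data, spec, skeleton, config)
      pi_k <- numeric(spec$K)
      for (m in seq_len(spec$M)) {
        rec_m <- alloc(q$est[m, ])
        pi_k[rec_m] <- pi_k[rec_m] + q$ordering_post[m]
      }
      list(estimates = NULL, next_dose = which.max(pi_k),
           ordering_post = q$ordering_post, selected_m = NULL, pi = pi_k)
    })
}
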