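# Sequential-trial simulation and operating characteristics.
#
# Outcomes are pre-drawn as per-dose response streams (the j-th patient ever
# assigned dose k receives entry j of stream k).  Running several designs on
# the same streams therefore exposes them to identical patient responses -
# the common-random-numbers device that makes design comparisons fair and
# reduces Monte Carlo variance.

#' Define a simulation scenario
#'
#' @param true_R per-dose true toxicity probabilities in (0, 1).
#' @param theta target toxicity rate.
#' @param grid optional [dose_grid()].
#' @param label optional scenario name.
#' @return object of class `scenario`.
#' @export
scenario <- function(true_R, theta, grid = NULL, label = "") {
  stopifnot(all(true_R > 0), all(true_R < 1), theta > 0, theta < 1)
  if (!is.null(grid)) stopifnot(inherits(grid, "dose_grid"),
                                grid$K == length(true_R))
  structure(list(true_R = true_R, theta = theta, grid = grid, label = label),
            class = "scenario")
}

# per-dose Bernoulli outcome streams for one simulated trial
draw_streams <- function(true_R, n_patients) {
  K <- length(true_R)
  matrix(stats::rbinom(n_patients * K, 1L,
                       rep(true_R, each = n_patients)),
         nrow = n_patients, ncol = K)
}

#' Simulate one sequential trial
#'
#' Runs a design from an empty trial for `n_cohorts` cohorts.  Outcomes come
#' from `streams` when supplied (see [draw_streams] semantics above),
#' otherwise they are drawn Bernoulli(true_R) under `seed`.
#'
#' @param scen a [scenario()].
#' @param design a [design_config()].
#' @param spec,skeleton,config the partial order, skeleton and working model.
#' @param seed integer seed (used only when `streams` is `NULL`).
#' @param streams optional matrix of pre-drawn 0/1 outcomes, one column per
#'   dose; must hold at least `n_cohorts * cohort_size` rows.
#' @return object of class `trial_record`: `allocations` and `outcomes` per
#'   cohort (a cohort's outcome is its vector of patient outcomes),
#'   `estimates` (matrix, row c = estimates after cohort c), `est0`
#'   (pre-trial estimates), `selected_m`/`selected_m0` (POCRM only),
#'   `final_recommendation`, the final `data`, and the configuration used.
#' @export
run_trial <- function(scen, design, spec, skeleton, config,
                      seed = NULL, streams = NULL) {
  stopifnot(inherits(scen, "scenario"), inherits(design, "design_config"))
  n_pat <- design$n_cohorts * design$cohort_size
  if (is.null(streams)) {
    if (is.null(seed)) stop("either a seed or pre-drawn streams is required")
    set.seed(seed)
    streams <- draw_streams(scen$true_R, n_pat)
  }
  if (nrow(streams) < n_pat) stop("outcome streams too short for the trial")
  K <- spec$K
  data <- trial_data(rep(0L, K), rep(0L, K),
                     history = data.frame(dose = integer(0), dlt = integer(0)))
  fit0 <- recommend(design, data, spec, skeleton, config)
  est0 <- if (is.null(fit0$estimates)) rep(NA_real_, K) else fit0$estimates
  used <- rep(0L, K)                     # stream positions consumed per dose
  allocations <- integer(design$n_cohorts)
  outcomes <- matrix(NA_integer_, design$n_cohorts, design$cohort_size)
  estimates <- matrix(NA_real_, design$n_cohorts, K)
  selected_m <- rep(NA_integer_, design$n_cohorts)
  next_dose <- design$start_dose
  for (cc in seq_len(design$n_cohorts)) {
    allocations[cc] <- next_dose
    for (p in seq_len(design$cohort_size)) {
      used[next_dose] <- used[next_dose] + 1L
      out <- streams[used[next_dose], next_dose]
      outcomes[cc, p] <- out
      data <- add_patient(data, next_dose, out)
    }
    fit <- recommend(design, data, spec, skeleton, config)
    if (!is.null(fit$estimates)) estimates[cc, ] <- fit$estimates
    if (!is.null(fit$selected_m)) selected_m[cc] <- fit$selected_m
    next_dose <- fit$next_dose
  }
  structure(list(allocations = allocations,
                 outcomes = if (design$cohort_size == 1L)
                   as.vector(outcomes) else outcomes,
                 estimates = estimates, est0 = est0,
                 selected_m = selected_m, selected_m0 = fit0$selected_m,
                 final_recommendation = next_dose,
                 data = data, design = design, scenario = scen, seed = seed),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s, %d cohorts, recommended d%d\n",
              x$design$design, length(x$allocations), x$final_recommendation))
  invisible(x)
}

#' Operating characteristics of a set of simulated trials
#'
#' Summarises recommendation accuracy, allocation safety and estimation
#' coherency: PCS (proportion of trials recommending a dose whose true
#' toxicity equals the target exactly), PAS (true toxicity within
#' `[theta - 0.1, theta]`), POTS (true toxicity above `1.1 * theta`), NPTOT
#' (mean number of patients treated at such overly toxic doses), the
#' fraction of trials with at least one estimation incoherency, the mean
#' number of cohorts with an event, the largest event magnitude, and the
#' RMSE of the final estimates against the true curve.
#'
#' @param records list of `trial_record`s from one design on one scenario.
#' @param scen the [scenario()] they were run on.
#' @param spec a [partial_order_spec()] (for the comparability sets).
#' @param threshold,sided incoherency detection settings
#'   (see [detect_incoherencies()]).
#' @param overdose_factor a dose is overly toxic when its true toxicity
#'   exceeds `overdose_factor * theta` (default 1.1).
#' @return object of class `operating_characteristics` (a list of metrics).
#' @export
operating_characteristics <- function(records, scen, spec,
                                      threshold = 0.001, sided = "two",
                                      overdose_factor = 1.1) {
  stopifnot(length(records) > 0)
  theta <- scen$theta; true_R <- scen$true_R
  correct <- abs(true_R - theta) < 1e-9
  acceptable <- true_R >= theta - 0.1 & true_R <= theta
  toxic <- true_R > overdose_factor * theta
  recs <- vapply(records, function(r) r$final_recommendation, integer(1))
  nptot <- vapply(records, function(r) sum(r$data$n[toxic]), numeric(1))
  sets <- comparability_sets(spec)
  audits <- lapply(records, function(r) {
    if (all(is.na(r$estimates))) return(NULL)      # design without estimates
    audit_trial(r, sets, threshold = threshold, sided = sided)
  })
  audits <- Filter(Negate(is.null), audits)
  has_audit <- length(audits) > 0
  rmse <- vapply(records, function(r) {
    fin <- r$estimates[nrow(r$estimates), ]
    if (all(is.na(fin))) NA_real_ else sqrt(mean((fin - true_R)^2))
  }, numeric(1))
  structure(list(
    n_trials = length(records),
    pcs = mean(correct[recs]),
    pas = mean(acceptable[recs]),
    pots = mean(toxic[recs]),
    nptot = mean(nptot),
    incoherency_trial_fraction = if (has_audit)
      mean(vapply(audits, function(a) a$n_cohorts_with_event > 0, logical(1)))
      else NA_real_,
    mean_incoherent_cohorts = if (has_audit)
      mean(vapply(audits, function(a) a$n_cohorts_with_event, numeric(1)))
      else NA_real_,
    max_incoherent_magnitude = if (has_audit)
      max(vapply(audits, function(a) a$max_magnitude, numeric(1)))
      else NA_real_,
    rmse = mean(rmse)),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf(paste0("<operating_characteristics> %d trials\n",
                     "  PCS %.3f  PAS %.3f  POTS %.3f  NPTOT %.2f\n",
                     "  incoherent trials %.3f  mean incoherent cohorts %.3f",
                     "  RMSE %.4f\n"),
              x$n_trials, x$pcs, x$pas, x$pots, x$nptot,
              x$incoherency_trial_fraction, x$mean_incoherent_cohorts,
              x$rmse))
  invisible(x)
}

# draw one monotone toxicity matrix as a vector in linear dose order
random_monotone_surface <- function(grid, lo, hi) {
  R <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  incr <- matrix(stats::rexp(grid$n_rows * grid$n_cols), grid$n_rows)
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    base <- max(if (i > 1) R[i - 1, j] else 0, if (j > 1) R[i, j - 1] else 0)
    R[i, j] <- base + incr[i, j]
  }
  R <- lo + (hi - lo) * R / (max(R) * 1.05)     # squash into (lo, hi)
  as.vector(t(R))                               # row-major = linear index
}

n_consistent_orderings <- function(true_R, spec) {
  sum(apply(spec$orderings, 1L, function(o) all(diff(true_R[o]) > 0)))
}

#' Generate synthetic scenario families
#'
#' Draws monotone toxicity surfaces with controlled structure: families
#' `zero_correct`, `one_correct` and `two_correct` contain exactly 0, 1 or 2
#' candidate orderings that rank-sort the true toxicities (duplicated
#' candidate orderings count separately), and carry exactly one dose with
#' true toxicity equal to the target; `all_toxic` surfaces lie entirely
#' above `1.1 * theta`; `all_safe` surfaces lie entirely below `theta`
#' (so no correct selection exists).
#'
#' @param grid a [dose_grid()].
#' @param theta target toxicity rate.
#' @param family scenario family (see above).
#' @param spec a [partial_order_spec()]; needed to count consistent
#'   orderings for the `*_correct` families.
#' @param n_scenarios how many scenarios to draw.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per scenario.
#' @return list of [scenario()]s.
#' @export
generate_scenarios <- function(grid, theta,
                               family = c("zero_correct", "one_correct",
                                          "two_correct", "all_toxic",
                                          "all_safe"),
                               spec = NULL, n_scenarios = 1L, seed = 1L,
                               max_tries = 5000L) {
  family <- match.arg(family)
  if (family %in% c("zero_correct", "one_correct", "two_correct") &&
      is.null(spec))
    stop("the *_correct families need a partial_order_spec")
  set.seed(seed)
  want <- switch(family, zero_correct = 0L, one_correct = 1L,
                 two_correct = 2L, NA_integer_)
  out <- vector("list", n_scenarios)
  for (s in seq_len(n_scenarios)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      if (family == "all_toxic") {
        lo <- min(1.1 * theta + 0.05, 0.9); hi <- 0.95
        true_R <- random_monotone_surface(grid, lo, hi)
        ok <- min(true_R) > 1.1 * theta
      } else if (family == "all_safe") {
        true_R <- random_monotone_surface(grid, 0.01, theta - 0.01)
        ok <- max(true_R) < theta
      } else {
        true_R <- random_monotone_surface(grid, 0.02, 0.9)
        # anchor the dose nearest the target exactly at it, keeping
        # within-margin monotonicity
        k <- which.min(abs(true_R - theta))
        cand <- true_R; cand[k] <- theta
        xy <- dose_coords(grid)
        mono <- TRUE
        for (kk in seq_len(grid$K)) {
          i <- xy$row[kk]; j <- xy$col[kk]
          if (i < grid$n_rows && cand[grid$n_cols * i + j] <= cand[kk])
            mono <- FALSE
          if (j < grid$n_cols && cand[kk + 1L] <= cand[kk]) mono <- FALSE
        }
        ok <- mono && n_consistent_orderings(cand, spec) == want &&
          sum(abs(cand - theta) < 1e-9) == 1L
        if (ok) true_R <- cand
      }
      if (ok) break
    }
    if (!ok) stop("could not generate a '", family, "' scenario for this grid")
    out[[s]] <- scenario(true_R, theta, grid,
                         label = sprintf("%s_%d", family, s))
  }
  out
}

#' Compare designs on shared outcome streams
#'
#' Runs each design `n_reps` times on every scenario, with the per-dose
#' outcome streams of each replicate shared across designs (common random
#' numbers), and aggregates operating characteristics into a tidy table.
#'
#' @param scenarios list of [scenario()]s.
#' @param designs character vector of design names (see [design_config()]).
#' @param spec,skeleton,config the partial order, skeleton, working model.
#' @param n_reps replicates per scenario.
#' @param seed master seed; every stream is derived from it.
#' @param cohort_size,n_cohorts,start_dose,allow_skipping trial settings
#'   shared by all designs.
#' @param threshold incoherency detection threshold.
#' @return data.frame with columns `scenario`, `design`, `metric`, `value`;
#'   cross-scenario arithmetic means are appended as scenario `"mean"`.
#' @export
compare_designs <- function(scenarios, designs, spec, skeleton, config,
                            n_reps = 100L, seed = 1L,
                            cohort_size = 1L, n_cohorts = 20L,
                            start_dose = 1L, allow_skipping = TRUE,
                            threshold = 0.001) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  n_pat <- n_cohorts * cohort_size
  rows <- NULL
  ocs <- list()
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    lab <- if (nzchar(scen$label)) scen$label else paste0("scenario_", si)
    set.seed((seed + 7919L * si) %% .Machine$integer.max)
    streams <- lapply(seq_len(n_reps),
                      function(r) draw_streams(scen$true_R, n_pat))
    for (d in designs) {
      dc <- design_config(d, theta = scen$theta, cohort_size = cohort_size,
                          n_cohorts = n_cohorts, start_dose = start_dose,
                          allow_skipping = allow_skipping)
      recs <- lapply(seq_len(n_reps), function(r)
        run_trial(scen, dc, spec, skeleton, config, streams = streams[[r]]))
      oc <- operating_characteristics(recs, scen, spec, threshold = threshold)
      ocs[[paste(lab, d, sep = "|")]] <- oc
      vals <- unlist(oc[c("pcs", "pas", "pots", "nptot",
                          "incoherency_trial_fraction",
                          "mean_incoherent_cohorts",
                          "max_incoherent_magnitude", "rmse")])
      rows <- rbind(rows, data.frame(scenario = lab, design = d,
                                     metric = names(vals),
                                     value = unname(vals)))
    }
  }
  for (d in designs) {
    sub <- rows[rows$design == d, ]
    agg <- stats::aggregate(value ~ metric, data = sub, FUN = mean)
    rows <- rbind(rows, data.frame(scenario = "mean", design = d,
                                   metric = agg$metric, value = agg$value))
  }
  rownames(rows) <- NULL
  rows
}
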