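# Estimation-coherency auditing and the closed-form 2x2 condition checkers.
#
# After a non-DLT at dose i, no estimate at a dose that is less (or more)
# toxic than i under *every* candidate ordering should rise; after a DLT,
# none should fall.  Updates violating this are "estimation incoherencies".
# A small detection threshold guards against quadrature noise.

#' Detect estimation incoherencies in one estimate update
#'
#' Compares the toxicity estimates before and after one patient (cohort)
#' outcome.  Two-sided auditing checks every dose in
#' `nu[[i]] U xi[[i]]` of the administered dose i: after a non-DLT any rise
#' beyond `threshold` is flagged; after a DLT any fall.  One-sided auditing
#' restricts to `nu[[i]]` after a non-DLT and `xi[[i]]` after a DLT.
#'
#' @param prev_estimates,new_estimates per-dose estimate vectors before and
#'   after the update.
#' @param administered_dose dose index given to the new patient.
#' @param outcome 0/1 DLT indicator.
#' @param sets [comparability_sets()] of the partial order.
#' @param threshold minimum absolute wrong-direction change to flag
#'   (default 0.001, guarding against numerical noise).
#' @param sided `"two"` (default) or `"one"`.
#' @return data.frame with one row per flagged dose: `violating_dose`,
#'   `direction` (`"rise-after-nonDLT"` or `"fall-after-DLT"`),
#'   `magnitude` (absolute wrong-direction change).  Zero rows when the
#'   update is coherent.
#' @export
detect_incoherencies <- function(prev_estimates, new_estimates,
                                 administered_dose, outcome, sets,
                                 threshold = 0.001,
                                 sided = c("two", "one")) {
  sided <- match.arg(sided)
  K <- sets$K
  if (length(prev_estimates) != K || length(new_estimates) != K)
    stop("estimate vectors must match the number of doses")
  if (administered_dose < 1 || administered_dose > K)
    stop("administered dose out of range")
  stopifnot(outcome %in% c(0, 1), threshold >= 0)
  i <- administered_dose
  watch <- if (sided == "two") {
    c(sets$nu[[i]], sets$xi[[i]])
  } else if (outcome == 0) sets$nu[[i]] else sets$xi[[i]]
  delta <- new_estimates - prev_estimates
  if (outcome == 0) {
    bad <- watch[delta[watch] > threshold]
    direction <- "rise-after-nonDLT"
  } else {
    bad <- watch[delta[watch] < -threshold]
    direction <- "fall-after-DLT"
  }
  data.frame(violating_dose = as.integer(bad),
             direction = rep(direction, length(bad)),
             magnitude = abs(delta[bad]))
}

#' Audit a full trial for estimation incoherencies
#'
#' Applies [detect_incoherencies()] to every sequential update recorded in a
#' trial, and notes, per event, whether the POCRM's selected ordering
#' changed at that update (the mechanism behind POCRM incoherencies; under a
#' constant selected ordering the single-model CRM update is coherent).
#'
#' @param record a `trial_record` as produced by [run_trial()] or
#'   [replay_trial()]: needs `allocations`, `outcomes`, the estimate matrix
#'   `estimates` (row c = estimates after cohort c; row 0 is supplied as
#'   `est0`, the pre-trial estimates), and optionally `selected_m`.
#' @param spec a [partial_order_spec()] (or precomputed
#'   [comparability_sets()]).
#' @param threshold,sided see [detect_incoherencies()].
#' @return object of class `coherency_report`: list with `events`
#'   (data.frame: `cohort`, `administered_dose`, `outcome`,
#'   `violating_dose`, `direction`, `magnitude`, `ordering_changed`),
#'   `n_cohorts`, `n_cohorts_with_event`, `max_magnitude`,
#'   `fraction_coinciding_with_ordering_change`.
#' @export
audit_trial <- function(record, spec, threshold = 0.001,
                        sided = c("two", "one")) {
  sided <- match.arg(sided)
  sets <- if (inherits(spec, "comparability_sets")) spec else
    comparability_sets(spec)
  n_up <- length(record$allocations)
  prev <- record$est0
  events <- NULL
  for (cc in seq_len(n_up)) {
    new <- record$estimates[cc, ]
    ev <- detect_incoherencies(prev, new, record$allocations[cc],
                               record$outcomes[cc], sets, threshold, sided)
    if (nrow(ev)) {
      ev$cohort <- cc
      ev$administered_dose <- record$allocations[cc]
      ev$outcome <- record$outcomes[cc]
      ev$ordering_changed <- if (!is.null(record$selected_m)) {
        prev_m <- if (cc == 1L) record$selected_m0 else record$selected_m[cc - 1L]
        !is.null(prev_m) && !is.na(prev_m) && record$selected_m[cc] != prev_m
      } else NA
      events <- rbind(events, ev)
    }
    prev <- new
  }
  if (is.null(events))
    events <- data.frame(violating_dose = integer(0), direction = character(0),
                         magnitude = numeric(0), cohort = integer(0),
                         administered_dose = integer(0), outcome = integer(0),
                         ordering_changed = logical(0))
  structure(list(
    events = events,
    n_cohorts = n_up,
    n_cohorts_with_event = length(unique(events$cohort)),
    max_magnitude = if (nrow(events)) max(events$magnitude) else 0,
    fraction_coinciding_with_ordering_change =
      if (nrow(events) && !all(is.na(events$ordering_changed)))
        mean(events$ordering_changed) else NA_real_),
    class = "coherency_report")
}

#' @export
print.coherency_report <- function(x, ...) {
  cat(sprintf("<coherency_report> %d/%d cohorts with events, max magnitude %.4f\n",
              x$n_cohorts_with_event, x$n_cohorts, x$max_magnitude))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

# candidate parameter values log(R_k)/log(alpha) under the two 2x2 orderings:
# ordering 1 = d1-d2-d3-d4 (identity), ordering 2 = d1-d3-d2-d4 (swap 2,3)
a_sets_2x2 <- function(skeleton, true_R) {
  if (length(skeleton) != 4 || length(true_R) != 4)
    stop("2x2 condition checkers need 4 skeleton values and 4 true probabilities")
  if (any(skeleton <= 0) || any(skeleton >= 1) ||
      any(true_R <= 0) || any(true_R >= 1))
    stop("skeleton values and true probabilities must lie in (0,1)")
  A1 <- log(true_R) / log(skeleton)
  A2 <- log(true_R) / log(skeleton[c(1, 3, 2, 4)])
  list(A1 = A1, A2 = A2,
       a1min = min(A1), a1max = max(A1),
       a2min = min(A2), a2max = max(A2))
}

#' Sufficient condition for POCRM estimation coherency on a 2x2 grid
#'
#' Evaluates, for the plain power model `psi = alpha^a` with the two
#' admissible 2x2 orderings at equal prior weight, the pair of inequalities
#' `alpha3^(a2min) <= alpha2^(a1max)` and `alpha3^(a1min) <= alpha2^(a2max)`
#' where the extrema are taken over the candidate parameter sets
#' `log(R_k)/log(alpha)` under each ordering.  When the condition holds, the
#' POCRM's estimate updates stay coherent along every outcome path (checked
#' by exhaustive enumeration in the tests).
#'
#' @param skeleton 4-vector, increasing in (0,1).
#' @param true_R 4-vector of true toxicity probabilities in (0,1).
#' @return list: `coherent` flag plus all intermediate quantities.
#' @export
pocrm_2x2_condition <- function(skeleton, true_R) {
  s <- a_sets_2x2(skeleton, true_R)
  lhs1 <- skeleton[3]^s$a2min; rhs1 <- skeleton[2]^s$a1max
  lhs2 <- skeleton[3]^s$a1min; rhs2 <- skeleton[2]^s$a2max
  c(list(coherent = lhs1 <= rhs1 && lhs2 <= rhs2,
         lhs1 = lhs1, rhs1 = rhs1, lhs2 = lhs2, rhs2 = rhs2), s)
}

#' Sufficient condition for BMA-POCRM estimation coherency on a 2x2 grid
#'
#' Mechanical evaluation of the model-averaged analogue of
#' [pocrm_2x2_condition()]: two inequalities bounding `1/(1 - log alpha_1)`
#' and `1/(1 - log alpha_4)` by minima of ratios built from the skeleton and
#' the candidate parameter extrema, with intermediate quantities
#' `U1..U4`.  The published statement of `U4` references a parameter
#' maximum with an index outside the two-ordering setting; by the pattern of
#' `U1..U3` this is read as the ordering-1 maximum (`u4_hat = "a1max"`, the
#' default); set `u4_hat = "a2max"` for the alternative reading.
#'
#' @inheritParams pocrm_2x2_condition
#' @param u4_hat which parameter maximum enters `U4`.
#' @return list: `coherent` flag plus all intermediate quantities.
#' @export
bma_2x2_condition <- function(skeleton, true_R, u4_hat = c("a1max", "a2max")) {
  u4_hat <- match.arg(u4_hat)
  s <- a_sets_2x2(skeleton, true_R)
  a1 <- skeleton[1]; a2 <- skeleton[2]; a3 <- skeleton[3]; a4 <- skeleton[4]
  U <- function(alpha, ahatmax)
    (1 - 2 * log(alpha)) / (1 - log(alpha)) * ahatmax - 1 / (1 - log(alpha))^2
  U1 <- U(a1, s$a2max); U2 <- U(a1, s$a1max)
  U3 <- U(a4, s$a2max)
  U4 <- U(a4, if (u4_hat == "a1max") s$a1max else s$a2max)
  den1 <- 1 - a2^s$a1min / a3^s$a2max
  den2 <- 1 - a2^s$a2min / a3^s$a1max
  rhs_lo <- min(a3^s$a2min * (a3^U1 - 1) / den1,
                a3^s$a1min * (a3^U2 - 1) / den2)
  rhs_hi <- min(a3^s$a2min * (a3^U3 - 1) / den1,
                a3^s$a1min * (a3^U4 - 1) / den2)
  ineq1 <- 1 / (1 - log(a1)) <= rhs_lo
  ineq2 <- 1 / (1 - log(a4)) <= rhs_hi
  c(list(coherent = ineq1 && ineq2, ineq1 = ineq1, ineq2 = ineq2,
         lhs_lo = 1 / (1 - log(a1)), rhs_lo = rhs_lo,
         lhs_hi = 1 / (1 - log(a4)), rhs_hi = rhs_hi,
         U1 = U1, U2 = U2, U3 = U3, U4 = U4, u4_hat = u4_hat), s)
}

#' Check the incoherence-magnitude bound on paired events
#'
#' When the POCRM and the model-averaged design are both incoherent at the
#' same update, the model-averaged magnitude is bounded by the POCRM
#' magnitude scaled by `1 / (1 - log alpha_K)` (the top skeleton value).
#' Events are paired by cohort; cohorts present in only one design's event
#' list are skipped (and counted in `n_unpaired`).
#'
#' @param skeleton skeleton vector (top value enters the bound).
#' @param events_pocrm,events_bma event data.frames from [audit_trial()]
#'   reports on the same data.
#' @return list: `ok` (no violation), `bound_factor`, `pairs` data.frame
#'   (`cohort`, `M_S`, `M_A`, `bound`, `violated`), `n_unpaired`.
#' @export
magnitude_bound_check <- function(skeleton, events_pocrm, events_bma) {
  factor <- 1 / (1 - log(skeleton[length(skeleton)]))
  mag_by_cohort <- function(ev) {
    if (!nrow(ev)) return(numeric(0))
    vapply(split(ev$magnitude, ev$cohort), max, numeric(1))
  }
  ms <- mag_by_cohort(events_pocrm)
  ma <- mag_by_cohort(events_bma)
  shared <- intersect(names(ms), names(ma))
  pairs <- data.frame(cohort = as.integer(shared),
                      M_S = unname(ms[shared]), M_A = unname(ma[shared]))
  pairs$bound <- factor * pairs$M_S
  pairs$violated <- pairs$M_A > pairs$bound
  list(ok = !any(pairs$violated), bound_factor = factor, pairs = pairs,
       n_unpaired = length(ms) + length(ma) - 2L * length(shared))
}
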