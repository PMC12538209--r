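# Replay of a completed trial from per-dose response streams.
#
# A completed study reports per-dose patient and DLT counts.  To re-run
# model-guided escalation on those data, each dose gets a fixed ordered
# response stream: its first n_j entries are a seeded random permutation of
# the outcomes actually observed there, and the remainder are imputed by
# Beta-Bernoulli sampling from the posterior of that dose's DLT rate.
# Because the streams are fixed before any design runs, the j-th patient
# assigned to a dose receives the same response under every design.

#' Build fixed per-dose response streams from trial summary counts
#'
#' For dose j with `n_j` patients and `y_j` DLTs observed, the first `n_j`
#' stream entries are a random permutation of the observed outcomes; each
#' remaining entry is Bernoulli with success probability drawn from
#' `Beta(1 + y_j, 1 + n_j - y_j)` (a fresh draw per entry by default, or one
#' draw per dose with `beta_draw = "per_dose"`).  Doses never assigned in
#' the original study use `Beta(3, 3)`.
#'
#' @param observed_n,observed_y per-dose patient and DLT counts.
#' @param total_patients stream length per dose (at least `max(observed_n)`).
#' @param seed integer seed; streams are fully reproducible from it.
#' @param beta_draw `"per_patient"` (default) or `"per_dose"`.
#' @return object of class `response_streams`: list with `streams`
#'   (total_patients x K 0/1 matrix), `observed` (logical matrix flagging
#'   the permuted-observed entries), `observed_n`, `observed_y`, `seed`.
#' @export
build_response_streams <- function(observed_n, observed_y, total_patients,
                                   seed,
                                   beta_draw = c("per_patient", "per_dose")) {
  beta_draw <- match.arg(beta_draw)
  observed_n <- as.integer(observed_n); observed_y <- as.integer(observed_y)
  K <- length(observed_n)
  if (length(observed_y) != K) stop("observed_n and observed_y lengths differ")
  if (any(observed_y < 0) || any(observed_y > observed_n))
    stop("need 0 <= y_j <= n_j at every dose")
  if (total_patients < max(observed_n))
    stop("total_patients must cover the largest per-dose count")
  set.seed(seed)
  streams <- matrix(NA_integer_, total_patients, K)
  observed <- matrix(FALSE, total_patients, K)
  for (j in seq_len(K)) {
    nj <- observed_n[j]; yj <- observed_y[j]
    if (nj > 0) {
      streams[seq_len(nj), j] <- sample(rep(c(1L, 0L), c(yj, nj - yj)))
      observed[seq_len(nj), j] <- TRUE
    }
    extra <- total_patients - nj
    if (extra > 0) {
      shape <- if (nj > 0) c(1 + yj, 1 + nj - yj) else c(3, 3)
      p <- if (beta_draw == "per_patient")
        stats::rbeta(extra, shape[1], shape[2])
      else rep(stats::rbeta(1, shape[1], shape[2]), extra)
      streams[nj + seq_len(extra), j] <- stats::rbinom(extra, 1L, p)
    }
  }
  structure(list(streams = streams, observed = observed,
                 observed_n = observed_n, observed_y = observed_y,
                 seed = seed, beta_draw = beta_draw),
            class = "response_streams")
}

#' Replay a trial design against fixed response streams
#'
#' Starts from the listed run-in cohorts (entered into the data, in order,
#' before the first model update), then proceeds with model-guided
#' allocation, consuming each dose's stream sequentially.
#'
#' @param streams a [build_response_streams()] result (or any
#'   `response_streams`-shaped object).
#' @param design a [design_config()]; its `n_cohorts` counts the
#'   model-guided cohorts run after the run-in.
#' @param spec,skeleton,config the partial order, skeleton, working model.
#' @param initial_cohorts optional run-in: list of `c(dose, size)` pairs.
#' @return a `trial_record` (see [run_trial()]); run-in allocations are
#'   included at the head of `allocations`, with the estimate rows starting
#'   at the first post-run-in update.
#' @export
replay_trial <- function(streams, design, spec, skeleton, config,
                         initial_cohorts = NULL) {
  stopifnot(inherits(streams, "response_streams"),
            inherits(design, "design_config"))
  S <- streams$streams
  K <- ncol(S)
  if (K != spec$K) stop("stream count does not match the dose grid")
  used <- rep(0L, K)
  take <- function(dose) {
    used[dose] <<- used[dose] + 1L
    if (used[dose] > nrow(S)) stop("response stream exhausted at dose ", dose)
    S[used[dose], dose]
  }
  data <- trial_data(rep(0L, K), rep(0L, K),
                     history = data.frame(dose = integer(0), dlt = integer(0)))
  runin_alloc <- integer(0); runin_out <- list()
  for (cohort in initial_cohorts) {
    dose <- as.integer(cohort[1]); size <- as.integer(cohort[2])
    outs <- integer(size)
    for (p in seq_len(size)) {
      outs[p] <- take(dose)
      data <- add_patient(data, dose, outs[p])
    }
    runin_alloc <- c(runin_alloc, dose)
    runin_out <- c(runin_out, list(outs))
  }
  fit0 <- recommend(design, data, spec, skeleton, config)
  est0 <- if (is.null(fit0$estimates)) rep(NA_real_, K) else fit0$estimates
  allocations <- integer(design$n_cohorts)
  outcomes <- matrix(NA_integer_, design$n_cohorts, design$cohort_size)
  estimates <- matrix(NA_real_, design$n_cohorts, K)
  selected_m <- rep(NA_integer_, design$n_cohorts)
  next_dose <- fit0$next_dose
  for (cc in seq_len(design$n_cohorts)) {
    allocations[cc] <- next_dose
    for (p in seq_len(design$cohort_size)) {
      out <- take(next_dose)
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
                 data = data, design = design,
                 runin = list(allocations = runin_alloc,
                              outcomes = runin_out),
                 seed = streams$seed),
            class = "trial_record")
}

#' Read a per-dose trial summary table
#'
#' CSV with columns `dose`, `n`, `y` (one row per dose, in linear dose
#' order).
#'
#' @param path file path.
#' @return list with `n` and `y` integer vectors.
#' @export
read_trial_summary <- function(path) {
  x <- utils::read.csv(path)
  for (f in c("dose", "n", "y"))
    if (is.null(x[[f]])) stop("trial summary missing column '", f, "'")
  x <- x[order(x$dose), ]
  if (!all(x$dose == seq_len(nrow(x))))
    stop("dose column must enumerate 1..K")
  list(n = as.integer(x$n), y = as.integer(x$y))
}
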