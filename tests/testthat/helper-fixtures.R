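# Shared fixtures and independent oracles for the test suite.

# memoised worked example (construction is cheap but used everywhere)
wex_cached <- local({
  wex <- NULL
  function() {
    if (is.null(wex)) wex <<- worked_example()
    wex
  }
})

# Independent skeleton oracle: solves the indifference-interval recursion by
# 1-D root bracketing instead of the closed form used by the package.
oracle_skeleton <- function(K, target, hw, nu) {
  a <- rep(NA_real_, K)
  a[nu] <- target
  if (nu < K) for (k in nu:(K - 1)) {
    b <- stats::uniroot(function(b) a[k]^exp(b) - (target - hw),
                        c(-20, 20), tol = 1e-13)$root
    a[k + 1] <- stats::uniroot(function(x) x^exp(b) - (target + hw),
                               c(1e-9, 1 - 1e-9), tol = 1e-14)$root
  }
  if (nu > 1) for (k in nu:2) {
    b <- stats::uniroot(function(b) a[k]^exp(b) - (target + hw),
                        c(-20, 20), tol = 1e-13)$root
    a[k - 1] <- stats::uniroot(function(x) x^exp(b) - (target - hw),
                               c(1e-9, 1 - 1e-9), tol = 1e-14)$root
  }
  a
}

# random admissible data for K doses (occasionally empty doses)
random_data <- function(K, max_n = 6) {
  n <- rpois(K, 1.2)
  n <- pmin(n, max_n)
  y <- rbinom(K, n, runif(1, 0.1, 0.6))
  trial_data(n, y)
}

# random partial-order spec: M arbitrary permutations of 1..K (monotonicity
# is not needed for the inference machinery itself)
random_spec <- function(M, K) {
  partial_order_spec(t(replicate(M, sample(K))))
}

# POCRM and BMA estimate paths along one fixed (dose, outcome) sequence,
# sharing a single posterior pass per prefix.
estimate_paths <- function(doses, outcomes, spec, skeleton, config,
                           tie_break = "last") {
  K <- spec$K
  data <- trial_data(rep(0L, K), rep(0L, K))
  q <- bmapocrm:::posterior_quantities(data, spec, skeleton, config)
  s <- bmapocrm:::select_ordering(q$ordering_post, tie_break)
  po_est0 <- q$plug[s$selected_m, ]
  bma_est0 <- as.vector(q$ordering_post %*% q$est)
  sel0 <- s$selected_m
  n_up <- length(doses)
  po <- matrix(NA_real_, n_up, K); bma <- matrix(NA_real_, n_up, K)
  sel <- integer(n_up)
  for (t in seq_len(n_up)) {
    data <- add_patient(data, doses[t], outcomes[t])
    q <- bmapocrm:::posterior_quantities(data, spec, skeleton, config)
    s <- bmapocrm:::select_ordering(q$ordering_post, tie_break)
    po[t, ] <- q$plug[s$selected_m, ]
    bma[t, ] <- as.vector(q$ordering_post %*% q$est)
    sel[t] <- s$selected_m
  }
  list(pocrm = list(allocations = doses, outcomes = outcomes,
                    estimates = po, est0 = po_est0,
                    selected_m = sel, selected_m0 = sel0),
       bma = list(allocations = doses, outcomes = outcomes,
                  estimates = bma, est0 = bma_est0,
                  selected_m = NULL, selected_m0 = NULL))
}

# Run a design along every binary outcome path of length n_pat and count
# flagged incoherencies (exhaustive enumeration oracle for 2x2 theory).
enumerate_path_incoherencies <- function(skeleton, spec, sets, config,
                                         design_name, theta, n_pat = 6) {
  dc <- design_config(design_name, theta = theta, n_cohorts = n_pat)
  total <- 0L
  K <- spec$K
  for (bits in 0:(2^n_pat - 1)) {
    outs <- as.integer(intToBits(bits))[seq_len(n_pat)]
    data <- trial_data(rep(0L, K), rep(0L, K))
    fit <- recommend(dc, data, spec, skeleton, config)
    prev <- fit$estimates
    dose <- dc$start_dose
    for (p in seq_len(n_pat)) {
      data <- add_patient(data, dose, outs[p])
      fit <- recommend(dc, data, spec, skeleton, config)
      ev <- detect_incoherencies(prev, fit$estimates, dose, outs[p], sets,
                                 0.001, "two")
      total <- total + nrow(ev)
      prev <- fit$estimates
      dose <- fit$next_dose
    }
  }
  total
}
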