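# Dose grids, simple orderings, partial-order specifications and skeletons.
#
# Linear dose indexing is fixed throughout the package: for an n_rows x n_cols
# combination matrix (rows = drug A levels, columns = drug B levels, counted
# from the lowest level), dose k corresponds to row i, column j with
# k = n_cols * (i - 1) + j.  So for a 3x2 grid: d1=(1,1), d2=(1,2), d3=(2,1),
# d4=(2,2), d5=(3,1), d6=(3,2).

#' Define a two-drug dose combination grid
#'
#' @param n_rows number of dose levels of drug A (rows).
#' @param n_cols number of dose levels of drug B (columns).
#'
#' @return An object of class `dose_grid` with elements `n_rows`, `n_cols`
#'   and `K = n_rows * n_cols`.  Linear dose index `k` maps to
#'   `(row, col) = (ceiling(k / n_cols), k - n_cols * (row - 1))`.
#' @export
#' @examples
#' g <- dose_grid(3, 2)
#' dose_coords(g)
dose_grid <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  K <- n_rows * n_cols
  if (K < 2L) stop("a dose grid needs at least 2 dose levels")
  structure(list(n_rows = n_rows, n_cols = n_cols, K = K),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d (%d dose levels)\n", x$n_rows, x$n_cols, x$K))
  invisible(x)
}

#' Row/column coordinates of each linear dose index
#'
#' @param grid a [dose_grid()].
#' @return data.frame with columns `dose`, `row`, `col`.
#' @export
dose_coords <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  k <- seq_len(grid$K)
  row <- ceiling(k / grid$n_cols)
  col <- k - grid$n_cols * (row - 1L)
  data.frame(dose = k, row = as.integer(row), col = as.integer(col))
}

#' Check single-agent monotonicity of an ordering
#'
#' A simple ordering (a permutation of the doses, least toxic first) is
#' admissible when, holding either drug fixed, its position strictly
#' increases with the level of the other drug.
#'
#' @param ordering integer vector: the dose indices in toxicity order
#'   (position 1 = least toxic).
#' @param grid a [dose_grid()].
#' @return `TRUE` or `FALSE`.
#' @export
is_monotone_ordering <- function(ordering, grid) {
  K <- grid$K
  if (length(ordering) != K || !setequal(ordering, seq_len(K))) return(FALSE)
  pos <- match(seq_len(K), ordering)   # I_m(d_k)
  xy <- dose_coords(grid)
  for (k in seq_len(K)) {
    i <- xy$row[k]; j <- xy$col[k]
    if (i < grid$n_rows) {
      up <- grid$n_cols * i + j        # (i + 1, j)
      if (pos[up] <= pos[k]) return(FALSE)
    }
    if (j < grid$n_cols) {
      right <- k + 1L                  # (i, j + 1)
      if (pos[right] <= pos[k]) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate the recommended set of simple orderings for a dose matrix
#'
#' Returns the six-ordering scheme commonly used to span the partial order of
#' a two-drug combination matrix: by rows, by columns, and four traversals of
#' the antidiagonals (within-diagonal ascending in drug A, descending,
#' and the two alternating variants).  For a 3x2 grid this reproduces, in
#' order, the six orderings of the worked example shipped with the package
#' (the by-rows and ascending-diagonal traversals coincide there, so only
#' five are unique - the duplicate is retained deliberately, doubling that
#' ordering's prior weight under uniform priors).  For a 2x2 grid the scheme
#' collapses to the two distinct admissible orderings
#' d1-d2-d3-d4 and d1-d3-d2-d4, which are returned without duplicates.
#'
#' @param grid a [dose_grid()] with at least 2 doses.
#' @return integer matrix, one ordering per row, entries are dose indices in
#'   toxicity order.
#' @export
#' @examples
#' enumerate_matrix_orderings(dose_grid(3, 2))
enumerate_matrix_orderings <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  if (grid$K < 2L) stop("grid too small")
  if (grid$n_rows == 2L && grid$n_cols == 2L) {
    out <- rbind(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L))
  } else {
    xy <- dose_coords(grid)
    by_rows <- order(xy$row, xy$col)
    by_cols <- order(xy$col, xy$row)
    diag_traverse <- function(mode) {
      s <- xy$row + xy$col
      out <- integer(0)
      flip <- FALSE
      for (d in sort(unique(s))) {
        idx <- which(s == d)
        idx <- idx[order(xy$row[idx])]           # ascending in drug A
        desc <- switch(mode,
                       asc = FALSE,
                       desc = TRUE,
                       alt_asc = flip,
                       alt_desc = !flip)
        if (desc) idx <- rev(idx)
        out <- c(out, idx)
        if (length(idx) > 1L) flip <- !flip      # alternate only on real runs
      }
      out
    }
    out <- rbind(by_rows, by_cols,
                 diag_traverse("desc"), diag_traverse("asc"),
                 diag_traverse("alt_asc"), diag_traverse("alt_desc"))
  }
  dimnames(out) <- list(paste0("m", seq_len(nrow(out))), NULL)
  bad <- !apply(out, 1L, is_monotone_ordering, grid = grid)
  if (any(bad))
    stop("internal error: generated ordering violates single-agent monotonicity")
  out
}

#' Build a partial-order specification
#'
#' Bundles M candidate simple orderings with prior ordering weights.
#' Duplicate orderings are retained verbatim by default: listing an ordering
#' twice deliberately doubles its prior weight under uniform priors.
#'
#' @param orderings matrix (one ordering per row) or list of integer vectors;
#'   each a permutation of `1:K`, least toxic dose first.
#' @param prior_weights optional nonnegative weights summing to 1; default
#'   uniform over the listed orderings.
#' @param grid optional [dose_grid()]; when supplied, every ordering is
#'   checked against single-agent monotonicity.
#' @param dedup collapse duplicated orderings, summing their weights.
#'   Off by default.
#'
#' @return An object of class `partial_order_spec` with elements
#'   `orderings` (M x K integer matrix), `prior_weights`, `M`, `K`, `grid`.
#' @export
partial_order_spec <- function(orderings, prior_weights = NULL, grid = NULL,
                               dedup = FALSE) {
  if (is.list(orderings)) orderings <- do.call(rbind, orderings)
  orderings <- matrix(as.integer(orderings), nrow = nrow(orderings))
  M <- nrow(orderings); K <- ncol(orderings)
  if (M < 1L) stop("need at least one ordering")
  for (m in seq_len(M))
    if (!setequal(orderings[m, ], seq_len(K)))
      stop(sprintf("ordering %d is not a permutation of 1:%d", m, K))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "dose_grid"), grid$K == K)
    ok <- apply(orderings, 1L, is_monotone_ordering, grid = grid)
    if (!all(ok))
      stop("ordering(s) ", paste(which(!ok), collapse = ", "),
           " violate single-agent monotonicity")
  }
  if (is.null(prior_weights)) prior_weights <- rep(1 / M, M)
  if (length(prior_weights) != M || any(prior_weights < 0))
    stop("prior_weights must be M nonnegative values")
  if (abs(sum(prior_weights) - 1) > 1e-12)
    stop("prior_weights must sum to 1")
  if (dedup) {
    key <- apply(orderings, 1L, paste, collapse = ",")
    keep <- !duplicated(key)
    w <- vapply(split(prior_weights, key), sum, numeric(1))
    orderings <- orderings[keep, , drop = FALSE]
    prior_weights <- unname(w[apply(orderings, 1L, paste, collapse = ",")])
    M <- nrow(orderings)
  }
  structure(list(orderings = orderings, prior_weights = prior_weights,
                 M = M, K = K, grid = grid),
            class = "partial_order_spec")
}

#' @export
print.partial_order_spec <- function(x, ...) {
  cat(sprintf("<partial_order_spec> M = %d orderings over K = %d doses\n",
              x$M, x$K))
  for (m in seq_len(x$M))
    cat(sprintf("  m=%d (w=%.4g): %s\n", m, x$prior_weights[m],
                paste0("d", x$orderings[m, ], collapse = " -> ")))
  invisible(x)
}

#' Position of each dose under each ordering
#'
#' @param spec a [partial_order_spec()].
#' @return M x K integer matrix; entry (m, k) is the toxicity rank
#'   of dose k under ordering m (1 = least toxic).
#' @export
ordering_positions <- function(spec) {
  stopifnot(inherits(spec, "partial_order_spec"))
  t(apply(spec$orderings, 1L, function(o) match(seq_len(spec$K), o)))
}

#' Universally less-toxic and more-toxic dose sets
#'
#' For each dose i, `nu[[i]]` collects the doses ranked below i under every
#' candidate ordering, and `xi[[i]]` those ranked above i under every
#' ordering.  These are the comparability sets used by the
#' estimation-coherency auditor: after a non-DLT at dose i no estimate in
#' `nu[[i]] U xi[[i]]` should rise, and after a DLT none should fall.
#'
#' @param spec a [partial_order_spec()].
#' @return An object of class `comparability_sets`: list with `nu` and `xi`,
#'   each a list of K integer vectors.
#' @export
comparability_sets <- function(spec) {
  pos <- ordering_positions(spec)
  K <- spec$K
  nu <- vector("list", K); xi <- vector("list", K)
  for (i in seq_len(K)) {
    below <- vapply(seq_len(K), function(j) all(pos[, j] < pos[, i]), logical(1))
    above <- vapply(seq_len(K), function(j) all(pos[, j] > pos[, i]), logical(1))
    nu[[i]] <- which(below)
    xi[[i]] <- which(above)
  }
  structure(list(nu = nu, xi = xi, K = K), class = "comparability_sets")
}

#' @export
print.comparability_sets <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste0("{d", paste(v, collapse = ",d"), "}") else "{}"
  for (i in seq_len(x$K))
    cat(sprintf("  d%-2d nu=%s xi=%s\n", i, fmt(x$nu[[i]]), fmt(x$xi[[i]])))
  invisible(x)
}

#' Indifference-interval skeleton
#'
#' Generates the monotone vector of prior toxicity guesses for the
#' one-parameter power working model by the indifference-interval recursion
#' of Lee and Cheung: the skeleton is anchored at the prior MTD
#' (`alpha[prior_mtd] = target`), and each neighbouring value is chosen so
#' that the model parameter at which one dose sits at `target - halfwidth`
#' puts its neighbour at `target + halfwidth`.  The recursion has the closed
#' form `log a[k+1] = log a[k] * log(target + halfwidth) / log(target -
#' halfwidth)` moving up, and symmetrically moving down.
#'
#' @param K number of dose levels.
#' @param target target toxicity rate in (0, 1).
#' @param halfwidth indifference half-width, `0 < halfwidth <
#'   min(target, 1 - target)`.  Larger values spread the skeleton.
#' @param prior_mtd index of the dose believed a priori to be the MTD.
#' @return numeric vector of length K, strictly increasing within (0, 1).
#' @export
#' @examples
#' indifference_interval_skeleton(6, target = 0.4, halfwidth = 0.08,
#'                                prior_mtd = 3)
indifference_interval_skeleton <- function(K, target, halfwidth, prior_mtd) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (!(target > 0 && target < 1)) stop("target must be in (0,1)")
  if (!(halfwidth > 0 && halfwidth < min(target, 1 - target)))
    stop("halfwidth must satisfy 0 < halfwidth < min(target, 1 - target)")
  prior_mtd <- as.integer(prior_mtd)
  if (prior_mtd < 1L || prior_mtd > K) stop("prior_mtd must be in 1..K")
  alpha <- rep(NA_real_, K)
  alpha[prior_mtd] <- target
  lo <- log(target - halfwidth); hi <- log(target + halfwidth)
  if (prior_mtd < K)
    for (k in prior_mtd:(K - 1L)) alpha[k + 1L] <- exp(log(alpha[k]) * hi / lo)
  if (prior_mtd > 1L)
    for (k in prior_mtd:2L) alpha[k - 1L] <- exp(log(alpha[k]) * lo / hi)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1) ||
      (K > 1L && any(diff(alpha) <= 0)))
    stop("invalid skeleton parameters: output not strictly increasing in (0,1)")
  alpha
}

#' Permute a skeleton according to a simple ordering
#'
#' Under ordering m the dose in toxicity position p receives the p-th
#' skeleton value; dose k therefore receives `skeleton[I_m(d_k)]`.
#'
#' @param skeleton increasing numeric vector in (0,1).
#' @param ordering integer vector of dose indices, least toxic first.
#' @return numeric vector: working-model skeleton value per dose.
#' @export
skeleton_under_ordering <- function(skeleton, ordering) {
  K <- length(skeleton)
  if (length(ordering) != K) stop("skeleton and ordering lengths differ")
  if (!setequal(ordering, seq_len(K))) stop("ordering is not a permutation")
  skeleton[match(seq_len(K), ordering)]
}

# ---- serialization -------------------------------------------------------

#' Read / write partial-order specifications as JSON
#'
#' The JSON schema is `{"K": 6, "orderings": [[1,2,...],[...]],
#' "prior_weights": [...]}` where list position gives the toxicity rank and
#' entries are 1-based dose indices.  `prior_weights` may be omitted
#' (uniform).  An optional `"grid": [n_rows, n_cols]` enables monotonicity
#' validation on read.
#'
#' @param path file path.
#' @return `read_order_spec` returns a [partial_order_spec()].
#' @export
read_order_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$orderings)) stop("no 'orderings' field in ", path)
  ords <- x$orderings
  if (is.list(ords)) ords <- do.call(rbind, ords)
  grid <- if (!is.null(x$grid)) dose_grid(x$grid[1], x$grid[2]) else NULL
  partial_order_spec(ords, prior_weights = x$prior_weights, grid = grid)
}

#' @rdname read_order_spec
#' @param spec a [partial_order_spec()].
#' @export
write_order_spec <- function(spec, path) {
  stopifnot(inherits(spec, "partial_order_spec"))
  x <- list(K = spec$K,
            orderings = unname(lapply(seq_len(spec$M),
                                      function(m) spec$orderings[m, ])),
            prior_weights = spec$prior_weights)
  if (!is.null(spec$grid)) x$grid <- c(spec$grid$n_rows, spec$grid$n_cols)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a skeleton configuration from YAML or JSON
#'
#' Accepts either an explicit `alpha` vector or the parameter form
#' `{K, target, halfwidth, prior_mtd}` passed to
#' [indifference_interval_skeleton()].
#'
#' @param path file path; `.yaml`/`.yml` parsed as YAML, otherwise JSON.
#' @return numeric skeleton vector.
#' @export
read_skeleton_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$alpha)) {
    alpha <- as.numeric(unlist(x$alpha))
    if (any(alpha <= 0) || any(alpha >= 1) || any(diff(alpha) <= 0))
      stop("explicit alpha must be strictly increasing in (0,1)")
    return(alpha)
  }
  for (f in c("K", "target", "halfwidth", "prior_mtd"))
    if (is.null(x[[f]])) stop("skeleton config missing field '", f, "'")
  indifference_interval_skeleton(x$K, x$target, x$halfwidth, x$prior_mtd)
}
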