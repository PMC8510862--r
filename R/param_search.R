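## Polymerization-parameter selection: grid evaluation with fiber-diameter
## and incorporation filters, rank-based scoring of lysis-curve errors, and
## variance-based (Sobol) sensitivity analysis via the Saltelli scheme.

#' Cartesian grid of polymerization parameters
#'
#' @param kA,kPI,kPG,kFI,kFG,kFA Numeric vectors of candidate values (all
#'   positive).  Defaults are log-spaced decades bracketing the best-ranked
#'   set.
#' @return A data.frame with one row per parameter set (class
#'   `parameter_grid`).
#' @export
parameter_grid <- function(kA = c(0.002, 0.02, 0.2),
                           kPI = 10^c(-18, -17, -16),
                           kPG = 10^c(-16, -15, -14),
                           kFI = 10^c(-19, -18, -17),
                           kFG = 10^c(-17, -16, -15),
                           kFA = 10^c(-19, -18, -17)) {
  vals <- list(kA = kA, kPI = kPI, kPG = kPG, kFI = kFI, kFG = kFG, kFA = kFA)
  if (any(unlist(vals) <= 0)) stop("all grid values must be positive")
  g <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("parameter_grid", "data.frame")
  g
}

#' Evaluate a parameter grid against fiber-diameter and incorporation filters
#'
#' Runs [run_clot_formation()] for every parameter set at each fibrinogen
#' concentration (default 1-4 mg/mL) under control protein levels, and
#' keeps the sets whose simulated fiber diameter `2*rf0` falls inside
#' `diameter_window` at every concentration and whose fibrinogen
#' incorporation is at least `incorporation_min` (default 0.80).  The
#' diameter acceptance window comes from electron-microscopy measurements
#' and must be supplied.
#'
#' @param grid A [parameter_grid()] (data.frame of parameter sets).
#' @param diameter_window Length-2 numeric, accepted fiber diameter range
#'   in nm.
#' @param fibrinogen Fibrinogen concentrations to test, mg/mL.
#' @param conditions Control protein levels (ug/mL) used at every
#'   fibrinogen concentration.
#' @param incorporation_min Minimal fibrinogen fraction incorporated into
#'   fibers.
#' @param t_clot Clotting time, s.
#' @param ... Passed to [run_clot_formation()].
#' @return List with `survivors` (row indices into `grid`), `diagnostics`
#'   (data.frame: set, fibrinogen, diameter, incorporation, ok) and
#'   `failures` (sets whose integration failed).
#' @export
evaluate_grid <- function(grid, diameter_window,
                          fibrinogen = c(1, 2, 3, 4),
                          conditions = list(tpa = 0.001, pai1 = 0.01, pg = 13),
                          incorporation_min = 0.80, t_clot = 1000, ...) {
  stopifnot(length(diameter_window) == 2, diameter_window[1] < diameter_window[2])
  if (nrow(grid) == 0)
    return(list(survivors = integer(0),
                diagnostics = data.frame(), failures = integer(0)))
  diag_rows <- list()
  failures <- integer(0)
  ok_set <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pr <- do.call(polymerization_rates, as.list(grid[i, ]))
    for (fg in fibrinogen) {
      res <- tryCatch(
        run_clot_formation(c(list(fibrinogen = fg), conditions),
                           poly_rates = pr, t_clot = t_clot, ...),
        error = function(e) NULL)
      if (is.null(res)) {
        failures <- c(failures, i)
        ok_set[i] <- FALSE
        diag_rows[[length(diag_rows) + 1L]] <-
          data.frame(set = i, fibrinogen = fg, diameter = NA_real_,
                     incorporation = NA_real_, ok = FALSE)
        next
      }
      dia <- 2 * res$rf0
      ok <- !is.na(dia) && dia >= diameter_window[1] &&
        dia <= diameter_window[2] && res$incorporation >= incorporation_min
      if (!ok) ok_set[i] <- FALSE
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(set = i, fibrinogen = fg, diameter = dia,
                   incorporation = res$incorporation, ok = ok)
    }
  }
  list(survivors = which(ok_set),
       diagnostics = do.call(rbind, diag_rows),
       failures = unique(failures))
}

#' Maximal error between a simulated and a target lysis profile
#'
#' `max |sim - target|` over the common grid restricted to `t <= up_to`
#' (the total lysis time).  Incompatible grids are reconciled by linear
#' interpolation of the simulation onto the target grid.
#'
#' @param sim A [run_fibrinolysis()] trajectory, or a list/data.frame with
#'   `time`/`t` and `value`/`percent`.
#' @param target List with `time` and `value` (dense target).
#' @param up_to Truncation time in seconds (default: end of target).
#' @return Maximal absolute error (scalar).
#' @export
max_error <- function(sim, target, up_to = max(target$time)) {
  st <- if (!is.null(sim$t)) sim$t else sim$time
  sv <- if (!is.null(sim$percent)) sim$percent else sim$value
  keep <- target$time <= up_to
  simv <- stats::approx(st, sv, xout = target$time[keep], rule = 2)$y
  max(abs(simv - target$value[keep]))
}

#' Rank-based score of parameter sets over experiments
#'
#' Per experiment (column), sets are ranked by increasing error (ties get
#' the average rank; undefined errors rank last).  A set's score is the
#' sum of its ranks over all experiments; the normalized score divides by
#' the worst possible score `S * E` (always ranked last), so scores lie in
#' `[1/S, 1]` and lower is better.
#'
#' @param errors Numeric S x E matrix of per-set (rows), per-experiment
#'   (columns) maximal errors.
#' @return An object of class `rank_score`: list with `ranks` (S x E),
#'   `score` (length S), `normalized` (length S), `best` (index of the
#'   minimal score).
#' @export
rank_score <- function(errors) {
  errors <- as.matrix(errors)
  S <- nrow(errors); E <- ncol(errors)
  if (S < 1 || E < 1) stop("need at least one set and one experiment")
  ranks <- apply(errors, 2, function(col) {
    col[!is.finite(col)] <- Inf   # undefined errors rank last
    rank(col, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = S)
  score <- rowSums(ranks)
  structure(list(ranks = ranks, score = score,
                 normalized = score / (S * E),
                 best = which.min(score)),
            class = "rank_score")
}

#' @export
print.rank_score <- function(x, ...) {
  cat(sprintf(
    "<rank_score> %d sets x %d experiments | best set #%d, normalized score %.3f\n",
    nrow(x$ranks), ncol(x$ranks), x$best, x$normalized[x$best]))
  invisible(x)
}

#' Saltelli sample for Sobol sensitivity analysis
#'
#' Builds the radial Saltelli design: two independent base matrices A and
#' B of size N x k, plus the k cross matrices AB_i (A with column i taken
#' from B) and, when second-order indices are requested, BA_i.  Inputs are
#' sampled uniformly or log-uniformly within `ranges`.
#'
#' @param ranges Named list of length-2 numeric ranges, one per parameter.
#' @param N Base sample size.
#' @param seed Integer seed.
#' @param sampler `"uniform"` or `"log_uniform"`.
#' @param second_order Include the BA_i matrices.
#' @return List with `X` (the stacked design matrix, row blocks A, B,
#'   AB_1..AB_k\[, BA_1..BA_k\]), `N`, `k`, `names`, `second_order`.
#' @export
saltelli_sample <- function(ranges, N, seed = 1L,
                            sampler = c("uniform", "log_uniform"),
                            second_order = TRUE) {
  sampler <- match.arg(sampler)
  k <- length(ranges)
  nm <- names(ranges)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  unit <- matrix(stats::runif(2 * N * k), ncol = 2 * k)
  A01 <- unit[, 1:k, drop = FALSE]
  B01 <- unit[, k + 1:k, drop = FALSE]
  scale1 <- function(u, rg) {
    if (sampler == "uniform") rg[1] + u * (rg[2] - rg[1])
    else exp(log(rg[1]) + u * (log(rg[2]) - log(rg[1])))
  }
  A <- B <- matrix(NA_real_, N, k, dimnames = list(NULL, nm))
  for (j in seq_len(k)) {
    A[, j] <- scale1(A01[, j], ranges[[j]])
    B[, j] <- scale1(B01[, j], ranges[[j]])
  }
  blocks <- list(A, B)
  for (j in seq_len(k)) { ABj <- A; ABj[, j] <- B[, j]; blocks[[2 + j]] <- ABj }
  if (second_order)
    for (j in seq_len(k)) { BAj <- B; BAj[, j] <- A[, j]; blocks[[2 + k + j]] <- BAj }
  list(X = do.call(rbind, blocks), N = N, k = k, names = nm,
       second_order = second_order)
}

#' Sobol sensitivity indices from model evaluations
#'
#' Variance-based first-order (Jansen/Saltelli estimator), total-order
#' (Jansen) and, optionally, second-order (Saltelli 2002) indices, with
#' bootstrap confidence intervals.
#'
#' @param f Function mapping a named parameter vector (one design row) to
#'   a scalar output; or a function taking the whole matrix and returning
#'   a vector (set `vectorized = TRUE`).
#' @param ranges Named list of length-2 ranges.
#' @param N Base sample size (the total number of evaluations is
#'   `N*(k+2)` or `N*(2k+2)` with second-order indices).
#' @param seed Integer seed (sampling and bootstrap).
#' @param sampler `"uniform"` or `"log_uniform"`.
#' @param second_order Compute second-order indices.
#' @param vectorized Whether `f` accepts the whole design matrix.
#' @param n_boot Bootstrap replicates for confidence intervals (0 = none).
#' @return An object of class `sobol_result`: data.frame `first` (S1 with
#'   CI), `total` (ST with CI), optional `second` (S2 per pair), plus
#'   `n_failed` (evaluations that returned non-finite values, which are
#'   dropped pairwise by resampling the affected rows' contribution).
#' @export
sobol_sensitivity <- function(f, ranges, N = 1024, seed = 1L,
                              sampler = c("uniform", "log_uniform"),
                              second_order = TRUE, vectorized = FALSE,
                              n_boot = 100L) {
  sampler <- match.arg(sampler)
  design <- saltelli_sample(ranges, N, seed, sampler, second_order)
  k <- design$k
  X <- design$X
  y <- if (vectorized) f(X) else apply(X, 1, function(row) f(stats::setNames(row, design$names)))
  y <- as.numeric(y)
  n_failed <- sum(!is.finite(y))
  if (n_failed > 0) {
    ## a failed evaluation poisons its whole radial block row: drop those rows
    nb <- nrow(X) / N
    bad_rows <- unique((which(!is.finite(y)) - 1L) %% N + 1L)
    keep <- setdiff(seq_len(N), bad_rows)
    idx <- as.vector(outer(keep, (seq_len(nb) - 1L) * N, "+"))
    y <- y[sort(idx)]
    N <- length(keep)
  }
  yA <- y[1:N]
  yB <- y[N + 1:N]
  yAB <- matrix(vapply(seq_len(k), function(j) y[(1 + j) * N + 1:N],
                       numeric(N)), ncol = k)
  yBA <- if (design$second_order)
    matrix(vapply(seq_len(k), function(j) y[(1 + k + j) * N + 1:N],
                  numeric(N)), ncol = k) else NULL

  est <- function(sel) {
    ## centering the outputs reduces the variance of the mean-product
    ## estimators without changing their expectation
    m <- mean(c(yA[sel], yB[sel]))
    a <- yA[sel] - m; b <- yB[sel] - m
    ab <- yAB[sel, , drop = FALSE] - m
    V <- stats::var(c(a, b))
    s1 <- vapply(seq_len(k), function(j)
      mean(b * (ab[, j] - a)) / V, numeric(1))
    st <- vapply(seq_len(k), function(j)
      0.5 * mean((a - ab[, j])^2) / V, numeric(1))
    s2 <- NULL
    if (!is.null(yBA)) {
      ba <- yBA[sel, , drop = FALSE] - m
      s2 <- list()
      for (i1 in seq_len(k - 1)) for (j1 in (i1 + 1):k) {
        vij <- mean(ba[, i1] * ab[, j1] - a * b) / V
        s2[[paste(design$names[i1], design$names[j1], sep = ":")]] <-
          vij - s1[i1] - s1[j1]
      }
      s2 <- unlist(s2)
    }
    list(s1 = s1, st = st, s2 = s2)
  }
  full <- est(seq_len(N))
  ci1 <- cit <- matrix(NA_real_, k, 2)
  if (n_boot > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed + 1L)
    bs1 <- matrix(NA_real_, n_boot, k)
    bst <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      e <- est(sample.int(N, N, replace = TRUE))
      bs1[b, ] <- e$s1; bst[b, ] <- e$st
    }
    ci1 <- t(apply(bs1, 2, stats::quantile, c(0.025, 0.975)))
    cit <- t(apply(bst, 2, stats::quantile, c(0.025, 0.975)))
  }
  structure(list(
    first = data.frame(parameter = design$names, S1 = full$s1,
                       lo = ci1[, 1], hi = ci1[, 2]),
    total = data.frame(parameter = design$names, ST = full$st,
                       lo = cit[, 1], hi = cit[, 2]),
    second = full$s2,
    N = N, n_failed = n_failed, seed = seed
  ), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> N = %d base samples (%d failed evaluations)\n",
              x$N, x$n_failed))
  df <- merge(x$first[, c("parameter", "S1")], x$total[, c("parameter", "ST")])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sobol sensitivity of the clot-formation outputs
#'
#' Convenience wrapper running [sobol_sensitivity()] on the six
#' polymerization rate constants (log-uniform within `ranges`) with the
#' end-of-clotting bound-tPA concentration and the initial fiber radius as
#' outputs.
#'
#' @param ranges Named list of ranges for kA, kPI, kPG, kFI, kFG, kFA.
#' @param conditions Laboratory concentrations, see
#'   [run_clot_formation()].
#' @param N Base sample size.
#' @param seed Integer seed.
#' @param ... Passed to [sobol_sensitivity()].
#' @return Named list of `sobol_result` objects for outputs `tpa_b` and
#'   `rf0`.
#' @export
sobol_clot_formation <- function(ranges = list(kA = c(0.002, 0.2),
                                               kPI = c(1e-18, 1e-16),
                                               kPG = c(1e-16, 1e-14),
                                               kFI = c(1e-19, 1e-17),
                                               kFG = c(1e-17, 1e-15),
                                               kFA = c(1e-19, 1e-17)),
                                 conditions = list(fibrinogen = 3,
                                                   tpa = 0.001,
                                                   pai1 = 0.01, pg = 13),
                                 N = 64, seed = 1L, ...) {
  run1 <- function(p) {
    res <- tryCatch(
      run_clot_formation(conditions,
                         poly_rates = do.call(polymerization_rates,
                                              as.list(p))),
      error = function(e) NULL)
    if (is.null(res)) c(tpa_b = NA_real_, rf0 = NA_real_)
    else c(tpa_b = res$binding[["tpa_b"]], rf0 = res$rf0)
  }
  cache <- new.env()
  out <- list()
  for (target in c("tpa_b", "rf0")) {
    out[[target]] <- sobol_sensitivity(function(p) {
      key <- paste(signif(p, 12), collapse = "_")
      if (is.null(cache[[key]])) cache[[key]] <- run1(p)
      cache[[key]][[target]]
    }, ranges, N = N, seed = seed, sampler = "log_uniform", ...)
  }
  out
}
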