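## Pan-genome openness: rarefaction of pan/core sizes over random genome
## orderings, Heaps'-law power-law fitting (pan = kappa * n^gamma),
## extrapolation of pan size and per-genome gene novelty, and the
## reciprocal-genome-count (1/n) extrapolation of the core.

#' Rarefaction of pan and core genome sizes
#'
#' For each of `permutations` random genome orderings and each prefix
#' length n, counts the pan size (orthogroups present in at least one of
#' the first n genomes) and core size (present in all first n).
#'
#' @param m a [pa_matrix()] with at least 2 genomes.
#' @param permutations number of random orderings.
#' @param seed integer seed.
#' @param orderings optional list of explicit genome orderings (integer
#'   vectors); overrides `permutations`, e.g. to rarefy over every
#'   ordering of a small genome set.
#' @return object of class `"rarefaction"`: list with `n` (1..N),
#'   matrices `pan` and `core` (permutations x N), and per-n `pan_median`,
#'   `pan_sd`, `core_median`, `core_sd`.
#' @export
rarefy <- function(m, permutations = 100, seed = 1L, orderings = NULL) {
  stopifnot(inherits(m, "pa_matrix"))
  if (ncol(m) < 2) stop("rarefaction needs >= 2 genomes")
  if (!is.null(orderings)) permutations <- length(orderings)
  if (permutations < 1) stop("permutations must be >= 1")
  N <- ncol(m)
  pm <- unclass(m) * 1L
  npm <- 1L - pm
  all_present <- rowSums(pm) == N
  pan <- matrix(0L, permutations, N)
  core <- matrix(0L, permutations, N)
  set.seed(seed)
  for (p in seq_len(permutations)) {
    ord <- if (is.null(orderings)) sample.int(N) else orderings[[p]]
    mm <- pm[, ord, drop = FALSE]
    # first genome (in this ordering) containing each orthogroup
    first_hit <- max.col(mm, ties.method = "first")
    pan[p, ] <- cumsum(tabulate(first_hit, N))
    # first genome missing each orthogroup; all-present rows never drop out
    first_miss <- max.col(npm[, ord, drop = FALSE], ties.method = "first")
    lost <- tabulate(first_miss[!all_present], N)
    core[p, ] <- nrow(pm) - cumsum(lost)
  }
  structure(list(
    n = seq_len(N),
    pan = pan, core = core,
    pan_median = apply(pan, 2, stats::median),
    pan_sd = apply(pan, 2, stats::sd),
    core_median = apply(core, 2, stats::median),
    core_sd = apply(core, 2, stats::sd),
    permutations = permutations, seed = seed
  ), class = "rarefaction")
}

#' @export
print.rarefaction <- function(x, ...) {
  N <- length(x$n)
  cat(sprintf("Rarefaction over %d permutations of %d genomes\n",
              x$permutations, N))
  cat(sprintf("  median pan: %s -> %s; median core: %s -> %s\n",
              x$pan_median[1], x$pan_median[N],
              x$core_median[1], x$core_median[N]))
  invisible(x)
}

#' Fit Heaps' law to a rarefaction curve
#'
#' Least-squares fit of the median pan sizes to kappa * n^gamma.
#' The default method fits on the original scale
#' (Levenberg-Marquardt, started from the log-log linear fit); method
#' `"loglog"` reports the log-log linear fit itself. gamma < 1 indicates
#' an open pan-genome. A constant curve is returned as
#' kappa = constant, gamma = 0 and flagged closed.
#'
#' @param x a `"rarefaction"` object, or a numeric vector of median pan
#'   sizes at n = 1..length(x).
#' @param method `"nls"` (default) or `"loglog"`.
#' @return object of class `"heaps_fit"`: list with `kappa`, `gamma`,
#'   `rss`, `method`, `open` (logical).
#' @export
fit_heaps <- function(x, method = c("nls", "loglog")) {
  method <- match.arg(method)
  y <- if (inherits(x, "rarefaction")) x$pan_median else as.numeric(x)
  n <- seq_along(y)
  if (length(unique(n)) < 3) stop("need >= 3 distinct genome counts to fit")
  if (any(y <= 0)) stop("pan sizes must be positive")
  if (stats::sd(y) == 0) {
    return(structure(list(kappa = y[1], gamma = 0, rss = 0,
                          method = method, open = FALSE),
                     class = "heaps_fit"))
  }
  ll <- stats::lm(log(y) ~ log(n))
  k0 <- exp(stats::coef(ll)[[1]]); g0 <- stats::coef(ll)[[2]]
  if (method == "loglog") {
    fitted <- k0 * n^g0
    return(structure(list(kappa = k0, gamma = g0,
                          rss = sum((y - fitted)^2),
                          method = "loglog", open = g0 < 1),
                     class = "heaps_fit"))
  }
  fit <- minpack.lm::nlsLM(y ~ kappa * n^gamma,
                           start = list(kappa = k0, gamma = g0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(kappa = co[["kappa"]], gamma = co[["gamma"]],
                 rss = sum(stats::resid(fit)^2),
                 method = "nls", open = co[["gamma"]] < 1),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps'-law fit (%s): pan(n) = %.4g * n^%.4g  [%s pan-genome]\n",
              x$method, x$kappa, x$gamma,
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Extrapolate the pan-genome size
#'
#' @param fit a `"heaps_fit"` (or list with `kappa`, `gamma`).
#' @param n genome count(s).
#' @return expected pan size round(kappa * n^gamma), per n.
#' @export
extrapolate_pan <- function(fit, n) {
  stopifnot(all(n >= 1))
  round(fit$kappa * n^fit$gamma)
}

#' New genes contributed by the n-th genome
#'
#' Finite difference of the fitted Heaps curve:
#' round(kappa * n^gamma - kappa * (n-1)^gamma).
#'
#' @inheritParams extrapolate_pan
#' @export
new_genes <- function(fit, n) {
  stopifnot(all(n >= 2))
  round(fit$kappa * (n^fit$gamma - (n - 1)^fit$gamma))
}

#' Genome count at which gene novelty falls below a threshold
#'
#' Smallest n for which [new_genes()] drops below `threshold`, seeded by
#' the closed form kappa * gamma * n^(gamma-1) = threshold and refined by
#' a local scan. With gamma >= 1 novelty never falls, and the result is
#' `Inf` with a `"never"` flag.
#'
#' @inheritParams extrapolate_pan
#' @param threshold gene count (>= 1).
#' @return list with `n` (count or Inf) and `never` (logical).
#' @export
novelty_horizon <- function(fit, threshold) {
  stopifnot(threshold >= 1)
  if (fit$gamma >= 1) return(list(n = Inf, never = TRUE))
  if (fit$gamma <= 0) return(list(n = 2, never = FALSE))
  # unrounded finite difference; novelty is decreasing in n for gamma < 1
  below <- function(n) fit$kappa * (n^fit$gamma - (n - 1)^fit$gamma) < threshold
  n <- max(2, floor((fit$kappa * fit$gamma / threshold)^(1 / (1 - fit$gamma))))
  if (below(n)) {
    while (n > 2 && below(n - 1)) n <- n - 1
  } else {
    while (!below(n)) n <- n + 1
  }
  list(n = n, never = FALSE)
}

#' Core-genome extrapolation against the reciprocal genome count
#'
#' Ordinary least squares of the median core size on 1/n, using n >= 2
#' (n = 1 is excluded because core(1) = pan(1) by definition). The
#' intercept estimates the core at an infinite number of genomes; a
#' negative intercept is clamped to 0 and flagged.
#'
#' @param x a `"rarefaction"` object, or a numeric vector of median core
#'   sizes at n = 1..length(x).
#' @return object of class `"core_fit"`: list with `intercept`, `slope`,
#'   `r_squared`, `clamped`.
#' @export
fit_core_inverse <- function(x) {
  y <- if (inherits(x, "rarefaction")) x$core_median else as.numeric(x)
  n <- seq_along(y)
  keep <- n >= 2
  if (sum(keep) < 3) stop("need >= 3 genome counts with n >= 2")
  inv <- 1 / n[keep]
  fit <- stats::lm(y[keep] ~ inv)
  co <- stats::coef(fit)
  intercept <- co[[1]]; slope <- co[[2]]
  clamped <- FALSE
  if (intercept < 0) { intercept <- 0; clamped <- TRUE }
  yk <- y[keep]
  r2 <- if (stats::sd(yk) == 0) 1 else
    1 - sum(stats::resid(fit)^2) / sum((yk - mean(yk))^2)
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r2, clamped = clamped),
            class = "core_fit")
}

#' @export
print.core_fit <- function(x, ...) {
  cat(sprintf(
    "Core extrapolation: core(n) = %.4g + %.4g / n (R^2 = %.3f)%s\n",
    x$intercept, x$slope, x$r_squared,
    if (x$clamped) " [intercept clamped to 0]" else ""))
  cat(sprintf("  core at infinite genomes: %d genes\n", round(x$intercept)))
  invisible(x)
}

#' Full openness analysis of a presence/absence matrix
#'
#' Convenience wrapper: rarefy, fit Heaps' law and the 1/n core
#' regression, and tabulate extrapolations.
#'
#' @inheritParams rarefy
#' @param extrapolate_at genome counts for the extrapolation table.
#' @param novelty_threshold gene count for the novelty horizon.
#' @param config an [analysis_config()]; supplies the permutation count
#'   and seed when `permutations`/`seed` are missing.
#' @return list with `rarefaction`, `heaps`, `core_fit`, `extrapolation`
#'   (data.frame n / pan / new_genes), `novelty_horizon` and
#'   `observed` (pan size, core size at N).
#' @export
openness <- function(m, permutations = NULL, seed = NULL,
                     extrapolate_at = c(101, 501, 1001),
                     novelty_threshold = 100,
                     config = analysis_config()) {
  if (is.null(permutations)) permutations <- config$rarefaction_permutations
  if (is.null(seed)) seed <- config$rng_seed
  rar <- rarefy(m, permutations = permutations, seed = seed)
  hf <- fit_heaps(rar)
  cf <- fit_core_inverse(rar)
  ext <- data.frame(
    n = extrapolate_at,
    pan = extrapolate_pan(hf, extrapolate_at),
    new_genes = new_genes(hf, extrapolate_at))
  list(rarefaction = rar, heaps = hf, core_fit = cf,
       extrapolation = ext,
       novelty_horizon = novelty_horizon(hf, novelty_threshold),
       observed = list(pan = nrow(m),
                       core = sum(rowSums(unclass(m)) == ncol(m))))
}
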