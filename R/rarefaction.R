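#' Carrier-count spectrum of a genotype matrix
#'
#' For each variant, its carriers are the samples with at least one
#' alternate allele copy. The spectrum c_k (k = 1..N) counts variants
#' carried by exactly k of the N isolates; c_1 is the singleton count and
#' sum(c_k) the total variant count. The spectrum is a sufficient
#' statistic for exact rarefaction.
#'
#' @param x a [genotype_matrix()], or an integer vector of per-variant
#'   carrier numbers.
#' @param n_samples required when `x` is a plain vector.
#' @return object of class `carrier_counts`: list(N, c_k integer vector of
#'   length N).
#' @export
carrier_counts <- function(x, n_samples = NULL) {
  if (inherits(x, "genotype_matrix")) {
    if (n_loci(x) == 0) stop("empty genotype matrix")
    k <- rowSums(x$dosage >= 1L, na.rm = TRUE)
    N <- length(x$samples)
  } else {
    stopifnot(is.numeric(x), !is.null(n_samples))
    k <- x; N <- n_samples
  }
  k <- k[k >= 1]
  structure(list(N = as.integer(N),
                 c_k = tabulate(k, nbins = N)),
            class = "carrier_counts")
}

#' @export
#' @method print carrier_counts
print.carrier_counts <- function(x, ...) {
  cat("carrier_counts: N =", x$N, "isolates;",
      sum(x$c_k), "variants of which", x$c_k[1], "singletons\n")
  invisible(x)
}

#' Exact expected rarefaction
#'
#' Expected number of variants observed (with at least `min_carriers`
#' carriers inside the subsample) when n of the N isolates are drawn
#' without replacement. For a variant with k carriers,
#' P(>=1 carrier) = 1 - C(N-k, n)/C(N, n) and
#' P(>=2 carriers) = P(>=1) - k C(N-k, n-1)/C(N, n); the expectation sums
#' these over the carrier spectrum. Singleton status is evaluated within
#' the subsample, the standard rarefaction semantics.
#'
#' @param counts a [carrier_counts()].
#' @param n subsample size(s), 1 <= n <= N (vectorised).
#' @param min_carriers 1 (all variants) or 2 (non-singletons).
#' @return numeric vector of expected counts.
#' @export
expected_rarefaction <- function(counts, n, min_carriers = 1) {
  stopifnot(inherits(counts, "carrier_counts"), min_carriers %in% c(1, 2))
  N <- counts$N
  if (any(n < 1 | n > N)) stop("subsample size out of range 1..N")
  ks <- which(counts$c_k > 0)
  vapply(n, function(nn) {
    p1 <- 1 - exp(lchoose(N - ks, nn) - lchoose(N, nn))
    if (min_carriers == 1) return(sum(counts$c_k[ks] * p1))
    p_exactly1 <- ks * exp(lchoose(N - ks, nn - 1) - lchoose(N, nn))
    sum(counts$c_k[ks] * pmax(0, p1 - p_exactly1))
  }, numeric(1))
}

#' Monte-Carlo rarefaction
#'
#' Stochastic twin of [expected_rarefaction()]: mean over `reps` random
#' n-subsets of the number of variants with at least `min_carriers`
#' carriers in the subset.
#'
#' @param x a [genotype_matrix()].
#' @param n subsample size.
#' @param reps number of subsets.
#' @param seed RNG seed.
#' @param min_carriers 1 or 2.
#' @return list: mean, se (standard error over reps).
#' @export
monte_carlo_rarefaction <- function(x, n, reps = 100, seed = 1,
                                    min_carriers = 1) {
  stopifnot(inherits(x, "genotype_matrix"))
  carrier <- !is.na(x$dosage) & x$dosage >= 1L
  N <- length(x$samples)
  stopifnot(n >= 1, n <= N)
  draws <- with_seed(seed, vapply(seq_len(reps), function(r) {
    sub <- carrier[, sample.int(N, n), drop = FALSE]
    sum(rowSums(sub) >= min_carriers)
  }, numeric(1)))
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}

#' Rarefaction curve over a grid of subsample sizes
#'
#' @param x a [genotype_matrix()] or [carrier_counts()].
#' @param grid number of geometrically spaced subsample sizes (default 50,
#'   from 2 to N), or an explicit integer vector of sizes.
#' @param min_carriers 1 or 2.
#' @param mode "exact" (default) or "monte_carlo".
#' @param reps,seed Monte-Carlo settings.
#' @return object of class `rarefaction_curve`: data.frame (n, y) with
#'   attributes `min_carriers` and `N`.
#' @export
rarefaction_curve <- function(x, grid = 50, min_carriers = 1,
                              mode = c("exact", "monte_carlo"),
                              reps = 100, seed = 1) {
  mode <- match.arg(mode)
  counts <- if (inherits(x, "carrier_counts")) x else carrier_counts(x)
  N <- counts$N
  ns <- if (length(grid) > 1) as.integer(grid) else {
    unique(pmin(N, pmax(2L, round(exp(seq(log(2), log(N), length.out = grid))))))
  }
  y <- if (mode == "exact") {
    expected_rarefaction(counts, ns, min_carriers)
  } else {
    stopifnot(inherits(x, "genotype_matrix"))
    vapply(seq_along(ns), function(i)
      monte_carlo_rarefaction(x, ns[i], reps = reps, seed = seed + i,
                              min_carriers = min_carriers)$mean, numeric(1))
  }
  structure(data.frame(n = ns, y = y),
            class = c("rarefaction_curve", "data.frame"),
            min_carriers = min_carriers, N = N, mode = mode)
}

#' Fit a power-law curve to a rarefaction curve
#'
#' Nonlinear least squares for y = a x^b - c with a > 0 and 0 < b < 1.
#' A power-law growth has no finite asymptote: the variant count tends to
#' infinity with sample size, so no coverage fraction can be derived from
#' this fit. Initialised from a log-log regression, with jittered
#' restarts.
#'
#' @param curve a [rarefaction_curve()] or data.frame (n, y).
#' @param restarts jittered re-initialisations (default 5).
#' @param seed seed for the jitter.
#' @return object of class `saturation_fit`: list(model = "power_law",
#'   params (a, b, c), rss, fitted function, converged).
#' @export
fit_power_law <- function(curve, restarts = 5, seed = 1) {
  df <- as.data.frame(curve)[, c("n", "y")]
  if (nrow(df) < 4) stop("at least 4 grid points required")
  lm0 <- stats::lm(log(pmax(y, 1e-9)) ~ log(n), data = df)
  a0 <- exp(stats::coef(lm0)[1]); b0 <- min(0.95, max(0.05, stats::coef(lm0)[2]))
  starts <- with_seed(seed, c(list(c(a = unname(a0), b = unname(b0), c = 0)),
    lapply(seq_len(restarts - 1), function(i)
      c(a = unname(a0) * stats::runif(1, 0.5, 2),
        b = min(0.95, max(0.05, unname(b0) * stats::runif(1, 0.6, 1.4))),
        c = stats::runif(1, -0.1, 0.1) * max(df$y)))))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * n^b - c, data = df, start = as.list(st),
                        lower = c(a = 1e-12, b = 1e-6, c = -Inf),
                        upper = c(a = Inf, b = 1, c = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(model = "power_law", params = NULL, rss = NA_real_,
                          converged = FALSE), class = "saturation_fit"))
  p <- stats::coef(best$fit)
  structure(list(model = "power_law",
                 params = c(a = unname(p["a"]), b = unname(p["b"]),
                            c = unname(p["c"])),
                 rss = best$rss,
                 fitted = function(x) unname(p["a"]) * x^unname(p["b"]) - unname(p["c"]),
                 asymptote = Inf,
                 converged = TRUE),
            class = "saturation_fit")
}

#' Fit a Michaelis-Menten saturation curve
#'
#' Nonlinear least squares for y = Vmax x / (K + x) with positive
#' parameters, initialised from a double-reciprocal (Lineweaver-Burk)
#' linear pass. The asymptote Vmax estimates the total (species-wide)
#' variant count the curve saturates toward.
#'
#' @param curve a [rarefaction_curve()] or data.frame (n, y).
#' @return object of class `saturation_fit`: list(model =
#'   "michaelis_menten", params (Vmax, K), rss, fitted, asymptote,
#'   converged).
#' @export
fit_michaelis_menten <- function(curve) {
  df <- as.data.frame(curve)[, c("n", "y")]
  df <- df[df$y > 0, , drop = FALSE]
  if (nrow(df) < 3) stop("at least 3 grid points required")
  lb <- stats::lm(I(1 / y) ~ I(1 / n), data = df)
  v0 <- 1 / stats::coef(lb)[1]
  k0 <- stats::coef(lb)[2] * v0
  if (!is.finite(v0) || v0 <= 0) v0 <- max(df$y) * 2
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(df$n)
  starts <- list(c(Vmax = unname(v0), K = unname(k0)),
                 c(Vmax = max(df$y) * 1.2, K = stats::median(df$n)),
                 c(Vmax = max(df$y) * 2, K = max(df$n)))
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ Vmax * n / (K + n), data = df,
                        start = as.list(st),
                        lower = c(Vmax = 1e-12, K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2)))
      fit <- cand
  }
  if (is.null(fit))
    return(structure(list(model = "michaelis_menten", params = NULL,
                          rss = NA_real_, converged = FALSE),
                     class = "saturation_fit"))
  p <- stats::coef(fit)
  structure(list(model = "michaelis_menten",
                 params = c(Vmax = unname(p["Vmax"]), K = unname(p["K"])),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = function(x) unname(p["Vmax"]) * x / (unname(p["K"]) + x),
                 asymptote = unname(p["Vmax"]),
                 converged = TRUE),
            class = "saturation_fit")
}

#' @export
#' @method print saturation_fit
print.saturation_fit <- function(x, ...) {
  cat("saturation_fit:", x$model, "\n")
  if (!is.null(x$params)) {
    cat("  params:", paste(names(x$params), signif(x$params, 7),
                           sep = "=", collapse = "  "), "\n")
    cat("  rss:", signif(x$rss, 6), " asymptote:",
        if (is.finite(x$asymptote)) signif(x$asymptote, 7) else "Inf", "\n")
  } else cat("  (not converged)\n")
  invisible(x)
}

#' Fraction of species diversity captured
#'
#' Given a Michaelis-Menten saturation fit of the non-singleton
#' rarefaction curve, the species-total non-singleton variant count is the
#' fit's asymptote Vmax, and the fraction captured by the N sampled
#' isolates is numerator / Vmax, where the numerator is the observed
#' non-singleton count (default) or the fitted curve value at N
#' (`fitted_at_N`, equal to N/(K+N) x Vmax). Power-law fits are refused:
#' their variant count tends toward infinity, so no finite coverage
#' fraction exists.
#'
#' @param fit a `saturation_fit` with model "michaelis_menten".
#' @param observed_count observed variant count at full sample size (used
#'   by mode "observed_count").
#' @param N full sample size.
#' @param numerator_mode "observed_count" (default) or "fitted_at_N".
#' @return list: fraction, numerator, vmax, numerator_mode.
#' @export
coverage_fraction <- function(fit, observed_count, N,
                              numerator_mode = c("observed_count", "fitted_at_N")) {
  numerator_mode <- match.arg(numerator_mode)
  stopifnot(inherits(fit, "saturation_fit"))
  if (fit$model != "michaelis_menten")
    stop("coverage fraction requires a Michaelis-Menten fit; under a power ",
         "law the number of variants tends toward infinity")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  num <- switch(numerator_mode,
                observed_count = observed_count,
                fitted_at_N = fit$fitted(N))
  list(fraction = num / fit$asymptote, numerator = num,
       vmax = fit$asymptote, numerator_mode = numerator_mode)
}
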