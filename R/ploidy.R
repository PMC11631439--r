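#' Fixed-mean Gaussian mixture models for ploidy inference
#'
#' At heterozygous sites, the alternate-allele read fraction clusters
#' around the possible allele-dosage ratios of the genome: {1/2} for a
#' diploid, {1/3, 2/3} for a triploid, {1/4, 1/2, 3/4} for a tetraploid.
#' Each ploidy hypothesis is a Gaussian mixture with component means FIXED
#' at those ratios; only the mixture weights and one shared standard
#' deviation are free. Comparing the fit of the three fixed models (and a
#' free-mean reference model) to a sample's fraction histogram yields the
#' ploidy call.
#'
#' @param ploidy 2, 3 or 4.
#' @return numeric vector of fixed component means.
#' @export
ploidy_model_means <- function(ploidy) {
  switch(as.character(ploidy),
         "2" = 1 / 2,
         "3" = c(1 / 3, 2 / 3),
         "4" = c(1 / 4, 1 / 2, 3 / 4),
         stop("ploidy must be 2, 3 or 4"))
}

# shared-sd Gaussian mixture EM; means fixed unless free_means = TRUE.
# Returns logLik trace (monotone non-decreasing), weights, means, sd.
mixture_em <- function(x, means, weights = NULL, sd0 = NULL,
                       free_means = FALSE, max_iter = 300, tol = 1e-8,
                       sd_floor = 1e-3) {
  n <- length(x)
  k <- length(means)
  w <- weights %||% rep(1 / k, k)
  s <- max(sd0 %||% stats::sd(x) %||% 0.05, sd_floor)
  if (is.na(s)) s <- sd_floor
  loglik <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, means[j], s),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    new_ll <- sum(log(tot))
    trace <- c(trace, new_ll)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol * (1 + abs(new_ll))) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    if (free_means) {
      upd <- nk > 0
      means[upd] <- (colSums(r * x) / nk)[upd]
    }
    s <- sqrt(sum(r * (outer(x, means, "-")^2)) / n)
    s <- max(s, sd_floor)
  }
  list(loglik = loglik, weights = w, means = means, sd = s, trace = trace,
       iterations = iter)
}

#' Fit a fixed-mean ploidy mixture model
#'
#' EM over mixture weights and one shared standard deviation, component
#' means fixed at the allele-dosage ratios of the ploidy hypothesis. The
#' log-likelihood is non-decreasing across iterations; the shared standard
#' deviation is floored at `sd_floor` to avoid degenerate spikes.
#'
#' @param freqs a [base_frequency_sample()] or numeric vector of fractions.
#' @param ploidy 2, 3 or 4.
#' @param n_min minimum number of sites required (default 100).
#' @param sd_floor lower bound on the shared standard deviation.
#' @param max_iter,tol EM stopping rule.
#' @return list: loglik, weights, means, sd, trace (per-iteration logLik).
#' @export
fit_fixed_mixture <- function(freqs, ploidy, n_min = 100, sd_floor = 1e-3,
                              max_iter = 300, tol = 1e-8) {
  x <- as_fractions(freqs)
  if (length(x) < n_min)
    stop("too few heterozygous sites (", length(x), " < ", n_min,
         "); ploidy cannot be estimated")
  fit <- mixture_em(x, ploidy_model_means(ploidy), max_iter = max_iter,
                    tol = tol, sd_floor = sd_floor)
  fit$ploidy <- ploidy
  fit
}

#' Fit a free-mean Gaussian mixture (reference model)
#'
#' EM with free means, weights and one shared standard deviation. Because
#' every fixed-mean ploidy model is nested in this model, its
#' log-likelihood is at least each fixed model's (up to numerical
#' tolerance); the gap logL_free - logL_fixed measures how much a ploidy
#' hypothesis' fixed ratios cost. The EM is started from `restarts`
#' seeded random initialisations plus the three fixed-model solutions, and
#' the best log-likelihood is kept — starting from the fixed solutions
#' guarantees the nesting inequality in finite samples.
#'
#' @inheritParams fit_fixed_mixture
#' @param n_components number of free components (default 3).
#' @param restarts number of random EM restarts (default 10).
#' @param seed integer seed for the restart draws.
#' @return list as [fit_fixed_mixture()].
#' @export
fit_free_mixture <- function(freqs, n_components = 3, n_min = 100,
                             restarts = 10, seed = 1, sd_floor = 1e-3,
                             max_iter = 300, tol = 1e-8) {
  x <- as_fractions(freqs)
  if (length(x) < n_min)
    stop("too few heterozygous sites (", length(x), " < ", n_min,
         "); ploidy cannot be estimated")
  starts <- with_seed(seed, lapply(seq_len(restarts), function(i)
    sort(stats::runif(n_components, min(x), max(x)))))
  for (p in 2:4) { # fixed-model solutions as additional starts (nesting)
    m <- ploidy_model_means(p)
    fit <- mixture_em(x, m, sd_floor = sd_floor, max_iter = max_iter, tol = tol)
    pad <- n_components - length(m)
    starts <- c(starts, list(c(fit$means, rep(fit$means[1], pad))))
  }
  best <- NULL
  for (m0 in starts) {
    fit <- mixture_em(x, m0, free_means = TRUE, sd_floor = sd_floor,
                      max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Histogram goodness-of-fit of a fixed ploidy model
#'
#' Bins the allele fractions into `n_bins` equal bins over the retention
#' interval and compares the observed bin proportions with the fitted
#' model's probability mass per bin (mixture density integrated over the
#' bin, renormalised over the interval). Reports the sum of squared
#' residuals and the regression-style R-squared
#' `1 - ssr / sum((obs - mean(obs))^2)`; R-squared can be negative for a
#' badly mismatched model and is returned as computed.
#'
#' @param freqs a [base_frequency_sample()] or numeric vector.
#' @param fit a fitted fixed mixture (from [fit_fixed_mixture()]).
#' @param n_bins number of histogram bins (default 100).
#' @param retain interval the fractions live on, default (0.1, 0.9).
#' @return list: ssr, r2, observed, expected, breaks.
#' @export
histotest <- function(freqs, fit, n_bins = 100, retain = c(0.1, 0.9)) {
  x <- as_fractions(freqs)
  breaks <- seq(retain[1], retain[2], length.out = n_bins + 1)
  obs <- as.vector(table(cut(x, breaks, include.lowest = TRUE))) / length(x)
  cdf <- function(q) {
    rowSums(vapply(seq_along(fit$means), function(j)
      fit$weights[j] * stats::pnorm(q, fit$means[j], fit$sd), numeric(length(q))))
  }
  mass <- cdf(breaks[-1]) - cdf(breaks[-length(breaks)])
  total <- sum(mass)
  expected <- if (total > 0) mass / total else rep(1 / n_bins, n_bins)
  ssr <- sum((obs - expected)^2)
  tss <- sum((obs - mean(obs))^2)
  r2 <- 1 - ssr / tss
  list(ssr = ssr, r2 = r2, observed = obs, expected = expected, breaks = breaks)
}

#' Call the ploidy of a sample from its allele-fraction spectrum
#'
#' Fits the three fixed-mean mixture models (2n, 3n, 4n) and the free-mean
#' reference model, then selects a ploidy by the chosen criterion:
#' `delta_loglik` minimises logL_free - logL_fixed, `ssr` minimises the
#' histogram sum of squared residuals, `r2` maximises the histogram
#' R-squared. Scores that agree within a small relative tolerance are
#' ties — a nested model (the tetraploid mixture contains the diploid as
#' a weight-degenerate case) can reproduce a lower model's fit to
#' machine precision — and ties break deterministically to the lowest
#' ploidy. Samples
#' with fewer than `n_min` usable sites are called `unknown` (ploidy cannot
#' be estimated reliably from sequencing data alone for homozygous
#' samples).
#'
#' @param freqs a [base_frequency_sample()] or numeric vector of fractions.
#' @param criterion "r2" (default), "ssr" or "delta_loglik".
#' @param n_min minimum usable site count (default 100).
#' @param n_bins histogram bins for the ssr/r2 criteria.
#' @param retain retention interval of the fractions.
#' @param seed seed for the free-model restarts.
#' @param tie_tol relative tolerance below which two histogram criterion
#'   scores are considered tied (default 1e-3); the delta_loglik
#'   criterion instead ties within the likelihood-ratio significance
#'   bound for the nested models' extra parameters.
#' @return object of class `ploidy_call`: list(sample, ploidy ("2","3","4"
#'   or "unknown"), criterion, n_sites, scores data.frame with
#'   delta_loglik/ssr/r2 per ploidy).
#' @export
call_ploidy <- function(freqs, criterion = c("r2", "ssr", "delta_loglik"),
                        n_min = 100, n_bins = 100, retain = c(0.1, 0.9),
                        seed = 1, tie_tol = 1e-3) {
  criterion <- match.arg(criterion)
  x <- as_fractions(freqs)
  id <- if (inherits(freqs, "base_frequency_sample")) freqs$sample else NA_character_
  if (length(x) < n_min) {
    return(structure(list(sample = id, ploidy = "unknown",
                          criterion = criterion, n_sites = length(x),
                          scores = NULL),
                     class = "ploidy_call"))
  }
  free <- fit_free_mixture(x, n_min = n_min, seed = seed)
  scores <- do.call(rbind, lapply(2:4, function(p) {
    fit <- fit_fixed_mixture(x, p, n_min = n_min)
    ht <- histotest(x, fit, n_bins = n_bins, retain = retain)
    data.frame(ploidy = p,
               loglik = fit$loglik,
               delta_loglik = max(0, free$loglik - fit$loglik),
               ssr = ht$ssr, r2 = ht$r2)
  }))
  pick <- pick_by_criterion(scores, criterion, tie_tol)
  ploidy <- as.character(scores$ploidy[pick])
  structure(list(sample = id, ploidy = ploidy, criterion = criterion,
                 n_sites = length(x), scores = scores),
            class = "ploidy_call")
}

#' @export
#' @method print ploidy_call
print.ploidy_call <- function(x, ...) {
  cat("ploidy_call:", x$sample %||% "?", "-> ploidy", x$ploidy,
      sprintf("(criterion %s, %d sites)\n", x$criterion, x$n_sites))
  if (!is.null(x$scores)) print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Benchmark the three ploidy-calling criteria on labelled samples
#'
#' For samples of known ploidy, computes the success rate (fraction of
#' samples whose call matches the truth) of each criterion.
#'
#' @param samples list of [base_frequency_sample()] objects (or numeric
#'   vectors of fractions).
#' @param truth integer vector of true ploidies in {2,3,4}, one per sample.
#' @param ... passed to [call_ploidy()].
#' @return data.frame: criterion, n, n_correct, success_rate.
#' @export
benchmark_criteria <- function(samples, truth, ...) {
  stopifnot(length(samples) == length(truth), length(truth) > 0,
            all(truth %in% 2:4))
  calls <- lapply(samples, function(s) {
    sc <- call_ploidy(s, criterion = "r2", ...)$scores
    sc
  })
  res <- lapply(c("delta_loglik", "ssr", "r2"), function(cr) {
    called <- vapply(calls, function(sc) {
      if (is.null(sc)) return(NA_character_)
      as.character(sc$ploidy[pick_by_criterion(sc, cr)])
    }, character(1))
    ok <- called == as.character(truth)
    data.frame(criterion = cr, n = length(truth),
               n_correct = sum(ok, na.rm = TRUE),
               success_rate = mean(ok, na.rm = TRUE))
  })
  do.call(rbind, res)
}

# Index of the winning ploidy row: best score under the criterion, ties
# resolved toward the lowest ploidy (parsimony). A higher-ploidy mixture
# nests a lower one (the tetraploid contains the diploid as a
# weight-degenerate case), so it can never score worse: score gaps that
# carry no evidence must count as ties. For delta_loglik the tie scale is
# the likelihood-ratio significance bound for the two extra weight
# parameters (qchisq(0.95, 2)/2 ~ 3 log-likelihood units); for the
# histogram criteria a relative tolerance, far below genuine model gaps.
pick_by_criterion <- function(scores, criterion, tie_tol = 1e-3) {
  v <- scores[[criterion]]
  if (criterion == "r2") v <- -v
  best <- min(v)
  tied <- if (criterion == "delta_loglik") {
    which(v - best <= stats::qchisq(0.95, df = 2) / 2)
  } else {
    which(v - best <= tie_tol * max(abs(best), 1e-12) + 1e-12)
  }
  tied[which.min(scores$ploidy[tied])]
}

as_fractions <- function(freqs) {
  if (inherits(freqs, "base_frequency_sample")) return(freqs$fractions)
  stopifnot(is.numeric(freqs))
  as.numeric(freqs)
}
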