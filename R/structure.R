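#' Filter to biallelic loci with common minor alleles
#'
#' Drops loci whose minor allele frequency (over observed allele copies)
#' is not strictly greater than `maf_min`, the "superior to 5%" retention
#' rule. Loci of a [genotype_matrix()] are biallelic by construction;
#' monomorphic loci fall out via MAF 0.
#'
#' @param x a [genotype_matrix()].
#' @param maf_min strict lower bound on minor allele frequency.
#' @return a `genotype_matrix` restricted to the retained loci.
#' @export
filter_biallelic_maf <- function(x, maf_min = 0.05) {
  stopifnot(inherits(x, "genotype_matrix"), n_loci(x) > 0)
  maf <- locus_maf(x)
  subset_genotypes(x, loci = which(maf > maf_min))
}

locus_maf <- function(x) {
  pl <- matrix(x$ploidy, nrow = n_loci(x), ncol = n_samples(x), byrow = TRUE)
  obs <- !is.na(x$dosage)
  n <- rowSums(pl * obs)
  alt <- rowSums(x$dosage * obs, na.rm = TRUE)
  p <- ifelse(n > 0, alt / n, NA_real_)
  pmin(p, 1 - p)
}

#' LD pruning by windowed pairwise r-squared
#'
#' plink-style `--indep-pairwise` pruning: sliding windows of `window`
#' loci advanced by `step` loci; within a window, for every pair with
#' squared dosage correlation above `r2_max`, the later locus (genome
#' order) is removed; passes repeat until no window contains a violating
#' pair. Deterministic.
#'
#' @param x a [genotype_matrix()] with coordinate-sorted loci.
#' @param window window size in number of loci (default 50).
#' @param step window advance in loci (default 1).
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @return a `genotype_matrix` of retained loci; removed loci recorded in
#'   attribute `removed` (row indices into the input).
#' @export
ld_prune <- function(x, window = 50, step = 1, r2_max = 0.5) {
  stopifnot(inherits(x, "genotype_matrix"))
  L <- n_loci(x)
  keep <- rep(TRUE, L)
  dos <- x$dosage
  repeat {
    removed_any <- FALSE
    idx <- which(keep)
    if (length(idx) < 2) break
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      cm <- suppressWarnings(stats::cor(dos[w, , drop = FALSE] |> t(),
                                        use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      r2 <- cm^2
      for (a in seq_len(length(w) - 1)) {
        if (!keep[w[a]]) next
        for (b in seq(a + 1, length(w))) {
          if (!keep[w[b]]) next
          if (r2[a, b] > r2_max) {
            keep[w[b]] <- FALSE
            removed_any <- TRUE
          }
        }
      }
    }
    if (!removed_any) break
  }
  out <- subset_genotypes(x, loci = which(keep))
  attr(out, "removed") <- which(!keep)
  out
}

#' Identity-by-state distance matrix
#'
#' d_ij = 1 - mean over loci where both samples are called of the allele
#' sharing 1 - |dose_i - dose_j| / max_dose, with max_dose the dosage
#' range of the coding (2 for diploid-coded data). Identical samples get
#' 0; samples homozygous for opposite alleles at every locus get 1. Pairs
#' with no comparable loci get NA.
#'
#' @param x a [genotype_matrix()].
#' @param max_dose dosage range; defaults to the largest known ploidy.
#' @return symmetric matrix of class `dist`-compatible numeric with sample
#'   ids as dimnames.
#' @export
ibs_distance <- function(x, max_dose = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ns <- n_samples(x)
  if (ns < 2) stop("at least 2 samples required")
  max_dose <- max_dose %||% max(x$ploidy, 2L, na.rm = TRUE)
  D <- matrix(0, ns, ns, dimnames = list(x$samples, x$samples))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      a <- x$dosage[, i]; b <- x$dosage[, j]
      ok <- !is.na(a) & !is.na(b)
      D[i, j] <- D[j, i] <- if (!any(ok)) NA_real_ else
        mean(abs(a[ok] - b[ok])) / max_dose
    }
  }
  D
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a complete distance
#' matrix, with negative branch lengths clamped to zero. Exactly
#' consistent on additive distances.
#'
#' @param D symmetric numeric distance matrix with sample dimnames.
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3) stop("at least 3 samples required")
  if (anyNA(D)) stop("incomplete distance matrix")
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Admixture ancestry estimation by EM
#'
#' Maximum-likelihood estimation of the classic admixture model: sample i
#' carries m_i allele copies per locus, its alternate-allele dosage g_il
#' is Binomial(m_i, sum_k q_ik f_kl) with per-sample ancestry proportions
#' q_ik over K components and per-component allele frequencies f_kl. The
#' EM updates keep each Q row on the simplex and are monotone in the
#' log-likelihood; component frequencies are clamped to [eps, 1-eps].
#' Multiple seeded restarts are run and the best log-likelihood kept.
#'
#' Samples are diploid-coded by default (m_i = ploidy, capped at the
#' dosage range); missing genotypes contribute nothing.
#'
#' @param x a [genotype_matrix()].
#' @param K number of ancestry components.
#' @param seed seed for the restart initialisations.
#' @param restarts number of EM restarts (default 2).
#' @param max_iter,tol stopping rule (relative log-likelihood change).
#' @param eps clamp for component frequencies.
#' @return object of class `ancestry_fit`: list(Q (samples x K), F
#'   (K x loci), K, loglik, trace, iterations, converged).
#' @export
admixture_em <- function(x, K, seed = 1, restarts = 2, max_iter = 300,
                         tol = 1e-8, eps = 1e-6) {
  stopifnot(inherits(x, "genotype_matrix"), K >= 1)
  ns <- n_samples(x)
  if (K > ns) stop("K exceeds the number of samples")
  G <- t(x$dosage)                       # samples x loci
  pl <- x$ploidy; pl[is.na(pl)] <- 2L
  M <- matrix(pl, nrow = ns, ncol = ncol(G))
  M[is.na(G)] <- 0
  G[is.na(G)] <- 0L
  storage.mode(G) <- "double"

  if (K == 1) {
    n <- colSums(M)
    f <- ifelse(n > 0, colSums(G) / n, 0.5)
    f <- pmin(pmax(f, eps), 1 - eps)
    ll <- sum(G * log(matrix(f, ns, ncol(G), byrow = TRUE)) +
              (M - G) * log(matrix(1 - f, ns, ncol(G), byrow = TRUE)))
    return(structure(list(Q = matrix(1, ns, 1, dimnames = list(x$samples, NULL)),
                          F = matrix(f, 1), K = 1L, loglik = ll,
                          trace = ll, iterations = 0L, converged = TRUE),
                     class = "ancestry_fit"))
  }

  run_em <- function(Q, F_) {
    trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      P <- Q %*% F_                       # samples x loci: allele freq mix
      P <- pmin(pmax(P, eps), 1 - eps)
      ll <- sum(G * log(P) + (M - G) * log(1 - P))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
      A_num <- matrix(0, ns, K)          # expected alt copies from k
      B_num <- matrix(0, ns, K)          # expected ref copies from k
      F_num <- matrix(0, K, ncol(G))
      F_den <- matrix(0, K, ncol(G))
      for (k in seq_len(K)) {
        fa <- matrix(F_[k, ], ns, ncol(G), byrow = TRUE)
        a_k <- Q[, k] * fa / P            # resp of k for an alt copy
        b_k <- Q[, k] * (1 - fa) / (1 - P)
        ga <- G * a_k
        gb <- (M - G) * b_k
        A_num[, k] <- rowSums(ga)
        B_num[, k] <- rowSums(gb)
        F_num[k, ] <- colSums(ga)
        F_den[k, ] <- colSums(ga + gb)
      }
      tot <- rowSums(A_num + B_num)
      Q <- (A_num + B_num) / tot
      F_ <- F_num / pmax(F_den, .Machine$double.xmin)
      F_ <- pmin(pmax(F_, eps), 1 - eps)
    }
    list(Q = Q, F = F_, loglik = ll, trace = trace, iterations = iter,
         converged = iter < max_iter)
  }

  fits <- with_seed(seed, lapply(seq_len(restarts), function(r) {
    Q0 <- matrix(stats::rgamma(ns * K, 1), ns, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(stats::runif(K * ncol(G), 0.05, 0.95), K)
    run_em(Q0, F0)
  }))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  dimnames(best$Q) <- list(x$samples, paste0("K", seq_len(K)))
  structure(c(best, list(K = as.integer(K))), class = "ancestry_fit")
}

#' @export
#' @method print ancestry_fit
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, "components,", nrow(x$Q), "samples; logLik",
      signif(x$loglik, 8), "\n")
  invisible(x)
}

#' Assign samples to clades by an ancestry threshold
#'
#' A sample is assigned to its majority ancestry component only when that
#' component's proportion strictly exceeds the threshold (default 60%);
#' otherwise it is left unassigned as admixed.
#'
#' @param fit an `ancestry_fit` (or a Q matrix, samples x K).
#' @param threshold strict ancestry threshold (default 0.60).
#' @return data.frame: sample, component (NA when unassigned), max_q,
#'   assigned.
#' @export
assign_clades <- function(fit, threshold = 0.60) {
  Q <- if (inherits(fit, "ancestry_fit")) fit$Q else as.matrix(fit)
  max_q <- apply(Q, 1, max)
  comp <- apply(Q, 1, which.max)
  assigned <- max_q > threshold
  data.frame(sample = rownames(Q) %||% paste0("S", seq_len(nrow(Q))),
             component = ifelse(assigned, comp, NA_integer_),
             max_q = unname(max_q),
             assigned = unname(assigned),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group clades into superclades
#'
#' Attaches superclade labels to clade assignments using a grouping
#' configuration (a named list mapping superclade name to a vector of
#' component ids). Unmapped clades and unassigned samples get NA; config
#' entries referencing unknown components raise a warning.
#'
#' @param assignments result of [assign_clades()].
#' @param grouping named list, e.g. `list(Wine = c(1, 2), Wild = 3)`.
#' @return the assignments data.frame with a `superclade` column.
#' @export
group_superclades <- function(assignments, grouping) {
  stopifnot(is.data.frame(assignments), "component" %in% names(assignments))
  map <- rep(NA_character_, max(c(assignments$component, 0), na.rm = TRUE))
  known <- unique(stats::na.omit(assignments$component))
  for (nm in names(grouping)) {
    ids <- grouping[[nm]]
    unknown <- setdiff(ids, known)
    if (length(unknown))
      warning("superclade '", nm, "' references unknown clade ids: ",
              paste(unknown, collapse = ", "))
    ids <- ids[ids <= length(map) & ids >= 1]
    map[ids] <- nm
  }
  assignments$superclade <- ifelse(is.na(assignments$component), NA_character_,
                                   map[assignments$component])
  assignments
}

#' Align estimated ancestry components to truth labels
#'
#' Greedy one-to-one matching of estimated Q columns to reference Q
#' columns by maximal column correlation (equivalently minimal absolute
#' error), used to compare simulation truth with estimates up to label
#' switching.
#'
#' @param Q estimated matrix (samples x K).
#' @param Q_true reference matrix (samples x K).
#' @return Q with columns permuted to match Q_true.
#' @export
align_components <- function(Q, Q_true) {
  stopifnot(ncol(Q) == ncol(Q_true), nrow(Q) == nrow(Q_true))
  K <- ncol(Q)
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K))
    cost[a, b] <- mean(abs(Q[, a] - Q_true[, b]))
  perm <- integer(K)
  free_a <- seq_len(K); free_b <- seq_len(K)
  while (length(free_a)) {
    sub <- cost[free_a, free_b, drop = FALSE]
    pick <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    perm[free_b[pick[2]]] <- free_a[pick[1]]
    free_a <- free_a[-pick[1]]; free_b <- free_b[-pick[2]]
  }
  Q[, perm, drop = FALSE]
}
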