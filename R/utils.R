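`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded internals (EM restarts, jittered optimizer
#' starts) do not perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  invisible(x)
}

# median over a run-length encoded set of values: equivalent to
# stats::median(rep(values, lengths)) without materialising the expansion
rle_median <- function(values, lengths) {
  stopifnot(length(values) == length(lengths), all(lengths >= 0))
  keep <- lengths > 0
  values <- values[keep]; lengths <- lengths[keep]
  if (!length(values)) return(NA_real_)
  o <- order(values)
  values <- values[o]; lengths <- lengths[o]
  n <- sum(lengths)
  cum <- cumsum(lengths)
  if (n %% 2 == 1) {
    values[which(cum >= (n + 1) / 2)[1]]
  } else {
    lo <- values[which(cum >= n / 2)[1]]
    hi <- values[which(cum >= n / 2 + 1)[1]]
    (lo + hi) / 2
  }
}
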