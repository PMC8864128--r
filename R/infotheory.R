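#' Empirical entropy of a categorical variable
#'
#' `-sum p(x) log p(x)` in nats, with empirical frequencies and the
#' convention `0 log 0 = 0`.
#'
#' @param x Categorical vector (factor or character), non-empty.
#' @return Entropy in nats.
#' @export
entropy <- function(x) {
  if (!length(x)) stop("empty data", call. = FALSE)
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

#' Empirical conditional entropy
#'
#' `H(X | Y1, ..., Yk) = -sum p(x, y) log( p(x, y) / p(y) )` over the joint
#' empirical distribution, in nats.
#'
#' @param x Categorical vector.
#' @param given Categorical vector, data frame or list of conditioning
#'   vectors (the candidate parent set); empty set gives `H(X)`.
#' @return Conditional entropy in nats.
#' @export
conditional_entropy <- function(x, given = NULL) {
  if (!length(x)) stop("empty data", call. = FALSE)
  if (is.null(given) || (is.list(given) && !length(given)))
    return(entropy(x))
  if (!is.list(given)) given <- list(given)
  if (any(lengths(given) != length(x)))
    stop("conditioning variables must match the length of x", call. = FALSE)
  y <- do.call(paste, c(given, sep = "\r"))
  .cond_entropy_counts(as.integer(factor(x)), as.integer(factor(y)))
}

.cond_entropy_counts <- function(xi, yi) {
  n <- length(xi)
  kx <- max(xi)
  joint <- tabulate((yi - 1L) * kx + xi, nbins = max(yi) * kx)
  marg <- tabulate(yi)
  hxy <- {p <- joint[joint > 0] / n; -sum(p * log(p))}
  hy  <- {p <- marg[marg > 0] / n; -sum(p * log(p))}
  hxy - hy
}

#' Information gain of a parent set
#'
#' Returns `H(X) - H(X | parents)`, a non-negative quantity (zero iff `X`
#' is empirically independent of the parent set). Note the sign convention:
#' the gain is reported as entropy *reduction*; rankings are identical
#' either way by magnitude.
#'
#' @inheritParams conditional_entropy
#' @return Information gain in nats (>= 0 up to floating-point error).
#' @export
information_gain <- function(x, given = NULL) {
  entropy(x) - conditional_entropy(x, given)
}
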