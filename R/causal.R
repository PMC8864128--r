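#' Utility weights over the intention-change categories
#'
#' The default assigns 2, 1, 0, -1, -2 to `high-positive`, `low-positive`,
#' `neutral`, `low-negative`, `high-negative`, exactly as the outcome is
#' weighted in the study. Because a *positive* intention change means
#' *increased* meat intention, a desirability-oriented analysis may prefer
#' the negated weights: set `negate = TRUE` to flip every sign (which
#' negates every average potential effect exactly).
#'
#' @param negate Flip the sign convention (default `FALSE`: as printed).
#' @return Named numeric weights, strictly monotone over the ordered scale
#'   and summing to zero.
#' @export
utility_weights <- function(negate = FALSE) {
  w <- stats::setNames(c(-2, -1, 0, 1, 2), .OUTCOME_LABELS)
  if (isTRUE(negate)) -w else w
}

#' Expected utility of an outcome distribution
#'
#' `sum_z w(z) p(z)`; bounded by the weight range (`[-2, 2]` under the
#' defaults).
#'
#' @param dist Named probability vector over outcome categories (sums to 1).
#' @param weights Named weights covering every category of `dist`.
#' @return A single real.
#' @export
utility <- function(dist, weights = utility_weights()) {
  if (abs(sum(dist) - 1) > 1e-6)
    stop("dist must sum to 1", call. = FALSE)
  w <- weights[names(dist)]
  if (anyNA(w))
    stop("weights lack categor(ies): ",
         paste(setdiff(names(dist), names(weights)), collapse = ", "),
         call. = FALSE)
  sum(w * dist)
}

.resolve_model <- function(object, cpts) {
  if (inherits(object, "framing_dbn"))
    list(structure = object$structure, cpts = object$cpts)
  else if (inherits(object, "bn_structure")) {
    if (is.null(cpts)) stop("cpts required with a bare structure",
                            call. = FALSE)
    list(structure = object, cpts = cpts)
  } else stop("object must be a framing_dbn or bn_structure", call. = FALSE)
}

#' Average potential effect of a message framing
#'
#' The expected utility of the intention-change distribution under the
#' intervention `do(message)`, given the observed Time-1 antecedents.
#' Because the framing is randomized (the message node is parentless), the
#' Time-1 variables form the adjustment set and the do-intervention
#' coincides with conditioning. With full Time-1 observation the APE is
#' `sum_z w(z) p(z | m, T1)`; with partial observation the unobserved
#' Time-1 variables are summed out against their learned joint marginal
#' (back-door adjustment). Observation of post-treatment (Time-2)
#' variables is rejected: they lie on the indirect path from message to
#' outcome.
#'
#' @param object A `framing_dbn` model, or a [bn_structure()] (then supply
#'   `cpts`).
#' @param message Framing label (one of the message node's categories).
#' @param observed Named character vector/list of observed Time-1 values
#'   (possibly partial or empty).
#' @param weights Utility weights ([utility_weights()]).
#' @param cpts CPTs when `object` is a bare structure.
#' @return The APE (within the weight range, `[-2, 2]` by default).
#' @export
ape <- function(object, message, observed = list(),
                weights = utility_weights(), cpts = NULL) {
  mdl <- .resolve_model(object, cpts)
  struct <- mdl$structure; cpts <- mdl$cpts
  t1 <- .vars_in_slice(struct, "T1")
  obs <- unlist(observed)
  obs <- if (length(obs)) stats::setNames(as.character(obs), names(obs)) else
    stats::setNames(character(), character())
  bad <- setdiff(names(obs), t1)
  if (length(bad))
    stop("only Time-1 variables may be observed (post-treatment variables ",
         "lie on the indirect path): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hidden <- setdiff(t1, names(obs))
  if (!length(hidden))
    return(utility(posterior_target(struct, cpts, obs, message), weights))
  marg <- .t1_marginal(struct, cpts, hidden)
  tot <- 0
  for (i in seq_len(nrow(marg$grid))) {
    if (marg$p[i] == 0) next
    full <- c(obs, stats::setNames(marg$grid[i, ], hidden))
    tot <- tot + marg$p[i] *
      utility(posterior_target(struct, cpts, full, message), weights)
  }
  tot
}

## Joint marginal p(vars) under the network, by exact enumeration of the
## ancestral closure (all within Time 1, since arcs respect time order).
.t1_marginal <- function(struct, cpts, vars) {
  closure <- vars
  repeat {
    more <- unique(unlist(struct$parents[closure]))
    new <- setdiff(more, closure)
    if (!length(new)) break
    closure <- c(closure, new)
  }
  closure <- intersect(struct$order, closure)  # deterministic order
  cards <- .cards(struct)
  grid <- as.matrix(do.call(expand.grid,
                            c(lapply(cards[closure], seq_len),
                              list(KEEP.OUT.ATTRS = FALSE))))
  colnames(grid) <- closure
  w <- rep(1, nrow(grid))
  for (v in closure) {
    pa <- struct$parents[[v]]
    conf <- rep(1, nrow(grid)); mult <- 1
    for (p0 in pa) {
      conf <- conf + (grid[, p0] - 1) * mult
      mult <- mult * cards[[p0]]
    }
    w <- w * cpts[[v]]$prob[cbind(conf, grid[, v])]
  }
  key <- .config_index(grid, vars, cards)
  p <- as.numeric(rowsum(w, key, reorder = TRUE))
  vgrid <- as.matrix(do.call(expand.grid,
                             c(lapply(cards[vars], seq_len),
                               list(KEEP.OUT.ATTRS = FALSE))))
  colnames(vgrid) <- vars
  labels <- matrix("", nrow(vgrid), length(vars),
                   dimnames = list(NULL, vars))
  for (v in vars)
    labels[, v] <- struct$variables[[v]]$categories[vgrid[, v]]
  list(grid = labels, p = p / sum(p))
}

#' Per-individual effect vector over the four framings
#'
#' Computes the APE of each framing for one fully observed Time-1 profile,
#' plus the mean effect (average of the four), the best effect (the pivot,
#' i.e. the maximum), the delta effect (pivot minus mean) and the best
#' framing label. Exact ties resolve by the message node's category order
#' (gain, non-loss, non-gain, loss).
#'
#' @inheritParams ape
#' @param t1 Named character vector/list assigning every Time-1 variable.
#' @return An `effect_vector`: `effects` (named over framings),
#'   `mean_effect`, `best_effect`, `delta_effect`, `best_framing`.
#' @export
effect_vector <- function(object, t1, weights = utility_weights(),
                          cpts = NULL) {
  mdl <- .resolve_model(object, cpts)
  struct <- mdl$structure
  t1v <- .vars_in_slice(struct, "T1")
  t1 <- unlist(t1)
  miss <- setdiff(t1v, names(t1))
  if (length(miss))
    stop("full Time-1 assignment required; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  msg <- .message_var(struct)
  if (is.null(msg)) stop("structure has no MESSAGE variable", call. = FALSE)
  framings <- struct$variables[[msg]]$categories
  e <- vapply(framings, function(m)
    ape(struct, m, t1[t1v], weights, cpts = mdl$cpts), 0)
  best <- which.max(e)
  out <- list(effects = e, mean_effect = mean(e),
              best_effect = unname(e[best]),
              delta_effect = unname(e[best]) - mean(e),
              best_framing = framings[best], t1 = t1[t1v])
  class(out) <- "effect_vector"
  out
}

#' @export
print.effect_vector <- function(x, ...) {
  cat("Effect vector:",
      paste(sprintf("%s=%.4f", names(x$effects), x$effects),
            collapse = "  "), "\n")
  cat(sprintf("  mean %.4f | best %.4f (%s) | delta %.4f\n",
              x$mean_effect, x$best_effect, x$best_framing, x$delta_effect))
  invisible(x)
}
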