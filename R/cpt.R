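#' Estimate conditional probability tables
#'
#' Fits one conditional probability table (CPT) per node by Laplace-smoothed
#' maximum likelihood: each row is `(count + alpha) / (row total + alpha * K)`
#' over the node's `K` categories. With `alpha = 0` every parent
#' configuration must have support in the data.
#'
#' @param structure A [bn_structure()].
#' @param data Data frame of categorical assignments covering the
#'   structure's variables (labels within the declared category lists).
#' @param alpha Non-negative smoothing pseudo-count (default 1, Laplace).
#' @return A `bn_cpts` object: per node, `parents`, `counts` and `prob`
#'   matrices (parent configurations x categories; configuration keys are
#'   the parent labels joined by `|` in declared parent order).
#' @export
fit_cpts <- function(structure, data, alpha = 1) {
  stopifnot(inherits(structure, "bn_structure"), alpha >= 0)
  m <- .encode_data(structure, data)
  cards <- .cards(structure)
  cpts <- setNames(vector("list", length(structure$order)), structure$order)
  for (v in structure$order) {
    pa <- structure$parents[[v]]
    k <- cards[[v]]
    nconf <- if (length(pa)) prod(cards[pa]) else 1L
    conf <- .config_index(m, pa, cards)
    cell <- (conf - 1) * k + m[, v]
    counts <- matrix(tabulate(cell, nbins = nconf * k),
                     nrow = nconf, ncol = k, byrow = TRUE)
    rt <- rowSums(counts)
    if (alpha == 0 && any(rt == 0))
      stop("zero-support parent configuration for node '", v,
           "' with alpha = 0", call. = FALSE)
    prob <- (counts + alpha) / (rt + alpha * k)
    dimnames(counts) <- dimnames(prob) <-
      list(.config_keys(structure, pa),
           structure$variables[[v]]$categories)
    cpts[[v]] <- list(node = v, parents = pa, counts = counts, prob = prob,
                      alpha = alpha)
  }
  class(cpts) <- "bn_cpts"
  cpts
}

#' @export
print.bn_cpts <- function(x, ...) {
  cat("Conditional probability tables for", length(x), "nodes",
      sprintf("(alpha = %g)\n", x[[1L]]$alpha))
  for (v in names(x))
    cat(sprintf("  %s | {%s}: %d x %d\n", v,
                paste(x[[v]]$parents, collapse = ", "),
                nrow(x[[v]]$prob), ncol(x[[v]]$prob)))
  invisible(x)
}

#' Joint probability of a complete assignment
#'
#' Evaluates the factorized joint `prod_i p(x_i | parents(x_i))` for one
#' complete assignment of all variables.
#'
#' @param structure A [bn_structure()].
#' @param cpts A [fit_cpts()] result (or hand-built tables of the same shape).
#' @param assignment Named character vector/list mapping every variable to a
#'   category label.
#' @return A single probability.
#' @export
joint_probability <- function(structure, cpts, assignment) {
  assignment <- unlist(assignment)
  miss <- setdiff(structure$order, names(assignment))
  if (length(miss))
    stop("incomplete assignment; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- .encode_data(structure, as.data.frame(as.list(assignment),
                                             stringsAsFactors = FALSE,
                                             check.names = FALSE))
  cards <- .cards(structure)
  p <- 1
  for (v in structure$order) {
    conf <- .config_index(m, structure$parents[[v]], cards)
    p <- p * cpts[[v]]$prob[conf, m[, v]]
  }
  unname(p)
}

#' Posterior distribution of the target variable
#'
#' Exact inference by summation over the unobserved variables: returns
#' `p(Z = z | observations, message)` for every category `z` of the outcome
#' variable. Factors not involving the target or an unobserved variable
#' cancel in the normalization and are skipped.
#'
#' @inheritParams joint_probability
#' @param observations Named character vector/list of observed variables
#'   (partial; must not include the target).
#' @param message Optional framing label for the MESSAGE variable (may
#'   equivalently be supplied inside `observations`).
#' @param target Target variable name; defaults to the OUTCOME node.
#' @return Named probability vector over the target's categories (sums to 1).
#' @export
posterior_target <- function(structure, cpts, observations = list(),
                             message = NULL, target = NULL) {
  if (is.null(target)) target <- .outcome_var(structure)
  ev <- unlist(observations)
  ev <- if (length(ev)) setNames(as.character(ev), names(ev)) else
    setNames(character(), character())
  if (!is.null(message)) {
    mv <- .message_var(structure)
    if (is.null(mv)) stop("structure has no MESSAGE variable", call. = FALSE)
    ev[mv] <- as.character(message)
  }
  if (target %in% names(ev))
    stop("the target variable cannot be observed", call. = FALSE)
  unknown <- setdiff(names(ev), structure$order)
  if (length(unknown))
    stop("observation of unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (v in names(ev))
    if (!ev[[v]] %in% structure$variables[[v]]$categories)
      stop("value '", ev[[v]], "' not in the category list of '", v, "'",
           call. = FALSE)

  cards <- .cards(structure)
  free <- c(target, setdiff(structure$order, c(names(ev), target)))
  relevant <- Filter(function(v)
    v %in% free || length(intersect(structure$parents[[v]], free)),
    structure$order)

  grid <- do.call(expand.grid,
                  c(lapply(cards[free], seq_len),
                    list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- free
  w <- rep(1, nrow(grid))
  lookup <- function(v) {
    if (v %in% free) grid[[v]]
    else rep(match(ev[[v]], structure$variables[[v]]$categories), nrow(grid))
  }
  for (f in relevant) {
    pa <- structure$parents[[f]]
    conf <- rep(1, nrow(grid)); mult <- 1
    for (p0 in pa) {
      conf <- conf + (lookup(p0) - 1) * mult
      mult <- mult * cards[[p0]]
    }
    w <- w * cpts[[f]]$prob[cbind(conf, lookup(f))]
  }
  tot <- vapply(seq_len(cards[[target]]),
                function(z) sum(w[grid[[target]] == z]), 0)
  s <- sum(tot)
  if (s <= 0) {
    cond <- errorCondition(
      "contradictory evidence: the observed context has probability zero",
      class = "framecast_zero_probability")
    stop(cond)
  }
  setNames(tot / s, structure$variables[[target]]$categories)
}

#' Predict the modal target category
#'
#' The argmax of [posterior_target()]; exact ties are broken by category
#' order (most negative first), for determinism.
#'
#' @inheritParams posterior_target
#' @return A single category label of the target variable.
#' @export
predict_target <- function(structure, cpts, observations = list(),
                           message = NULL, target = NULL) {
  post <- posterior_target(structure, cpts, observations, message, target)
  names(post)[which.max(post)]
}

#' Ancestral sampling from a fitted network
#'
#' Draws complete assignments in topological order, each node from its CPT
#' row given the already-sampled parents.
#'
#' @inheritParams joint_probability
#' @param n Number of records to draw.
#' @return Data frame of factors (levels in declared category order).
#' @export
sample_network <- function(structure, cpts, n) {
  stopifnot(n >= 1)
  cards <- .cards(structure)
  m <- matrix(NA_integer_, nrow = n, ncol = length(structure$order),
              dimnames = list(NULL, structure$order))
  for (v in structure$topo) {
    pa <- structure$parents[[v]]
    conf <- .config_index(m, pa, cards)
    pr <- cpts[[v]]$prob
    cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE) # row cumsums
    u <- stats::runif(n)
    hit <- ncol(pr) + 1L - as.integer(rowSums(u <= cum[conf, , drop = FALSE]))
    m[, v] <- pmin.int(ncol(pr), pmax.int(1L, hit))
  }
  out <- as.data.frame(lapply(structure$order, function(v)
    factor(structure$variables[[v]]$categories[m[, v]],
           levels = structure$variables[[v]]$categories)))
  names(out) <- structure$order
  out
}

## ---- vectorized batch posterior (shared by mAUC, LOO and profiling) --------
##
## Returns an n x K matrix of posteriors of `target` given the evidence
## variables of each row of `m` (integer-encoded data). With `loo = TRUE`
## each row's own contribution to the counts is subtracted before the
## probability lookup (exact leave-one-out, no refitting).
.posterior_batch <- function(structure, cpts, m, evidence_vars,
                             target = NULL, loo = FALSE) {
  if (is.null(target)) target <- .outcome_var(structure)
  cards <- .cards(structure)
  n <- nrow(m)
  ktar <- cards[[target]]
  free <- c(target, setdiff(structure$order, c(evidence_vars, target)))
  relevant <- Filter(function(v)
    v %in% free || length(intersect(structure$parents[[v]], free)),
    structure$order)
  grid <- as.matrix(do.call(expand.grid,
                            c(lapply(cards[free], seq_len),
                              list(KEEP.OUT.ATTRS = FALSE))))
  colnames(grid) <- free
  post <- matrix(0, nrow = n, ncol = ktar,
                 dimnames = list(NULL,
                                 structure$variables[[target]]$categories))
  alpha <- cpts[[1L]]$alpha
  for (g in seq_len(nrow(grid))) {
    w <- rep(1, n)
    val_of <- function(v)
      if (v %in% free) rep(grid[g, v], n) else m[, v]
    for (f in relevant) {
      pa <- structure$parents[[f]]
      conf <- rep(1, n); mult <- 1
      for (p0 in pa) {
        conf <- conf + (val_of(p0) - 1) * mult
        mult <- mult * cards[[p0]]
      }
      val <- val_of(f)
      if (!loo) {
        w <- w * cpts[[f]]$prob[cbind(conf, val)]
      } else {
        cnt <- cpts[[f]]$counts
        num <- cnt[cbind(conf, val)]
        den <- rowSums(cnt)[conf]
        ## does this row's own record sit in the looked-up cell?
        self_pa <- rep(TRUE, n)
        for (p0 in pa) if (p0 %in% free)
          self_pa <- self_pa & (m[, p0] == grid[g, p0])
        self_val <- if (f %in% free) self_pa & (m[, f] == grid[g, f]) else self_pa
        kf <- cards[[f]]
        w <- w * (num + alpha - self_val) / (den + alpha * kf - self_pa)
      }
    }
    z <- grid[g, target]
    post[, z] <- post[, z] + w
  }
  post / rowSums(post)
}
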