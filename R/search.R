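#' Binary area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula, which equals the trapezoidal
#' area under the ROC swept by the acceptance threshold; tied scores
#' contribute one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical/0-1 vector (or two-level factor, second level
#'   positive); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  ## tolerant tie detection: scores equal up to floating-point noise must
  ## share a rank, whatever arithmetic path produced them
  r <- rank(signif(scores, 10L), ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC (Hand-Till M measure)
#'
#' One-vs-one pairing of the class-posterior scores:
#' `M = 2 / (c (c - 1)) * sum_{i<j} A(i, j)` with
#' `A(i, j) = (A(i | j) + A(j | i)) / 2`, each term a [binary_auc()] of the
#' class-`i` (resp. `j`) posterior restricted to rows of classes `i` and
#' `j`. With two classes this reduces exactly to the binary AUC.
#'
#' @param posteriors Matrix of per-row class posteriors with class labels
#'   as column names.
#' @param labels Observed class labels (>= 2 distinct values present).
#' @return mAUC in `[0, 1]`.
#' @export
mauc <- function(posteriors, labels) {
  labels <- as.character(labels)
  posteriors <- as.matrix(posteriors)
  classes <- intersect(colnames(posteriors), unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 classes present", call. = FALSE)
  tot <- 0
  for (a in seq_along(classes)[-length(classes)]) {
    for (b in seq((a + 1L), length(classes))) {
      i <- classes[a]; j <- classes[b]
      sel <- labels %in% c(i, j)
      aij <- binary_auc(posteriors[sel, i], labels[sel] == i)
      aji <- binary_auc(posteriors[sel, j], labels[sel] == j)
      tot <- tot + (aij + aji) / 2
    }
  }
  c0 <- length(classes)
  2 * tot / (c0 * (c0 - 1))
}

#' In-sample mAUC of a structure on a dataset
#'
#' Probabilities are learnt from the full dataset and applied back to every
#' record: the posterior of the target given each record's Time-1 evidence
#' and message feeds [mauc()].
#'
#' @param structure A [bn_structure()].
#' @param data Categorical data frame.
#' @param alpha Smoothing pseudo-count for [fit_cpts()].
#' @return mAUC in `[0, 1]`.
#' @export
insample_mauc <- function(structure, data, alpha = 1) {
  .structure_mauc(structure, data, alpha, loo = FALSE)
}

#' Leave-one-out mAUC of a structure on a dataset
#'
#' For each record the CPTs are refit on the remaining records (implemented
#' exactly, by subtracting the held-out record's contribution from the
#' affected count cells) and the posterior of the target given that
#' record's Time-1 evidence and message is scored out-of-sample.
#'
#' @inheritParams insample_mauc
#' @return mAUC in `[0, 1]`.
#' @export
loo_mauc <- function(structure, data, alpha = 1) {
  if (alpha <= 0)
    stop("leave-one-out evaluation requires alpha > 0 (a class can vanish ",
         "from a training fold)", call. = FALSE)
  .structure_mauc(structure, data, alpha, loo = TRUE)
}

.structure_mauc <- function(structure, data, alpha, loo) {
  target <- .outcome_var(structure)
  ev <- c(.vars_in_slice(structure, "T1"), .message_var(structure))
  cpts <- fit_cpts(structure, data, alpha)
  m <- .encode_data(structure, data)
  post <- .posterior_batch(structure, cpts, m, ev, target, loo = loo)
  mauc(post, as.character(data[[target]]))
}

#' Screening and selection settings for structure elicitation
#'
#' @param max_parents_outcome Maximum parent-set size screened for the
#'   outcome node (default 6: message + mediator + four antecedents).
#' @param max_parents_t2 Maximum parent-set size for Time-2 nodes
#'   (default 5: message + four antecedents).
#' @param top_k Parent sets retained per node after screening (default 3).
#' @param alpha Smoothing pseudo-count used when scoring candidates.
#' @param allow_intra_t2 Allow arcs between Time-2 nodes (default `FALSE`;
#'   the study's graph class has none).
#' @return A `search_control` list.
#' @export
search_control <- function(max_parents_outcome = 6L, max_parents_t2 = 5L,
                           top_k = 3L, alpha = 1, allow_intra_t2 = FALSE) {
  stopifnot(max_parents_outcome >= 0, max_parents_t2 >= 0, top_k >= 1,
            alpha >= 0)
  out <- list(max_parents_outcome = as.integer(max_parents_outcome),
              max_parents_t2 = as.integer(max_parents_t2),
              top_k = as.integer(top_k), alpha = alpha,
              allow_intra_t2 = isTRUE(allow_intra_t2))
  class(out) <- "search_control"
  out
}

#' Rank candidate parent sets of a node by information gain
#'
#' Enumerates every subset of the allowed parents up to `max_size` and
#' scores it by the empirical information gain `H(X) - H(X | set)`.
#' Ties are broken deterministically: smaller set first, then
#' lexicographic variable names.
#'
#' @param data Categorical data frame.
#' @param node Child variable name.
#' @param allowed Character vector of admissible parent names (must respect
#'   the time-slice constraints of the caller; the node itself is
#'   excluded automatically).
#' @param max_size Largest subset size enumerated.
#' @param top_k Number of top-ranked sets retained in `$retained`.
#' @return A `parent_screen` object: data frame `$table` with columns
#'   `set` (list of character vectors), `size`, `entropy`, `cond_entropy`,
#'   `info_gain`, sorted by rank; `$retained` the top-k parent sets.
#' @export
screen_parent_sets <- function(data, node, allowed, max_size, top_k = 3L) {
  if (max_size < 0) stop("max_size must be >= 0", call. = FALSE)
  allowed <- setdiff(unique(as.character(allowed)), node)
  x <- data[[node]]
  if (is.null(x)) stop("unknown node '", node, "'", call. = FALSE)
  xi <- as.integer(factor(x))
  hx <- entropy(x)

  enc <- lapply(allowed, function(v) as.integer(factor(data[[v]])))
  names(enc) <- allowed
  card <- vapply(enc, max, 1L)

  sets <- list(character())
  for (s in seq_len(min(max_size, length(allowed))))
    sets <- c(sets, utils::combn(allowed, s, simplify = FALSE))

  hcond <- vapply(sets, function(s) {
    if (!length(s)) return(hx)
    yi <- rep(1L, length(xi)); mult <- 1L
    for (v in s) {
      yi <- yi + (enc[[v]] - 1L) * mult
      mult <- mult * card[[v]]
    }
    .cond_entropy_counts(xi, yi)
  }, 0)
  ig <- hx - hcond
  sizes <- lengths(sets)
  key <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  ord <- order(-ig, sizes, key, method = "radix")
  tab <- data.frame(size = sizes[ord], entropy = hx,
                    cond_entropy = hcond[ord], info_gain = ig[ord])
  tab$set <- sets[ord]
  out <- list(node = node, table = tab,
              retained = sets[ord][seq_len(min(top_k, length(sets)))])
  class(out) <- "parent_screen"
  out
}

#' @export
print.parent_screen <- function(x, ...) {
  cat("Parent-set screening for '", x$node, "' (", nrow(x$table),
      " subsets)\n", sep = "")
  top <- utils::head(x$table, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  IG %.4f  {%s}\n", top$info_gain[i],
                paste(top$set[[i]], collapse = ", ")))
  invisible(x)
}

#' Build the candidate-structure pool from screening results
#'
#' Takes the retained parent sets of the outcome and each Time-2 node
#' (screened backward from the target) and forms their cross product;
#' candidates violating the graph-class constraints (acyclicity, time
#' orientation, parentless MESSAGE, childless OUTCOME) are filtered out.
#'
#' @param screenings Named list of [screen_parent_sets()] results (or plain
#'   lists of parent sets), one entry per searched node.
#' @param variables List of [bn_variable()] specs for the full model.
#' @return List of `bn_structure` candidates (non-empty).
#' @export
enumerate_candidates <- function(screenings, variables) {
  sets <- lapply(screenings, function(s)
    if (inherits(s, "parent_screen")) s$retained else s)
  nodes <- names(sets)
  if (is.null(nodes) || !all(nzchar(nodes)))
    stop("screenings must be a named list (one entry per searched node)",
         call. = FALSE)
  combos <- do.call(expand.grid,
                    c(lapply(sets, seq_along), list(KEEP.OUT.ATTRS = FALSE)))
  pool <- list()
  for (r in seq_len(nrow(combos))) {
    arcs <- list()
    for (v in nodes) {
      pa <- sets[[v]][[combos[r, v]]]
      for (p0 in pa) arcs[[length(arcs) + 1L]] <- c(p0, v)
    }
    cand <- tryCatch(
      bn_structure(variables, if (length(arcs)) arcs else NULL),
      error = function(e) NULL)
    if (!is.null(cand)) pool[[length(pool) + 1L]] <- cand
  }
  if (!length(pool)) stop("empty candidate pool", call. = FALSE)
  pool
}

#' Select the best candidate structure by the combined mAUC metric
#'
#' Scores every candidate by in-sample mAUC and leave-one-out mAUC,
#' normalizes each by the pool maximum and sums:
#' `m = mAUC_in / max(mAUC_in) + mAUC_out / max(mAUC_out)`.
#' The highest `m` wins; exact ties are broken by fewer arcs, then by the
#' lexicographic arc list.
#'
#' @param candidates List of [bn_structure()] candidates (>= 1).
#' @param data Categorical data frame.
#' @param alpha Smoothing pseudo-count.
#' @return A `candidate_selection` list: `structure` (the winner),
#'   `mauc_in`, `mauc_out`, `m_score`, and `pool` (a data frame scoring
#'   every candidate).
#' @export
select_structure <- function(candidates, data, alpha = 1) {
  if (!length(candidates)) stop("empty candidate pool", call. = FALSE)
  mauc_in <- vapply(candidates, insample_mauc, 0, data = data, alpha = alpha)
  mauc_out <- vapply(candidates, loo_mauc, 0, data = data, alpha = alpha)
  m <- mauc_in / max(mauc_in) + mauc_out / max(mauc_out)
  n_arcs <- vapply(candidates, function(s) nrow(s$arcs), 0L)
  arc_key <- vapply(candidates, function(s)
    paste(sort(paste(s$arcs[, 1L], s$arcs[, 2L], sep = ">")), collapse = ";"),
    "")
  ord <- order(-m, n_arcs, arc_key, method = "radix")
  best <- ord[1L]
  out <- list(structure = candidates[[best]],
              mauc_in = mauc_in[best], mauc_out = mauc_out[best],
              m_score = m[best],
              pool = data.frame(candidate = seq_along(candidates),
                                mauc_in = mauc_in, mauc_out = mauc_out,
                                m_score = m, n_arcs = n_arcs)[ord, ])
  class(out) <- "candidate_selection"
  out
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat(sprintf(
    "Selected structure: m = %.4f (mAUC in %.4f / out %.4f) of %d candidates\n",
    x$m_score, x$mauc_in, x$mauc_out, nrow(x$pool)))
  invisible(x)
}

#' Elicit a network structure from data
#'
#' The full automated elicitation: screen parent sets backward from the
#' target (outcome first, allowed parents = message, Time-2 and Time-1
#' variables; then each Time-2 node, allowed parents = message and Time-1
#' variables), form the candidate pool from the retained sets, and select
#' the structure maximizing the combined in-/out-of-sample mAUC metric.
#'
#' @param data Categorical data frame covering all declared variables.
#' @param variables List of [bn_variable()] specs.
#' @param control A [search_control()].
#' @return A `candidate_selection` (see [select_structure()]) with the
#'   screening reports attached as `$screenings`.
#' @export
elicit_structure <- function(data, variables, control = search_control()) {
  variables <- lapply(variables, function(v)
    if (inherits(v, "bn_variable")) v else do.call(bn_variable, v))
  names(variables) <- vapply(variables, `[[`, "", "name")
  sl <- vapply(variables, `[[`, "", "slice")
  t1 <- names(variables)[sl == "T1"]
  msg <- names(variables)[sl == "MESSAGE"]
  t2 <- names(variables)[sl == "T2"]
  z <- names(variables)[sl == "OUTCOME"]
  if (length(z) != 1L) stop("exactly one OUTCOME variable", call. = FALSE)

  screenings <- list()
  screenings[[z]] <- screen_parent_sets(
    data, z, allowed = c(msg, t2, t1),
    max_size = control$max_parents_outcome, top_k = control$top_k)
  for (v in t2) {
    allowed <- c(msg, t1, if (control$allow_intra_t2) setdiff(t2, v))
    screenings[[v]] <- screen_parent_sets(
      data, v, allowed = allowed,
      max_size = control$max_parents_t2, top_k = control$top_k)
  }
  pool <- enumerate_candidates(screenings, variables)
  sel <- select_structure(pool, data, alpha = control$alpha)
  sel$screenings <- screenings
  sel
}
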