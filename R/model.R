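#' Fit a message-framing dynamic Bayesian network
#'
#' The package's central fitting function. Given a discretized two-wave
#' study table, it either takes a fixed network structure or elicits one
#' automatically (information-gain screening of parent sets, candidate
#' enumeration, and selection by the combined in-sample / leave-one-out
#' multiclass-AUC metric), then estimates smoothed conditional probability
#' tables. The fitted object doubles as a graphical causal model: because
#' the message framing is randomized, the Time-1 antecedents form the
#' adjustment set and average potential effects of the four framings are
#' identified by back-door adjustment (see [ape()], [profile_population()]).
#'
#' @param data Data frame of categorical assignments (factors) covering all
#'   model variables, e.g. from [apply_discretization()].
#' @param structure A fixed [bn_structure()]; `NULL` to elicit one from
#'   `data` (then `variables` is required).
#' @param variables List of [bn_variable()] specs delimiting the search
#'   (see [study_variables()]); ignored when `structure` is given.
#' @param alpha Smoothing pseudo-count for the CPTs (default 1, Laplace;
#'   the outcome node may have hundreds of parent configurations against a
#'   few hundred records, so unsmoothed leave-one-out is undefined).
#' @param control [search_control()] settings for the elicitation.
#' @param weights Default utility weights attached to the model.
#' @return A `framing_dbn` object with components `structure`, `cpts`,
#'   `alpha`, `mauc_in`, `mauc_out`, `search` (the `candidate_selection`
#'   when elicited), `data`, `n`, `weights`, `call`.
#' @seealso [predict.framing_dbn()], [simulate.framing_dbn()], [ape()],
#'   [effect_vector()], [profile_population()], [extract_prototypes()]
#' @export
framing_dbn <- function(data, structure = NULL, variables = NULL,
                        alpha = 1, control = search_control(),
                        weights = utility_weights()) {
  search <- NULL
  if (is.null(structure)) {
    if (is.null(variables))
      stop("supply either a structure or variable specs to elicit one",
           call. = FALSE)
    search <- elicit_structure(data, variables, control)
    structure <- search$structure
  }
  stopifnot(inherits(structure, "bn_structure"))
  cpts <- fit_cpts(structure, data, alpha)
  mauc_in <- if (!is.null(search)) search$mauc_in else
    tryCatch(insample_mauc(structure, data, alpha), error = function(e) NA_real_)
  mauc_out <- if (!is.null(search)) search$mauc_out else
    tryCatch(loo_mauc(structure, data, alpha), error = function(e) NA_real_)
  obj <- list(structure = structure, cpts = cpts, alpha = alpha,
              mauc_in = mauc_in, mauc_out = mauc_out, search = search,
              data = data, n = nrow(data), weights = weights,
              call = match.call())
  class(obj) <- "framing_dbn"
  obj
}

#' Wrap a known structure and CPTs as a model object
#'
#' For ground-truth or externally loaded networks (no fitting involved).
#'
#' @param structure A [bn_structure()].
#' @param cpts Matching CPTs.
#' @param weights Default utility weights.
#' @return A `framing_dbn`.
#' @export
as_framing_dbn <- function(structure, cpts, weights = utility_weights()) {
  stopifnot(inherits(structure, "bn_structure"))
  obj <- list(structure = structure, cpts = cpts,
              alpha = cpts[[1L]]$alpha, mauc_in = NA_real_,
              mauc_out = NA_real_, search = NULL, data = NULL, n = NA_integer_,
              weights = weights, call = match.call())
  class(obj) <- "framing_dbn"
  obj
}

#' @export
print.framing_dbn <- function(x, ...) {
  cat("Message-framing dynamic Bayesian network\n")
  cat(sprintf("  %d variables, %d arcs; n = %s; alpha = %g\n",
              length(x$structure$variables), nrow(x$structure$arcs),
              ifelse(is.na(x$n), "-", x$n), x$alpha))
  if (!is.na(x$mauc_in))
    cat(sprintf("  mAUC in-sample %.4f | leave-one-out %.4f\n",
                x$mauc_in, x$mauc_out))
  z <- .outcome_var(x$structure)
  cat("  outcome:", z, "| parents:",
      paste(x$structure$parents[[z]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.framing_dbn <- function(object, ...) {
  s <- object$structure
  rows <- data.frame(
    node = s$order,
    slice = vapply(s$variables, `[[`, "", "slice"),
    categories = vapply(s$variables, function(v) length(v$categories), 1L),
    parents = vapply(s$order, function(v)
      paste(s$parents[[v]], collapse = ", "), ""),
    cpt_rows = vapply(s$order, function(v) nrow(object$cpts[[v]]$prob), 1L),
    row.names = NULL)
  out <- list(model = object, nodes = rows)
  class(out) <- "summary.framing_dbn"
  out
}

#' @export
print.summary.framing_dbn <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' @export
coef.framing_dbn <- function(object, ...) {
  lapply(object$cpts, `[[`, "prob")
}

#' @export
logLik.framing_dbn <- function(object, ...) {
  if (is.null(object$data))
    stop("no training data stored in the model", call. = FALSE)
  m <- .encode_data(object$structure, object$data)
  cards <- .cards(object$structure)
  ll <- 0
  npar <- 0
  for (v in object$structure$order) {
    conf <- .config_index(m, object$structure$parents[[v]], cards)
    ll <- ll + sum(log(object$cpts[[v]]$prob[cbind(conf, m[, v])]))
    npar <- npar + nrow(object$cpts[[v]]$prob) * (cards[[v]] - 1L)
  }
  structure(ll, df = npar, nobs = nrow(m), class = "logLik")
}

#' Predict intention change for new profiles
#'
#' Posterior of the outcome given each row's observed Time-1 variables and
#' message condition (exact inference, unobserved variables summed out), or
#' the modal category (ties broken by category order, most negative first).
#'
#' @param object A `framing_dbn`.
#' @param newdata Data frame of profiles; any subset of Time-1 columns plus
#'   optionally `condition`. Defaults to the training data.
#' @param message Framing applied to every row (overrides a condition
#'   column).
#' @param type `"class"` (default) or `"posterior"`.
#' @param ... Unused.
#' @return Factor of predicted categories, or a matrix of posteriors.
#' @export
predict.framing_dbn <- function(object, newdata = NULL, message = NULL,
                                type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  struct <- object$structure
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata)) stop("newdata required", call. = FALSE)
  msg <- .message_var(struct)
  target <- .outcome_var(struct)
  if (!is.null(message)) {
    if (is.null(msg)) stop("structure has no MESSAGE variable", call. = FALSE)
    newdata[[msg]] <- factor(rep(as.character(message), nrow(newdata)),
                             levels = struct$variables[[msg]]$categories)
  }
  evidence <- intersect(struct$order,
                        intersect(names(newdata),
                                  c(.vars_in_slice(struct, "T1"), msg)))
  m <- matrix(1L, nrow = nrow(newdata), ncol = length(struct$order),
              dimnames = list(NULL, struct$order))
  for (v in evidence) {
    cats <- struct$variables[[v]]$categories
    idx <- match(as.character(newdata[[v]]), cats)
    if (anyNA(idx))
      stop("newdata variable '", v, "' has values outside its categories",
           call. = FALSE)
    m[, v] <- idx
  }
  post <- .posterior_batch(struct, object$cpts, m, evidence, target)
  if (type == "posterior") return(post)
  cats <- struct$variables[[target]]$categories
  factor(cats[max.col(post, ties.method = "first")], levels = cats)
}

#' Simulate records from the fitted joint distribution
#'
#' Ancestral sampling of complete categorical records (all slices) from the
#' fitted network.
#'
#' @param object A `framing_dbn`.
#' @param nsim Number of records.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of factors with `nsim` rows.
#' @export
simulate.framing_dbn <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_network(object$structure, object$cpts, nsim)
}

#' Plot the network layered by time slice
#'
#' Nodes are arranged in four columns (Time 1, message, Time 2, outcome)
#' and arcs drawn left to right.
#'
#' @param x A `framing_dbn` or `bn_structure`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.framing_dbn <- function(x, ...) {
  plot(x$structure, ...)
  invisible(x)
}

#' @export
plot.bn_structure <- function(x, ...) {
  sl <- vapply(x$variables, `[[`, "", "slice")
  xs <- .SLICES[sl]
  ys <- stats::ave(seq_along(xs), xs, FUN = function(i)
    seq_along(i) - (length(i) + 1) / 2)
  names(xs) <- names(ys) <- names(x$variables)
  graphics::plot(NA, xlim = c(0.5, 4.5), ylim = range(ys) + c(-0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = 1:4, labels = names(.SLICES), tick = FALSE)
  if (nrow(x$arcs))
    graphics::arrows(xs[x$arcs[, 1L]], ys[x$arcs[, 1L]],
                     xs[x$arcs[, 2L]], ys[x$arcs[, 2L]],
                     length = 0.08, col = "grey40")
  graphics::points(xs, ys, pch = 21, bg = "white", cex = 3)
  graphics::text(xs, ys, labels = abbreviate(names(xs), 8L), cex = 0.6,
                 pos = 3, offset = 0.7)
  invisible(x)
}
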