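#' Enumerate the complete simulated population
#'
#' One individual per possible configuration of the Time-1 categorical
#' variables, in deterministic mixed-radix order (first declared variable
#' varies fastest). Eight ternary antecedents give 3^8 = 6561 individuals.
#'
#' @param structure A [bn_structure()] (or a `framing_dbn`).
#' @return Data frame of factors, one row per Time-1 profile (a single
#'   empty profile when the structure has no Time-1 variables).
#' @export
enumerate_population <- function(structure) {
  if (inherits(structure, "framing_dbn")) structure <- structure$structure
  stopifnot(inherits(structure, "bn_structure"))
  t1 <- .vars_in_slice(structure, "T1")
  if (!length(t1))
    return(as.data.frame(matrix(nrow = 1L, ncol = 0L)))
  grid <- do.call(expand.grid,
                  c(lapply(t1, function(v)
                      structure$variables[[v]]$categories),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  names(grid) <- t1
  for (v in t1)
    grid[[v]] <- factor(grid[[v]],
                        levels = structure$variables[[v]]$categories)
  grid
}

#' Attach effect vectors to the enumerated population
#'
#' Computes the four per-framing average potential effects for every
#' enumerated Time-1 profile (in enumeration order), plus the mean, best
#' and delta effect summaries and the best framing label. The per-framing
#' posteriors are computed exactly, vectorized over the population.
#'
#' @param object A `framing_dbn` model, or a [bn_structure()] plus `cpts`.
#' @param weights Utility weights ([utility_weights()]).
#' @param cpts CPTs when `object` is a bare structure.
#' @return An `effect_profile` data frame: the Time-1 assignment columns,
#'   `e_<framing>` effect columns, `mean_effect`, `best_effect`,
#'   `delta_effect`, `best_framing`.
#' @export
profile_population <- function(object, weights = utility_weights(),
                               cpts = NULL) {
  mdl <- .resolve_model(object, cpts)
  struct <- mdl$structure; cpts <- mdl$cpts
  msg <- .message_var(struct)
  if (is.null(msg)) stop("structure has no MESSAGE variable", call. = FALSE)
  framings <- struct$variables[[msg]]$categories
  target <- .outcome_var(struct)
  pop <- enumerate_population(struct)
  t1 <- .vars_in_slice(struct, "T1")
  n <- nrow(pop)
  cards <- .cards(struct)

  m <- matrix(1L, nrow = n, ncol = length(struct$order),
              dimnames = list(NULL, struct$order))
  for (v in t1) m[, v] <- as.integer(pop[[v]])
  wvec <- NULL
  E <- matrix(0, nrow = n, ncol = length(framings),
              dimnames = list(NULL, paste0("e_", framings)))
  for (k in seq_along(framings)) {
    m[, msg] <- k
    post <- .posterior_batch(struct, cpts, m, c(t1, msg), target)
    if (is.null(wvec)) {
      wvec <- weights[colnames(post)]
      if (anyNA(wvec))
        stop("weights lack categor(ies): ",
             paste(setdiff(colnames(post), names(weights)), collapse = ", "),
             call. = FALSE)
    }
    E[, k] <- as.numeric(post %*% wvec)
  }
  best <- max.col(E, ties.method = "first")
  out <- cbind(pop, as.data.frame(E))
  out$mean_effect <- rowMeans(E)
  out$best_effect <- E[cbind(seq_len(n), best)]
  out$delta_effect <- out$best_effect - out$mean_effect
  out$best_framing <- factor(framings[best], levels = framings)
  attr(out, "framings") <- framings
  attr(out, "effect_cols") <- paste0("e_", framings)
  attr(out, "t1_vars") <- t1
  class(out) <- c("effect_profile", "data.frame")
  out
}

.effect_matrix <- function(x) {
  if (inherits(x, "effect_profile"))
    as.matrix(as.data.frame(x)[, attr(x, "effect_cols"), drop = FALSE])
  else if (inherits(x, "effect_vector")) matrix(x$effects, nrow = 1L)
  else as.matrix(x)
}

#' Euclidean dissimilarity between two effect vectors
#'
#' The soft-clustering dissimilarity of the analysis: the Euclidean
#' distance between the 4-dimensional per-framing effect vectors.
#'
#' @param v1,v2 Numeric 4-vectors, `effect_vector` objects, or single-row
#'   `effect_profile` slices.
#' @return Non-negative real.
#' @export
dissimilarity <- function(v1, v2) {
  a <- as.numeric(.effect_matrix(v1)); b <- as.numeric(.effect_matrix(v2))
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

#' Extract receiver prototypes by quantile selection
#'
#' Six groups of exactly `ceiling(q * N)` individuals: for each framing,
#' the top individuals by best effect among those whose best framing is
#' that framing (set `restrict = FALSE` to rank everyone by that framing's
#' own effect); the *indifferent* receivers (bottom by delta effect,
#' equally swayed by all framings); and the *oppositive* receivers (bottom
#' by mean effect, expected to react negatively regardless of framing).
#' Each group is summarized by the modal category of the reporting
#' dimensions.
#'
#' @param profile An [profile_population()] result.
#' @param q Quantile fraction (default 0.02, the 2 percent tails).
#' @param dims Reporting dimensions for the modal profile (default:
#'   baseline intention, prevention focus, perceived severity).
#' @param restrict Restrict each framing's pool to individuals whose best
#'   framing is that framing (default `TRUE`).
#' @return A `prototype_report`: list of groups with `criterion`,
#'   `framing`, `indices`, `n`, `modal_profile`.
#' @export
extract_prototypes <- function(profile, q = 0.02,
                               dims = c("baseline_intention",
                                        "prevention_focus",
                                        "perceived_severity"),
                               restrict = TRUE) {
  stopifnot(inherits(profile, "effect_profile"))
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  N <- nrow(profile)
  size <- ceiling(q * N)
  if (size < 1) stop("q * N < 1: no individuals to select", call. = FALSE)
  dims <- as.character(dims)
  missd <- setdiff(dims, names(profile))
  if (length(missd))
    stop("unknown reporting dimension(s): ", paste(missd, collapse = ", "),
         call. = FALSE)
  framings <- attr(profile, "framings")
  df <- as.data.frame(profile)

  take <- function(ord, pool, k) pool[ord][seq_len(min(k, length(pool)))]
  modal <- function(idx) {
    vapply(dims, function(d) {
      tab <- table(df[[d]][idx])
      names(tab)[which.max(tab)]
    }, "")
  }
  groups <- list()
  for (f in framings) {
    pool <- if (restrict) which(df$best_framing == f) else seq_len(N)
    if (!length(pool)) {
      warning("no individual has best framing '", f, "'", call. = FALSE)
      next
    }
    score <- if (restrict) df$best_effect[pool] else df[[paste0("e_", f)]][pool]
    idx <- take(order(-score), pool, size)
    if (length(idx) < size)
      warning("best-", f, " pool smaller than the quantile group",
              call. = FALSE)
    groups[[paste0("best-", f)]] <-
      list(criterion = paste0("best-", f), framing = f, indices = idx,
           n = length(idx), modal_profile = modal(idx))
  }
  idx <- order(df$delta_effect)[seq_len(size)]
  groups[["indifferent"]] <-
    list(criterion = "indifferent", framing = "indifferent", indices = idx,
         n = length(idx), modal_profile = modal(idx))
  idx <- order(df$mean_effect)[seq_len(size)]
  groups[["oppositive"]] <-
    list(criterion = "oppositive", framing = "oppositive", indices = idx,
         n = length(idx), modal_profile = modal(idx))
  attr(groups, "q") <- q
  attr(groups, "size") <- size
  attr(groups, "dims") <- dims
  class(groups) <- "prototype_report"
  groups
}

#' @export
print.prototype_report <- function(x, ...) {
  cat("Receiver prototypes (", attr(x, "size"), " individuals per group, q = ",
      attr(x, "q"), ")\n", sep = "")
  for (g in x)
    cat(sprintf("  %-14s n=%4d  modal: %s\n", g$criterion, g$n,
                paste(names(g$modal_profile), g$modal_profile,
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Serialize a prototype report to JSON
#'
#' @param report A [extract_prototypes()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_prototypes <- function(report, path) {
  stopifnot(inherits(report, "prototype_report"))
  ser <- lapply(report, function(g)
    list(criterion = g$criterion, framing = g$framing, n = g$n,
         indices = g$indices, modal_profile = as.list(g$modal_profile)))
  jsonlite::write_json(list(q = attr(report, "q"), size = attr(report, "size"),
                            dims = attr(report, "dims"), groups = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the population effect profile as CSV
#'
#' One row per enumerated individual: Time-1 assignment, the four effects,
#' summaries, and the best framing.
#'
#' @param profile An `effect_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
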