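#' @importFrom stats setNames
NULL

.SLICES <- c(T1 = 1L, MESSAGE = 2L, T2 = 3L, OUTCOME = 4L)

#' Declare a network variable
#'
#' A variable in a time-sliced categorical network carries a slice tag
#' (`"T1"` antecedents, `"MESSAGE"` intervention, `"T2"` reactions,
#' `"OUTCOME"` target) and an ordered list of category labels.
#'
#' @param name Variable name (single string).
#' @param slice One of `"T1"`, `"MESSAGE"`, `"T2"`, `"OUTCOME"`.
#' @param categories Character vector of ordered category labels (>= 2).
#' @return A `bn_variable` list with elements `name`, `slice`, `categories`.
#' @export
bn_variable <- function(name, slice, categories) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  slice <- match.arg(slice, names(.SLICES))
  categories <- as.character(categories)
  if (length(categories) < 2L)
    stop("variable '", name, "' needs at least 2 categories", call. = FALSE)
  if (anyDuplicated(categories))
    stop("variable '", name, "' has duplicated category labels", call. = FALSE)
  if (slice == "MESSAGE" && length(categories) != 4L)
    stop("the MESSAGE variable must have exactly 4 categories (framings)",
         call. = FALSE)
  structure(list(name = name, slice = slice, categories = categories),
            class = "bn_variable")
}

#' Assemble a time-sliced network structure
#'
#' Builds and validates the directed acyclic graph over the declared
#' variables. Arcs must respect the orientation of time (parent slice <=
#' child slice), the MESSAGE node must be parentless (the framing is
#' randomized), and the OUTCOME node must have no children.
#'
#' @param variables List of [bn_variable()] specs.
#' @param arcs Two-column character matrix (or list of length-2 vectors)
#'   of `parent -> child` arcs; `NULL` for an edgeless network.
#' @return A `bn_structure` object: `variables` (named list), `arcs`
#'   (2-column matrix), `parents` (named list), `order` (declaration
#'   order), `topo` (a topological order).
#' @export
bn_structure <- function(variables, arcs = NULL) {
  if (inherits(variables, "bn_variable")) variables <- list(variables)
  stopifnot(is.list(variables), length(variables) >= 1L)
  variables <- lapply(variables, function(v) {
    if (!inherits(v, "bn_variable")) v <- do.call(bn_variable, v)
    v
  })
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicated variable names", call. = FALSE)
  names(variables) <- nms

  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0L)) {
    arcs <- matrix(character(), ncol = 2L,
                   dimnames = list(NULL, c("parent", "child")))
  } else {
    if (is.list(arcs)) arcs <- do.call(rbind, arcs)
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2L) stop("arcs must have two columns", call. = FALSE)
    colnames(arcs) <- c("parent", "child")
    storage.mode(arcs) <- "character"
  }

  unknown <- setdiff(unique(c(arcs)), nms)
  if (length(unknown))
    stop("arc references unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(arcs[, 1L] == arcs[, 2L]))
    stop("self-loop arc", call. = FALSE)
  key <- paste(arcs[, 1L], arcs[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicated arc", call. = FALSE)

  slices <- vapply(variables, `[[`, "", "slice")
  out <- structure(
    list(variables = variables,
         arcs = arcs,
         parents = .parent_map(nms, arcs),
         order = nms,
         topo = NULL),
    class = "bn_structure")

  ## slice orientation
  if (nrow(arcs)) {
    bad <- .SLICES[slices[arcs[, 1L]]] > .SLICES[slices[arcs[, 2L]]]
    if (any(bad))
      stop("arc(s) against the orientation of time: ",
           paste(arcs[bad, 1L], "->", arcs[bad, 2L], collapse = "; "),
           call. = FALSE)
  }
  msg <- nms[slices == "MESSAGE"]
  if (length(msg) > 1L) stop("more than one MESSAGE variable", call. = FALSE)
  if (length(msg) == 1L && length(out$parents[[msg]]))
    stop("the MESSAGE variable must have no parents (randomized assignment)",
         call. = FALSE)
  outc <- nms[slices == "OUTCOME"]
  if (length(outc) != 1L)
    stop("exactly one OUTCOME variable is required", call. = FALSE)
  if (nrow(arcs) && any(arcs[, 1L] == outc))
    stop("the OUTCOME variable must have no children", call. = FALSE)

  topo <- .topo_sort(nms, arcs)
  if (is.null(topo)) stop("arcs form a cycle", call. = FALSE)
  out$topo <- topo
  out
}

.parent_map <- function(nms, arcs) {
  pm <- setNames(vector("list", length(nms)), nms)
  for (v in nms) pm[[v]] <- character()
  if (nrow(arcs))
    for (i in seq_len(nrow(arcs)))
      pm[[arcs[i, 2L]]] <- c(pm[[arcs[i, 2L]]], arcs[i, 1L])
  pm
}

## Kahn's algorithm; NULL if cyclic
.topo_sort <- function(nms, arcs) {
  indeg <- setNames(integer(length(nms)), nms)
  if (nrow(arcs)) {
    tab <- table(arcs[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  queue <- nms[indeg == 0L]
  out <- character()
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    if (nrow(arcs)) {
      ch <- arcs[arcs[, 1L] == v, 2L]
      for (c0 in ch) {
        indeg[c0] <- indeg[c0] - 1L
        if (indeg[c0] == 0L) queue <- c(queue, c0)
      }
    }
  }
  if (length(out) != length(nms)) NULL else out
}

#' @export
print.bn_structure <- function(x, ...) {
  sl <- vapply(x$variables, `[[`, "", "slice")
  cat("Time-sliced categorical network:",
      length(x$variables), "variables,", nrow(x$arcs), "arcs\n")
  for (s in names(.SLICES)) {
    v <- names(x$variables)[sl == s]
    if (length(v)) cat(sprintf("  %-8s %s\n", s, paste(v, collapse = ", ")))
  }
  if (nrow(x$arcs))
    cat("Arcs:\n", paste("  ", x$arcs[, 1L], "->", x$arcs[, 2L],
                         collapse = "\n"), "\n", sep = "")
  invisible(x)
}

## ---- internal helpers ------------------------------------------------------

.vars_in_slice <- function(structure, slice) {
  sl <- vapply(structure$variables, `[[`, "", "slice")
  names(structure$variables)[sl %in% slice]
}

.outcome_var <- function(structure) .vars_in_slice(structure, "OUTCOME")

.message_var <- function(structure) {
  v <- .vars_in_slice(structure, "MESSAGE")
  if (length(v)) v else NULL
}

.cards <- function(structure)
  vapply(structure$variables, function(v) length(v$categories), 1L)

## data.frame of labels -> integer matrix (columns in structure order)
.encode_data <- function(structure, data) {
  nms <- structure$order
  miss <- setdiff(nms, names(data))
  if (length(miss))
    stop("data lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(data)
  m <- matrix(NA_integer_, nrow = n, ncol = length(nms),
              dimnames = list(NULL, nms))
  for (v in nms) {
    cats <- structure$variables[[v]]$categories
    col <- as.character(data[[v]])
    idx <- match(col, cats)
    if (anyNA(idx)) {
      bad <- unique(col[is.na(idx)])
      stop("variable '", v, "' has value(s) outside its category list: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    m[, v] <- idx
  }
  m
}

## mixed-radix configuration index over `vars` (1-based); 1 when no vars
.config_index <- function(m, vars, cards) {
  n <- if (is.matrix(m)) nrow(m) else length(m[[vars[1L]]])
  idx <- rep(1, n)
  mult <- 1
  for (v in vars) {
    col <- if (is.matrix(m)) m[, v] else m[[v]]
    idx <- idx + (col - 1) * mult
    mult <- mult * cards[[v]]
  }
  idx
}

## labels of parent configuration `conf` (1-based scalar) under mixed radix
.config_labels <- function(structure, vars, conf) {
  out <- character(length(vars))
  conf <- conf - 1L
  for (i in seq_along(vars)) {
    k <- length(structure$variables[[vars[i]]]$categories)
    out[i] <- structure$variables[[vars[i]]]$categories[(conf %% k) + 1L]
    conf <- conf %/% k
  }
  out
}

.config_keys <- function(structure, vars) {
  if (!length(vars)) return("")
  grids <- lapply(vars, function(v) structure$variables[[v]]$categories)
  g <- .expand_grid_msd_last(grids)   # first var varies fastest (mixed radix)
  do.call(paste, c(as.list(as.data.frame(g, stringsAsFactors = FALSE)),
                   sep = "|"))
}

## expand.grid with first list varying fastest, as data frame of labels
.expand_grid_msd_last <- function(lst) {
  g <- do.call(expand.grid,
               c(lst, list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  as.matrix(g)
}
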