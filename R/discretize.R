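.OUTCOME_LABELS <- c("high-negative", "low-negative", "neutral",
                     "low-positive", "high-positive")
.TERNARY_LABELS <- c("low", "medium", "high")

#' Fit quantile cut points for one variable
#'
#' Cut points are placed at empirical inverse-CDF quantiles: the k-th cut is
#' the smallest observed value whose empirical CDF strictly exceeds
#' `k / n_bins`. Together with the upper-bin assignment rule of
#' [apply_discretization()] (a value equal to a cut goes to the upper bin),
#' all-distinct samples of size divisible by `n_bins` split into exactly
#' balanced bins. Duplicate cuts, and cuts equal to the sample minimum
#' (which would leave a structurally empty lowest bin), are merged away;
#' the realized bin count is reported.
#'
#' @param values Numeric vector (non-empty).
#' @param n_bins Requested number of bins (>= 2; the study uses 3 for the
#'   antecedent scales and 5 for the intention-change target).
#' @return List with `cuts` (numeric), `requested_bins`, `realized_bins`.
#' @export
fit_quantile_cuts <- function(values, n_bins) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  if (!is.numeric(values))
    stop("values must be numeric; refitting on discretized labels is not ",
         "supported", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  sv <- sort(values)
  ux <- unique(sv)
  cdf <- cumsum(tabulate(match(sv, ux))) / length(sv)
  cuts <- vapply(seq_len(n_bins - 1L), function(k) {
    ux[which(cdf > k / n_bins + 1e-12)[1L]]
  }, 0)
  cuts <- unique(cuts[!is.na(cuts) & cuts > ux[1L]])
  list(cuts = cuts, requested_bins = as.integer(n_bins),
       realized_bins = length(cuts) + 1L)
}

#' Fit a discretization map for a cohort table
#'
#' Applies [fit_quantile_cuts()] per variable: 20% quantiles (5 bins,
#' labels `high-negative` ... `high-positive`) for the outcome variable and
#' 33% quantiles (3 bins, labels `low`/`medium`/`high`) for every other
#' variable. When ties collapse bins, the realized count is recorded and
#' labels are taken at evenly spaced positions of the canonical label list
#' (never padded).
#'
#' @param data Data frame with numeric columns.
#' @param vars Variables to map (default: all numeric columns).
#' @param outcome Name of the outcome variable (5 bins); `NULL` for none.
#' @return A `discretization_map`: per variable `cuts`, `labels`,
#'   `requested_bins`, `realized_bins`.
#' @export
fit_discretization <- function(data, vars = NULL, outcome = "delta_intention") {
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, TRUE)]
  bad <- vars[!vapply(data[vars], is.numeric, TRUE)]
  if (length(bad))
    stop("non-numeric column(s) (already discretized?): ",
         paste(bad, collapse = ", "), call. = FALSE)
  map <- setNames(vector("list", length(vars)), vars)
  for (v in vars) {
    nb <- if (!is.null(outcome) && v == outcome) 5L else 3L
    canonical <- if (nb == 5L) .OUTCOME_LABELS else .TERNARY_LABELS
    fq <- fit_quantile_cuts(data[[v]], nb)
    if (fq$realized_bins < nb)
      warning("variable '", v, "': ties collapse ", nb, " bins to ",
              fq$realized_bins, call. = FALSE)
    labs <- canonical[round(seq(1L, nb, length.out = fq$realized_bins))]
    map[[v]] <- list(cuts = fq$cuts, labels = labs,
                     requested_bins = fq$requested_bins,
                     realized_bins = fq$realized_bins)
  }
  class(map) <- "discretization_map"
  map
}

#' Apply a fitted discretization map
#'
#' Each value is replaced by the label of its bin; a value exactly equal to
#' a cut point is assigned to the upper bin, and values outside the fitted
#' range clamp to the outer bins. The mapping is monotone non-decreasing.
#'
#' @param data Data frame containing every mapped variable.
#' @param map A [fit_discretization()] result.
#' @return Data frame where mapped columns are ordered factors' labels
#'   (plain factors with levels in scale order); other columns pass through.
#' @export
apply_discretization <- function(data, map) {
  stopifnot(inherits(map, "discretization_map"))
  miss <- setdiff(names(map), names(data))
  if (length(miss))
    stop("data lacks mapped variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data
  for (v in names(map)) {
    e <- map[[v]]
    bin <- rep(1L, nrow(data))
    for (cut in e$cuts) bin <- bin + (data[[v]] >= cut)
    out[[v]] <- factor(e$labels[bin], levels = e$labels)
  }
  out
}

#' @export
print.discretization_map <- function(x, ...) {
  cat("Discretization map (", length(x), " variables)\n", sep = "")
  for (v in names(x))
    cat(sprintf("  %-28s cuts: %s -> %s\n", v,
                paste(signif(x[[v]]$cuts, 4L), collapse = ", "),
                paste(x[[v]]$labels, collapse = "/")))
  invisible(x)
}

#' Serialize / restore a discretization map (JSON)
#'
#' Round-trips bit-exactly so a fitted map can be re-applied to new cohorts.
#'
#' @param map A `discretization_map`.
#' @param path File path.
#' @return `write_discretization` returns `path` invisibly;
#'   `read_discretization` returns the map.
#' @export
write_discretization <- function(map, path) {
  stopifnot(inherits(map, "discretization_map"))
  ser <- lapply(unclass(map), function(e) {
    ## 17 significant digits round-trip IEEE doubles exactly
    e$cuts <- sprintf("%.17g", e$cuts)
    e
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_discretization
#' @export
read_discretization <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- lapply(raw, function(e)
    list(cuts = as.numeric(e$cuts), labels = as.character(e$labels),
         requested_bins = as.integer(e$requested_bins),
         realized_bins = as.integer(e$realized_bins)))
  class(map) <- "discretization_map"
  map
}
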