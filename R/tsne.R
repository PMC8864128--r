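#' Embed effect profiles in two dimensions with t-SNE
#'
#' Exact (non-approximate) t-distributed stochastic neighbour embedding of
#' the 4-dimensional effect vectors, preserving relative dissimilarities
#' as far as possible. The embedding is visualization only: conditional
#' input similarities are matched to the requested perplexity by binary
#' search, the map is optimized by momentum gradient descent with early
#' exaggeration, and a fixed seed gives an identical layout.
#'
#' @param x An [profile_population()] result or a numeric matrix (rows =
#'   individuals; >= 2 rows).
#' @param perplexity Effective neighbourhood size (default 30; reduced
#'   with a warning when the population is too small).
#' @param seed Integer seed for the random initial layout.
#' @param max_iter Gradient-descent iterations (default 500).
#' @param learning_rate Step size (default 200).
#' @return An `n x 2` matrix of coordinates.
#' @export
embed_population <- function(x, perplexity = 30, seed = 1L,
                             max_iter = 500L, learning_rate = 200) {
  X <- .effect_matrix(x)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 individuals", call. = FALSE)
  set.seed(seed)
  if (all(apply(X, 2L, function(col) diff(range(col)) == 0))) {
    warning("all effect vectors identical; jittering before embedding",
            call. = FALSE)
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-6), nrow = n)
  }
  if (3 * perplexity >= n) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning("perplexity too large for n; reduced to ", perplexity,
            call. = FALSE)
  }

  D2 <- as.matrix(stats::dist(X))^2
  P <- .perplexity_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), nrow = n)
  dY <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  exag_until <- min(100L, max_iter %/% 2L)
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= exag_until) P * 12 else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (rowSums(W) * Y - W %*% Y)
    momentum <- if (iter < 250L) 0.5 else 0.8
    gains <- pmax(0.01,
                  ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8))
    dY <- momentum * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  dimnames(Y) <- list(NULL, c("dim1", "dim2"))
  Y
}

## Row-wise conditional probabilities matched to a target perplexity by
## binary search over the Gaussian precision.
.perplexity_probs <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(50L)) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(d * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-d * beta)
    P[i, -i] <- w / sum(w)
  }
  P
}

#' Plot an effect-profile embedding
#'
#' Scatter of the 2-D embedding colored by one of the effect summaries
#' (`mean`, `best`, `delta`) on a cold-to-warm palette, or by the best
#' framing (one color per framing).
#'
#' @param x An `effect_profile`.
#' @param embedding Matrix from [embed_population()] (computed on the fly
#'   when omitted -- slow for large populations).
#' @param color One of `"mean"`, `"best"`, `"delta"`, `"framing"`.
#' @param ... Passed to [graphics::plot()].
#' @return The embedding, invisibly.
#' @export
plot.effect_profile <- function(x, embedding = NULL,
                                color = c("mean", "best", "delta", "framing"),
                                ...) {
  color <- match.arg(color)
  if (is.null(embedding)) embedding <- embed_population(x)
  if (color == "framing") {
    framings <- attr(x, "framings")
    pal <- grDevices::hcl.colors(length(framings), "Dark 3")
    col <- pal[as.integer(x$best_framing)]
    graphics::plot(embedding, col = col, pch = 16, cex = 0.5,
                   xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
    graphics::legend("topright", legend = framings, col = pal, pch = 16,
                     cex = 0.8, bty = "n")
  } else {
    v <- switch(color, mean = x$mean_effect, best = x$best_effect,
                delta = x$delta_effect)
    pal <- grDevices::hcl.colors(100L, "Blue-Red 3")
    idx <- cut(v, breaks = 100L, labels = FALSE, include.lowest = TRUE)
    graphics::plot(embedding, col = pal[idx], pch = 16, cex = 0.5,
                   xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = paste(color, "effect"), ...)
  }
  invisible(embedding)
}
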