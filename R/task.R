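#' Analog XOR ground truth
#'
#' An input pair is labelled `HIGH` when exactly one of the two inputs is
#' greater than or equal to the input boundary `b`, and `LOW` otherwise.
#' Ties follow the `>=` convention on both sides of the boundary.
#'
#' @param x0,x1 Input values in `[0, 1]` (vectorized).
#' @param b Input boundary in `[0, 1]`.
#' @return A factor with levels `LOW`, `HIGH`.
#' @examples
#' xor_label(c(0.2, 0.8, 0.8), c(0.8, 0.2, 0.8), b = 0.5)
#' @export
xor_label <- function(x0, x1, b) {
  stopifnot(length(x0) == length(x1), b >= 0, b <= 1)
  hi <- xor(x0 >= b, x1 >= b)
  factor(ifelse(hi, "HIGH", "LOW"), levels = c("LOW", "HIGH"))
}

#' Normalize an output surface
#'
#' Rescales the raw decision statistic (spike counts or ReLU activations)
#' over the input grid so that the output threshold `h` can be expressed in
#' `(0, 1)` regardless of the circuit's absolute firing level.  The default
#' divides by the grid maximum (raw values are non-negative); `"minmax"`
#' additionally subtracts the grid minimum.  An all-zero surface (a
#' degenerate, silent circuit) is returned as all zeros with a warning.
#'
#' @param raw Numeric vector of non-negative raw values.
#' @param method `"max"` or `"minmax"`.
#' @return Numeric vector in `[0, 1]` with maximum exactly 1 (unless the
#'   surface is degenerate).
#' @export
normalize_surface <- function(raw, method = c("max", "minmax")) {
  method <- match.arg(method)
  stopifnot(is.numeric(raw), length(raw) > 0)
  if (any(raw < 0)) stop("raw surface values must be non-negative")
  lo <- if (method == "minmax") min(raw) else 0
  span <- max(raw) - lo
  if (span == 0 && max(raw) == 0) {
    warning("all-zero output surface: circuit is silent")
    return(rep(0, length(raw)))
  }
  if (span == 0) return(rep(1, length(raw)))
  (raw - lo) / span
}

#' Analog XOR accuracy at one decision boundary
#'
#' Digitizes the normalized output against the firing threshold `h`
#' (`HIGH` iff value `>= h`) and the inputs against the boundary `b`, and
#' returns the fraction of grid points where the digitized output matches
#' the XOR ground truth.
#'
#' @param values Normalized output values, one per grid point.
#' @param x0,x1 Grid coordinates matching `values`.
#' @param b Input boundary in `[0, 1]`.
#' @param h Output firing threshold in `(0, 1)`.
#' @return Classification accuracy in `[0, 1]`.
#' @export
xor_accuracy <- function(values, x0, x1, b, h) {
  if (length(values) == 0L) stop("empty grid")
  stopifnot(length(x0) == length(values), length(x1) == length(values))
  pred <- values >= h
  truth <- xor(x0 >= b, x1 >= b)
  mean(pred == truth)
}

#' Accuracy over a grid of decision boundaries
#'
#' Evaluates [xor_accuracy()] for every combination of input boundary `b`
#' and output threshold `h`, vectorized via a match-count cross product.
#'
#' @param values Normalized output values, one per grid point.
#' @param x0,x1 Grid coordinates matching `values`.
#' @param b_grid,h_grid Candidate boundaries and thresholds.
#' @return A `length(b_grid) x length(h_grid)` matrix of accuracies with
#'   dimnames giving the candidate values.
#' @export
accuracy_grid <- function(values, x0, x1, b_grid, h_grid) {
  if (length(values) == 0L) stop("empty grid")
  stopifnot(length(x0) == length(values), length(x1) == length(values),
            length(b_grid) > 0, length(h_grid) > 0)
  n <- length(values)
  # truth: n x nb, prediction: n x nh, both as 0/1
  L <- outer(x0, b_grid, `>=`) != outer(x1, b_grid, `>=`)
  P <- outer(values, h_grid, `>=`)
  storage.mode(L) <- "double"
  storage.mode(P) <- "double"
  acc <- (crossprod(L, P) + crossprod(1 - L, 1 - P)) / n
  dimnames(acc) <- list(b = format(b_grid), h = format(h_grid))
  acc
}

#' Fit the decision boundary of an XOR surface
#'
#' Exhaustive grid search for the decision boundary `(b, h)` maximizing
#' analog XOR accuracy on a simulated (or analytic) output surface.  Ties
#' are broken toward the smallest `(b, h)` lexicographically.  This is the
#' package's "model fit": the surface is the data, the boundary is the
#' two-parameter decision rule.
#'
#' @param surface An [simulate_surface()] result (`"xor_surface"`), or a
#'   data frame with columns `x0`, `x1` and `norm`.
#' @param b Candidate input boundaries.
#' @param h Candidate output thresholds (in `(0, 1)`).
#' @return An object of class `"xor_fit"` with components `b`, `h`,
#'   `accuracy`, the full accuracy `grid`, and the surface.
#' @examples
#' g <- xor_grid(21)
#' surf <- data.frame(g, norm = abs(g$x0 - g$x1))
#' fit <- fit_boundary(surf)
#' coef(fit)
#' @export
fit_boundary <- function(surface, b = seq(0.02, 0.98, by = 0.02),
                         h = seq(0.02, 0.98, by = 0.02)) {
  df <- as_surface_df(surface)
  acc <- accuracy_grid(df$norm, df$x0, df$x1, b, h)
  best <- max(acc)
  hits <- which(acc >= best - 1e-12, arr.ind = TRUE)
  hits <- hits[order(b[hits[, 1]], h[hits[, 2]]), , drop = FALSE]
  structure(list(b = b[hits[1, 1]], h = h[hits[1, 2]], accuracy = best,
                 grid = acc, b_grid = b, h_grid = h, surface = df),
            class = "xor_fit")
}

as_surface_df <- function(surface) {
  if (inherits(surface, "xor_surface")) {
    df <- surface
    class(df) <- "data.frame"
    return(df)
  }
  df <- as.data.frame(surface)
  if (!all(c("x0", "x1", "norm") %in% names(df)))
    stop("surface must provide columns x0, x1 and norm")
  df
}

#' @export
print.xor_fit <- function(x, ...) {
  cat("Analog XOR decision boundary fit\n")
  cat(sprintf("  best boundary: (b, h) = (%.2f, %.2f)\n", x$b, x$h))
  cat(sprintf("  accuracy: %.2f%% over %d grid points\n",
              100 * x$accuracy, nrow(x$surface)))
  invisible(x)
}

#' @export
coef.xor_fit <- function(object, ...) c(b = object$b, h = object$h)

#' @export
summary.xor_fit <- function(object, tol = 0.01, ...) {
  near <- which(object$grid >= object$accuracy - tol, arr.ind = TRUE)
  out <- list(fit = object, tol = tol, n_near = nrow(near),
              near = data.frame(b = object$b_grid[near[, 1]],
                                h = object$h_grid[near[, 2]],
                                accuracy = object$grid[near]))
  class(out) <- "summary.xor_fit"
  out
}

#' @export
print.summary.xor_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d boundaries within %.1f%% of the maximum\n",
              x$n_near, 100 * x$tol))
  invisible(x)
}

#' @export
predict.xor_fit <- function(object, newdata = NULL, ...) {
  values <- if (is.null(newdata)) object$surface$norm
            else if (is.numeric(newdata)) newdata
            else newdata$norm
  factor(ifelse(values >= object$h, "HIGH", "LOW"),
         levels = c("LOW", "HIGH"))
}

#' @export
plot.xor_fit <- function(x, ...) {
  image(x$b_grid, x$h_grid, x$grid, xlab = "input boundary b",
        ylab = "output threshold h", main = "XOR accuracy", ...)
  points(x$b, x$h, pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}
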