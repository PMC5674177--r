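#' Principal component ordination of tangent shape coordinates
#'
#' Eigen-decomposes the covariance of the tangent coordinates about their
#' grand mean (covariance, not correlation: tangent coordinates share one
#' unit, and rescaling them would distort the shape geometry). Scores are
#' centered; over the full set of axes the score geometry is an isometry of
#' the tangent coordinates, so pairwise Euclidean distances are preserved.
#' Each axis is oriented so that its largest-magnitude loading is positive,
#' which makes plots reproducible across platforms.
#'
#' @param x a [gpa()] fit or a numeric n x p matrix of tangent coordinates
#'   (>= 3 specimens).
#' @return An object of class `shape_pca`: `axes` (p x m, orthonormal
#'   columns), `variance_pct` (non-increasing, sums to 100), `scores`
#'   (n x m), `center`, `sdev`, and the specimens' group labels if the
#'   `gpa` fit carried a label table.
#' @seealso [project_unknown()], [plot.shape_pca()]
#' @export
shape_pca <- function(x) {
  labels <- NULL; ids <- NULL
  if (inherits(x, "gpa")) {
    labels <- x$labels; ids <- x$specimen_ids
    X <- x$tangent
  } else if (is.matrix(x) && is.numeric(x)) {
    X <- x; ids <- rownames(X)
  } else stop("'x' must be a gpa fit or a numeric matrix")
  if (nrow(X) < 3L) stop("ordination needs at least 3 specimens")
  if (!all(is.finite(X))) stop("non-finite tangent coordinates")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) stop("zero total variance: all shapes identical")
  ## orient each axis so its largest-magnitude loading is positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- ids
  structure(
    list(axes = pc$rotation,
         variance_pct = 100 * ev / sum(ev),
         scores = pc$x,
         center = pc$center, sdev = pc$sdev,
         specimen_ids = ids, labels = labels),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(5L, length(x$variance_pct))
  cat("Principal component ordination of shape coordinates\n")
  cat("  ", nrow(x$scores), " specimens, ", ncol(x$scores), " axes\n",
      sep = "")
  cat("  variance explained (%):",
      paste(sprintf("PC%d %.2f", seq_len(m), x$variance_pct[seq_len(m)]),
            collapse = ", "),
      if (length(x$variance_pct) > m) "...", "\n")
  invisible(x)
}

#' Project an unknown specimen into a fitted ordination
#'
#' Places a new tangent vector into an existing principal component space
#' without refitting: `score = t(axes) %*% (x - grand mean)`. This is how a
#' fossil is ordinated among the reference specimens.
#'
#' @param result a `shape_pca` fit.
#' @param x tangent vector of length p (or n x p matrix), in the same basis
#'   as the training coordinates; alternatively a `landmark_config` plus a
#'   `reference` [gpa()] fit to produce the tangent vector.
#' @param reference optional `gpa` fit used to tangent-project a raw
#'   configuration.
#' @return numeric score vector (or matrix) on the ordination axes.
#' @export
project_unknown <- function(result, x, reference = NULL) {
  stopifnot(inherits(result, "shape_pca"))
  if (inherits(x, "landmark_config")) {
    if (is.null(reference))
      stop("projecting a raw configuration needs a 'reference' gpa fit")
    x <- align_to_consensus(reference, x)$tangent
  }
  X <- rbind(x)
  if (ncol(X) != length(result$center))
    stop("tangent vector length (", ncol(X),
         ") does not match the ordination basis (",
         length(result$center), ")")
  S <- sweep(X, 2L, result$center) %*% result$axes
  if (nrow(S) == 1L) S[1L, ] else S
}

#' @export
predict.shape_pca <- function(object, newdata, reference = NULL, ...)
  project_unknown(object, newdata, reference)

#' Ordination scatter plot
#'
#' Scatter of the reference specimens on two principal component axes,
#' colored by group, with an optional unknown specimen marked.
#'
#' @param x a `shape_pca` fit.
#' @param axes length-2 integer vector: which components to plot.
#' @param groups optional factor/character vector of group labels (defaults
#'   to the stored label table's level given by `level`).
#' @param level label level used for coloring when the fit carries labels.
#' @param unknown optional score vector from [project_unknown()].
#' @param ... passed to [graphics::plot()].
#' @return the fit, invisibly.
#' @export
plot.shape_pca <- function(x, axes = c(1L, 2L), groups = NULL,
                           level = NULL, unknown = NULL, ...) {
  s <- x$scores[, axes, drop = FALSE]
  if (is.null(groups) && !is.null(x$labels) && !is.null(level))
    groups <- labels_lookup(x$labels, x$specimen_ids, level)
  col <- "grey30"; pch <- 16
  if (!is.null(groups)) {
    g <- factor(groups)
    pal <- grDevices::hcl.colors(max(3L, nlevels(g)), "Dark 3")
    col <- pal[as.integer(g)]
  }
  lab <- sprintf("PC%d (%.2f%%)", axes, x$variance_pct[axes])
  graphics::plot(s, col = col, pch = pch, asp = 1,
                 xlab = lab[1L], ylab = lab[2L], ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = pal[seq_len(nlevels(factor(groups)))],
                     pch = 16, cex = 0.7, bty = "n")
  if (!is.null(unknown))
    graphics::points(unknown[axes[1L]], unknown[axes[2L]],
                     pch = 8, cex = 1.6, lwd = 2, col = "black")
  invisible(x)
}
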