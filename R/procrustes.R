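#' Center and scale a configuration to its preshape
#'
#' Translates the landmarks so their centroid is at the origin and scales
#' them to unit centroid size. The preshape retains only shape and
#' orientation; translation and size are removed.
#'
#' @param x a `landmark_config` or a numeric k x 2 matrix.
#' @return list with `coords` (the unit-size centered k x 2 matrix) and
#'   `centroid_size` (the original size).
#' @export
#' @examples
#' p <- preshape(cbind(c(0, 2, 0), c(0, 0, 2)))
#' p$centroid_size      # sqrt(16/3)
preshape <- function(x) {
  m <- config_coords(x)
  ctr <- colMeans(m)
  m <- sweep(m, 2L, ctr)
  cs <- sqrt(sum(m^2))
  if (cs < .Machine$double.eps * nrow(m))
    stop("degenerate shape: all landmarks coincide (zero centroid size)",
         if (inherits(x, "landmark_config")) paste0(" in '", x$specimen_id, "'"))
  list(coords = m / cs, centroid_size = cs)
}

#' Optimal rotation of one preshape onto another
#'
#' Returns the proper rotation (2 x 2, determinant +1) minimizing the summed
#' squared landmark distances between `A %*% R` and `B`. Reflections are
#' deliberately excluded: left and right wings are reflections of each
#' other, and silently absorbing a reflection would mask digitization on the
#' wrong wing side (use [mirror_config()] explicitly instead).
#'
#' When the cross-covariance between the two shapes is rank deficient the
#' optimum is not unique; the rotation from the SVD with non-negative
#' singular values is returned, which is deterministic.
#'
#' @param A,B k x 2 matrices (normally preshapes) with equal k.
#' @return 2 x 2 rotation matrix `R` such that `A %*% R` best matches `B`.
#' @export
optimal_rotation <- function(A, B) {
  A <- config_coords(A); B <- config_coords(B)
  if (nrow(A) != nrow(B))
    stop("configurations have different landmark counts: ",
         nrow(A), " vs ", nrow(B))
  M <- crossprod(A, B)              # 2 x 2 cross-covariance
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1                # fully degenerate: SVD convention
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Partial Procrustes distance between two shapes
#'
#' Both configurations are reduced to preshapes and one is optimally rotated
#' onto the other; the distance is the Euclidean (Frobenius) norm of the
#' remaining coordinate difference. It is symmetric, zero exactly when the
#' shapes differ only by translation, scale, and proper rotation, and
#' strictly positive for a shape and its mirror image (unless the shape is
#' symmetric).
#'
#' @param a,b `landmark_config` objects or k x 2 matrices with equal k.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  pa <- preshape(a); pb <- preshape(b)
  R <- optimal_rotation(pa$coords, pb$coords)
  sqrt(sum((pa$coords %*% R - pb$coords)^2))
}

#' Generalized Procrustes superimposition
#'
#' Iterative generalized least-squares superimposition of a sample of
#' landmark configurations: every configuration is centered and scaled to
#' unit centroid size, rotated onto a provisional consensus, and the
#' consensus is re-estimated as the mean of the rotated configurations
#' (rescaled to unit size) until it stops moving. Translation, size, and
#' rotation are thereby removed; reflection is not (see
#' [optimal_rotation()]).
#'
#' After convergence the whole aligned sample is rotated so that the
#' consensus's first-to-second landmark axis points along +x, which makes
#' the output orientation reproducible across runs, input orderings, and
#' arbitrary similarity transforms of the input.
#'
#' Tangent-space coordinates are computed at the consensus: each aligned
#' configuration, flattened to a 2k-vector (x1, y1, ..., xk, yk), has its
#' component along the (unit-norm) consensus vector removed, which maps the
#' consensus itself to zero and linearizes the curved shape space locally.
#'
#' @param x a [shape_dataset()] or a k x 2 x n coordinate array.
#' @param tol convergence threshold on the consensus movement (root summed
#'   squared coordinate change) between iterations.
#' @param max_iter iteration cap; if reached, the result is returned with
#'   `converged = FALSE` and a warning.
#' @return An object of class `gpa` with components `aligned` (k x 2 x n
#'   array), `consensus` (k x 2, unit centroid size), `centroid_sizes`,
#'   `tangent` (n x 2k matrix), `specimen_ids`, `iterations`, `converged`,
#'   and, when `x` was a dataset, its `labels` and `scheme_name`.
#' @export
#' @examples
#' spec <- synthetic_spec(hierarchy = c(group = 2), n_per_group = 5)
#' fit <- gpa(generate_dataset(spec))
#' fit
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  labels <- NULL; scheme <- NULL
  if (inherits(x, "shape_dataset")) {
    labels <- x$labels; scheme <- x$scheme_name
    arr <- coords_array(x)
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[2L] == 2L) {
    arr <- x
  } else stop("'x' must be a shape_dataset or a k x 2 x n array")
  n <- dim(arr)[3L]
  k <- dim(arr)[1L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- paste0("specimen_", seq_len(n))

  pre <- array(NA_real_, c(k, 2L, n))
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    p <- tryCatch(preshape(arr[, , i]), error = function(e)
      stop("specimen '", ids[i], "': ", conditionMessage(e), call. = FALSE))
    pre[, , i] <- p$coords
    sizes[i] <- p$centroid_size
  }

  consensus <- pre[, , 1L]
  aligned <- pre
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      aligned[, , i] <- pre[, , i] %*% optimal_rotation(pre[, , i], consensus)
    new_cons <- apply(aligned, c(1L, 2L), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    move <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (move < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  ## final pass against the converged consensus
  for (i in seq_len(n))
    aligned[, , i] <- pre[, , i] %*% optimal_rotation(pre[, , i], consensus)

  ## orientation tie-break: consensus landmark 1 -> 2 axis along +x
  v <- consensus[2L, ] - consensus[1L, ]
  theta <- atan2(v[2L], v[1L])
  Rfix <- rbind(c(cos(-theta), sin(-theta)),
                c(-sin(-theta), cos(-theta)))
  consensus <- consensus %*% Rfix
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% Rfix

  dimnames(aligned) <- list(NULL, c("x", "y"), ids)
  tangent <- tangent_coords_internal(aligned, consensus)
  structure(
    list(aligned = aligned, consensus = consensus,
         centroid_sizes = stats::setNames(sizes, ids),
         tangent = tangent, specimen_ids = ids,
         k = k, n = n, iterations = it, converged = converged,
         labels = labels, scheme_name = scheme,
         tol = tol),
    class = "gpa")
}

## flatten k x 2 to (x1, y1, ..., xk, yk)
flatten_config <- function(m) as.vector(t(m))

tangent_coords_internal <- function(aligned, consensus) {
  n <- dim(aligned)[3L]
  cvec <- flatten_config(consensus)          # unit norm
  X <- t(apply(aligned, 3L, flatten_config))
  if (n == 1L) X <- matrix(X, 1L)
  tang <- X - tcrossprod(X %*% cvec, cvec)   # remove consensus component
  dimnames(tang) <- list(dimnames(aligned)[[3L]],
                         paste0(rep(c("x", "y"), dim(aligned)[1L]),
                                rep(seq_len(dim(aligned)[1L]), each = 2L)))
  tang
}

#' Tangent-space coordinates of an aligned sample
#'
#' Projects each aligned configuration onto the linear space tangent to the
#' shape space at the consensus (component along the unit consensus vector
#' removed). The consensus maps to the zero vector; for small shape
#' variation, Euclidean distances between tangent vectors approximate
#' Procrustes distances.
#'
#' @param aligned a `gpa` fit.
#' @return n x 2k numeric matrix (columns x1, y1, ..., xk, yk).
#' @export
tangent_project <- function(aligned) {
  stopifnot(inherits(aligned, "gpa"))
  aligned$tangent
}

#' Project a single new configuration into a fitted GPA's tangent space
#'
#' The reference alignment is left untouched: the newcomer is preshaped,
#' optimally rotated onto the fixed consensus, and tangent-projected. This
#' is the "a posteriori" placement used for unknowns such as fossils.
#'
#' @param fit a `gpa` fit.
#' @param config a `landmark_config` with the fit's landmark count.
#' @return list with `tangent` (length-2k vector), `aligned` (k x 2), and
#'   `centroid_size`.
#' @export
align_to_consensus <- function(fit, config) {
  stopifnot(inherits(fit, "gpa"))
  m <- config_coords(config)
  if (nrow(m) != fit$k)
    stop("landmark scheme mismatch: configuration has ", nrow(m),
         " landmarks, reference has ", fit$k)
  p <- preshape(m)
  al <- p$coords %*% optimal_rotation(p$coords, fit$consensus)
  cvec <- flatten_config(fit$consensus)
  xv <- flatten_config(al)
  list(tangent = xv - sum(xv * cvec) * cvec,
       aligned = al, centroid_size = p$centroid_size)
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes superimposition\n")
  cat("  ", x$n, " configurations of ", x$k, " landmarks\n", sep = "")
  cat("  converged:", x$converged, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  d <- apply(object$aligned, 3L, function(m)
    sqrt(sum((m - object$consensus)^2)))
  cat("Generalized Procrustes superimposition\n")
  cat("  ", object$n, " configurations of ", object$k, " landmarks; ",
      "converged: ", object$converged, " (", object$iterations,
      " iterations)\n", sep = "")
  cat("  centroid size: ", sep = "")
  print(summary(unname(object$centroid_sizes)))
  cat("  root squared distance to consensus: ", sep = "")
  print(summary(unname(d)))
  invisible(object)
}

#' @export
#' @importFrom graphics plot points
plot.gpa <- function(x, links = NULL, ...) {
  rng <- range(x$aligned)
  graphics::plot(NA, xlim = rng, ylim = rng, asp = 1,
                 xlab = "x", ylab = "y",
                 main = "Procrustes-aligned configurations", ...)
  for (i in seq_len(x$n))
    graphics::points(x$aligned[, , i], pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("grey40", 0.5))
  graphics::points(x$consensus, pch = 21, bg = "tomato", cex = 1.1)
  invisible(x)
}

#' @export
as.data.frame.gpa <- function(x, row.names = NULL, optional = FALSE, ...) {
  flat <- t(apply(x$aligned, 3L, flatten_config))
  colnames(flat) <- colnames(x$tangent)
  data.frame(specimen_id = x$specimen_ids, flat, check.names = FALSE)
}

#' Tangent-space adequacy check
#'
#' Statistical analysis in the tangent space is justified only when the
#' tangent plane approximates the curved shape space well over the observed
#' variation. The standard check regresses, over all specimen pairs, the
#' Euclidean distances between tangent vectors on the Procrustes distances
#' in shape space: a through-origin least-squares slope and a product-moment
#' correlation both near 1 indicate adequacy.
#'
#' @param x a [shape_dataset()], coordinate array, or `gpa` fit (>= 3
#'   specimens).
#' @param ... passed to [gpa()] when `x` is not already aligned.
#' @return An object of class `tangent_check`: list with `slope`,
#'   `correlation`, and `n_pairs`.
#' @export
tangent_adequacy <- function(x, ...) {
  fit <- if (inherits(x, "gpa")) x else gpa(x, ...)
  if (fit$n < 3L) stop("adequacy check needs at least 3 specimens")
  pre <- lapply(seq_len(fit$n), function(i) fit$aligned[, , i])
  pairs <- utils::combn(fit$n, 2L)
  pd <- numeric(ncol(pairs)); td <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    pd[j] <- procrustes_distance(pre[[a]], pre[[b]])
    td[j] <- sqrt(sum((fit$tangent[a, ] - fit$tangent[b, ])^2))
  }
  if (all(pd < .Machine$double.eps * fit$k))
    stop("all shapes are identical: pairwise distances are zero, ",
         "slope and correlation are undefined")
  structure(list(slope = sum(td * pd) / sum(pd^2),
                 correlation = stats::cor(td, pd),
                 n_pairs = ncol(pairs)),
            class = "tangent_check")
}

#' @export
print.tangent_check <- function(x, ...) {
  cat("Tangent-space adequacy (", x$n_pairs, " specimen pairs)\n", sep = "")
  cat("  regression slope (through origin):", format(x$slope, digits = 6), "\n")
  cat("  correlation:", format(x$correlation, digits = 6), "\n")
  cat("  values near 1 justify linear statistics in the tangent space\n")
  invisible(x)
}
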