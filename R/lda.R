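#' Linear discriminant analysis of tangent-space shape coordinates
#'
#' Fits the Gaussian equal-covariance (linear) discriminant model used to
#' classify wing shapes: group-specific mean tangent vectors with one pooled
#' within-group covariance. Because Procrustes superimposition leaves at
#' least four exactly null directions in the tangent coordinates
#' (translation x2, rotation, scale), the coordinates are first reduced to
#' the principal directions of total variance with relative variance above
#' `var_tol`; the reduction map is stored so unknowns can be projected into
#' the same space. Canonical (discriminant) axes maximizing between- over
#' within-group variance are computed from the generalized eigenproblem in
#' the reduced basis; at most G - 1 axes exist for G groups.
#'
#' @param x a [gpa()] fit (tangent coordinates and labels are taken from
#'   it), or a numeric n x p matrix of tangent coordinates.
#' @param grouping when `x` is a `gpa` fit carrying labels: the name of the
#'   taxonomic level to use as a-priori groups (e.g. `"tribe"`); otherwise a
#'   factor/character vector of group memberships of length n.
#' @param priors `"equal"` (default) or `"proportional"` to group sizes.
#'   Equal priors are the default because reference collections are
#'   availability samples of taxa: proportional priors would pull unknowns
#'   toward well-sampled groups.
#' @param shrinkage ridge-style shrinkage weight in \[0, 1\] pulling the
#'   pooled covariance toward its diagonal; 0 (default) is plain LDA.
#' @param var_tol relative-variance cutoff for the preliminary principal
#'   component reduction.
#' @return An object of class `shape_lda`: group means, pooled covariance
#'   (Cholesky factor) in the reduced basis, the reduction map, canonical
#'   axes, priors, group sizes, and (when fitted from a `gpa`) the reference
#'   alignment needed to score raw configurations.
#' @seealso [predict.shape_lda()], [assign_unknown()], [loo_cv()],
#'   [hierarchical_assign()]
#' @export
#' @examples
#' spec <- synthetic_spec(hierarchy = c(tribe = 3), n_per_group = 10)
#' fit <- gpa(generate_dataset(spec))
#' model <- shape_lda(fit, "tribe")
#' model
shape_lda <- function(x, grouping, priors = c("equal", "proportional"),
                      shrinkage = 0, var_tol = 1e-12) {
  priors <- match.arg(priors)
  reference <- NULL
  level <- NULL
  if (inherits(x, "gpa")) {
    reference <- x
    X <- x$tangent
    if (is.character(grouping) && length(grouping) == 1L) {
      level <- grouping
      grouping <- labels_lookup(x$labels, x$specimen_ids, level,
                                require_complete = TRUE)
    }
  } else if (is.matrix(x) && is.numeric(x)) {
    X <- x
  } else stop("'x' must be a gpa fit or a numeric matrix")
  if (!all(is.finite(X))) stop("non-finite tangent coordinates")
  g <- factor(grouping)
  if (length(g) != nrow(X))
    stop("grouping length (", length(g), ") != number of specimens (",
         nrow(X), ")")
  counts <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups, got ", nlevels(g))
  if (any(counts < 2L))
    stop("every group needs n >= 2; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  if (shrinkage < 0 || shrinkage > 1) stop("'shrinkage' must be in [0, 1]")

  n <- nrow(X); G <- nlevels(g)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  sv <- svd(Xc, nu = 0L)
  ev <- sv$d^2 / max(1L, n - 1L)
  keep <- ev / sum(ev) > var_tol
  if (!any(keep)) stop("tangent coordinates have zero total variance")
  V <- sv$v[, keep, drop = FALSE]           # reduction map p x d
  Z <- Xc %*% V                              # reduced scores n x d
  d <- ncol(Z)

  means <- rowsum(Z, g) / as.vector(counts)  # G x d, rows in level order
  Sw <- matrix(0, d, d)
  for (lev in levels(g)) {
    Zi <- Z[g == lev, , drop = FALSE]
    Zi <- sweep(Zi, 2L, means[lev, ])
    Sw <- Sw + crossprod(Zi)
  }
  Sw <- Sw / (n - G)
  if (shrinkage > 0)
    Sw <- (1 - shrinkage) * Sw + shrinkage * diag(diag(Sw), d)
  C <- tryCatch(chol(Sw), error = function(e)
    stop("pooled within-group covariance is singular in the reduced basis ",
         "(too few specimens per dimension, or zero within-group ",
         "variation); consider the 'shrinkage' argument", call. = FALSE))

  ## canonical axes: whiten by chol(Sw), eigendecompose between-group part
  prior_vec <- if (priors == "equal") rep(1 / G, G)
               else as.vector(counts) / n
  names(prior_vec) <- levels(g)
  grand <- colSums(means * as.vector(counts)) / n
  Mc <- sweep(means, 2L, grand)
  Sb <- crossprod(Mc * sqrt(as.vector(counts))) / (n - G)
  Cinv <- backsolve(C, diag(d))
  Mw <- t(Cinv) %*% Sb %*% Cinv
  eg <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
  n_axes <- min(G - 1L, sum(eg$values > max(eg$values[1L], 0) * 1e-10))
  axes <- Cinv %*% eg$vectors[, seq_len(max(n_axes, 1L)), drop = FALSE]
  axes <- axes[, seq_len(n_axes), drop = FALSE]
  colnames(axes) <- if (n_axes) paste0("LD", seq_len(n_axes))

  structure(
    list(groups = levels(g), group_means = means,
         chol_pooled = C, pooled_cov = Sw,
         axes = axes, canonical_values = eg$values[seq_len(max(n_axes, 0L))],
         priors = prior_vec, priors_mode = priors,
         n_per_group = stats::setNames(as.vector(counts), levels(g)),
         center = center, rotation = V,
         grouping_level = level, shrinkage = shrinkage,
         n = n, dim_reduced = d, reference = reference,
         grouping = g),
    class = "shape_lda")
}

#' @export
print.shape_lda <- function(x, ...) {
  cat("Linear discriminant model of tangent shape coordinates\n")
  if (!is.null(x$grouping_level))
    cat("  grouping level:", x$grouping_level, "\n")
  cat("  ", length(x$groups), " groups, ", x$n, " specimens, ",
      x$dim_reduced, " reduced dimensions, ",
      ncol(x$axes), " canonical axes\n", sep = "")
  cat("  priors:", x$priors_mode, "\n")
  invisible(x)
}

#' @export
summary.shape_lda <- function(object, ...) {
  print(object)
  cat("  group sizes:\n")
  print(object$n_per_group)
  if (length(object$canonical_values)) {
    pct <- 100 * object$canonical_values / sum(object$canonical_values)
    cat("  canonical axis variance (%):",
        paste(sprintf("%.1f", pct), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.shape_lda <- function(object, ...) object$axes

## map a raw tangent vector (or matrix) into the model's reduced basis
reduce_tangent <- function(model, x) {
  x <- rbind(x)
  if (ncol(x) != length(model$center))
    stop("tangent vector length (", ncol(x),
         ") does not match the model's basis (", length(model$center), ")")
  if (!all(is.finite(x))) stop("non-finite tangent coordinates")
  sweep(x, 2L, model$center) %*% model$rotation
}

#' Mahalanobis distances from a specimen to every group mean
#'
#' Computes, in the model's reduced basis, the pooled-covariance Mahalanobis
#' distance \eqn{MD_g = \sqrt{(x-\mu_g)^\top \Sigma^{-1} (x-\mu_g)}} from a
#' tangent vector to each group mean. With equal priors, the group at
#' minimal Mahalanobis distance is also the group of maximal posterior
#' probability.
#'
#' @param model a `shape_lda` fit.
#' @param x numeric tangent vector of length 2k (or an n x 2k matrix).
#' @return named vector (or matrix) of non-negative distances, one per group.
#' @export
mahalanobis_to_groups <- function(model, x) {
  stopifnot(inherits(model, "shape_lda"))
  Z <- reduce_tangent(model, x)
  out <- matrix(NA_real_, nrow(Z), length(model$groups),
                dimnames = list(rownames(Z), model$groups))
  for (j in seq_along(model$groups)) {
    D <- sweep(Z, 2L, model$group_means[j, ])
    U <- backsolve(model$chol_pooled, t(D), transpose = TRUE)
    out[, j] <- sqrt(colSums(U^2))
  }
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Posterior group-membership probabilities
#'
#' Under the equal-covariance Gaussian model, the score of group g for a
#' specimen with reduced coordinates x is
#' \eqn{-\tfrac12 MD_g^2 + \log \pi_g}; posteriors are the softmax of the
#' scores and sum to 1. The specimen is assigned to the group with the
#' highest posterior.
#'
#' @inheritParams mahalanobis_to_groups
#' @return named probability vector (or matrix) summing to 1 per specimen.
#' @export
posterior_probabilities <- function(model, x) {
  md <- rbind(mahalanobis_to_groups(model, x))
  scores <- sweep(-0.5 * md^2, 2L, log(model$priors), `+`)
  m <- apply(scores, 1L, max)
  p <- exp(scores - m)
  p <- p / rowSums(p)
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Assign an unknown specimen to a group a posteriori
#'
#' The unknown configuration is preshaped, optimally rotated onto the fixed
#' reference consensus (the reference alignment is not recomputed),
#' projected into the tangent space at that consensus, mapped through the
#' model's dimension reduction, and scored: posterior probabilities and
#' Mahalanobis distances to every group mean are reported, and the specimen
#' is assigned to the group with the highest posterior. Exact posterior ties
#' are broken toward the alphabetically first tied group, with a warning.
#'
#' @param model a `shape_lda` fit.
#' @param unknown a `landmark_config` with the reference's landmark count.
#' @param reference the [gpa()] fit the model was trained on; defaults to
#'   the alignment stored in the model.
#' @param mirror logical: mirror the unknown (see [mirror_config()]) before
#'   alignment, e.g. when the reference wings are left wings and the unknown
#'   preserves a right wing.
#' @return An object of class `assignment`: named `posterior` and
#'   `mahalanobis` vectors, `assigned_group`, and `level`.
#' @export
assign_unknown <- function(model, unknown, reference = model$reference,
                           mirror = FALSE) {
  stopifnot(inherits(model, "shape_lda"))
  if (is.null(reference))
    stop("no reference alignment: fit the model from a gpa() object or ",
         "pass 'reference'")
  if (!inherits(unknown, "landmark_config"))
    unknown <- landmark_config(unknown)
  if (mirror) unknown <- mirror_config(unknown)
  proj <- align_to_consensus(reference, unknown)
  tangent_assignment(model, proj$tangent, unknown$specimen_id)
}

tangent_assignment <- function(model, tvec, id = "unknown") {
  post <- posterior_probabilities(model, tvec)
  md <- mahalanobis_to_groups(model, tvec)
  mx <- max(post)
  tied <- which(post == mx)
  if (length(tied) > 1L)
    warning("exact posterior tie between groups ",
            paste(names(post)[tied], collapse = ", "),
            "; assigning to the alphabetically first")
  win <- names(post)[min(tied)]          # groups are stored sorted
  structure(list(specimen_id = id, posterior = post, mahalanobis = md,
                 assigned_group = win, level = model$grouping_level),
            class = "assignment")
}

#' @export
print.assignment <- function(x, digits = 4, ...) {
  cat("A posteriori assignment of '", x$specimen_id, "'",
      if (!is.null(x$level)) paste0(" at level '", x$level, "'"),
      "\n", sep = "")
  ord <- order(-x$posterior)
  df <- data.frame(group = names(x$posterior)[ord],
                   posterior = round(unname(x$posterior[ord]), digits),
                   MD = round(unname(x$mahalanobis[ord]), digits))
  print(df, row.names = FALSE)
  cat("assigned to:", x$assigned_group, "\n")
  invisible(x)
}

#' Predict group membership for new shapes
#'
#' @param object a `shape_lda` fit.
#' @param newdata a `landmark_config`, a [shape_dataset()], or a matrix of
#'   tangent coordinates in the model's basis.
#' @param type `"assignment"` (full [assign_unknown()]-style result),
#'   `"posterior"`, `"mahalanobis"`, or `"class"`.
#' @param reference,mirror passed to [assign_unknown()] for raw
#'   configurations.
#' @param ... ignored.
#' @return depends on `type`; for several specimens, matrices / a list of
#'   assignments / a character vector.
#' @export
predict.shape_lda <- function(object, newdata,
                              type = c("assignment", "posterior",
                                       "mahalanobis", "class"),
                              reference = object$reference, mirror = FALSE,
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "shape_dataset")) {
    out <- lapply(newdata$configs, function(cfg)
      assign_unknown(object, cfg, reference, mirror))
    return(collect_predictions(out, type))
  }
  if (inherits(newdata, "landmark_config"))
    return(collect_predictions(
      list(assign_unknown(object, newdata, reference, mirror)), type,
      scalar = TRUE))
  X <- rbind(newdata)
  out <- lapply(seq_len(nrow(X)), function(i)
    tangent_assignment(object, X[i, ],
                       id = rownames(X)[i] %||% paste0("specimen_", i)))
  collect_predictions(out, type, scalar = nrow(X) == 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_predictions <- function(assignments, type, scalar = FALSE) {
  if (type == "assignment")
    return(if (scalar) assignments[[1L]] else assignments)
  val <- switch(type,
    posterior = t(vapply(assignments, `[[`,
                         assignments[[1L]]$posterior, "posterior")),
    mahalanobis = t(vapply(assignments, `[[`,
                           assignments[[1L]]$mahalanobis, "mahalanobis")),
    class = vapply(assignments, `[[`, character(1L), "assigned_group"))
  if (scalar && is.matrix(val)) val[1L, ] else val
}

#' Leave-one-out cross-validated classification report
#'
#' Each specimen is held out in turn, the discriminant model is refitted on
#' the remaining specimens, and the held-out specimen is assigned by maximal
#' posterior probability. The hit-ratio is the percentage of specimens
#' assigned back to their own a-priori group. By default the Procrustes
#' alignment (and hence the tangent coordinates) is computed once from the
#' full sample and held fixed across folds, which keeps folds in one common
#' shape space; `realign = TRUE` reruns the superimposition without the
#' held-out specimen in each fold (slower; for sensitivity analysis).
#'
#' @inheritParams shape_lda
#' @param realign logical: redo the GPA per fold (requires `x` to be a
#'   `gpa` fit built from a dataset's coordinates).
#' @param dataset the original [shape_dataset()]; only needed with
#'   `realign = TRUE`.
#' @return An object of class `loo_cv`: `global_hit_ratio` and
#'   `per_group_hit_ratio` (percentages), `n_misclassified`, `confusion`
#'   (true x predicted count table), `n`, and `predicted`.
#' @export
loo_cv <- function(x, grouping, priors = c("equal", "proportional"),
                   shrinkage = 0, var_tol = 1e-12, realign = FALSE,
                   dataset = NULL) {
  priors <- match.arg(priors)
  if (inherits(x, "gpa")) {
    X <- x$tangent
    if (is.character(grouping) && length(grouping) == 1L)
      grouping <- labels_lookup(x$labels, x$specimen_ids, grouping,
                                require_complete = TRUE)
  } else X <- x
  g <- factor(grouping)
  counts <- table(g)
  if (any(counts < 3L))
    stop("leave-one-out needs n >= 3 per group so every fold keeps n >= 2; ",
         "offending group(s): ",
         paste(names(counts)[counts < 3L], collapse = ", "))
  n <- nrow(X)
  if (realign) {
    if (is.null(dataset) || !inherits(dataset, "shape_dataset"))
      stop("realign = TRUE requires the original shape_dataset")
    if (length(dataset) != n) stop("dataset size does not match")
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(g[-i])
    if (nlevels(gi) < nlevels(g) || any(table(gi) < 2L))
      stop("removing specimen ", i, " leaves a group too small to fit")
    if (realign) {
      fold_fit <- gpa(dataset[-i])
      m <- shape_lda(fold_fit$tangent, gi, priors, shrinkage, var_tol)
      proj <- align_to_consensus(fold_fit, dataset$configs[[i]])
      pred[i] <- tangent_assignment(m, proj$tangent)$assigned_group
    } else {
      m <- shape_lda(X[-i, , drop = FALSE], gi, priors, shrinkage, var_tol)
      pred[i] <- tangent_assignment(m, X[i, ])$assigned_group
    }
  }
  truth <- as.character(g)
  confusion <- table(true = factor(truth, levels(g)),
                     predicted = factor(pred, levels(g)))
  n_miss <- sum(pred != truth)
  per_group <- 100 * diag(confusion) / as.vector(counts)
  structure(
    list(global_hit_ratio = 100 * (n - n_miss) / n,
         per_group_hit_ratio = per_group,
         n_misclassified = n_miss,
         confusion = confusion, n = n,
         predicted = stats::setNames(pred, rownames(X)),
         priors_mode = priors, realigned = realign),
    class = "loo_cv")
}

#' @export
print.loo_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation (", x$n, " specimens, priors: ",
      x$priors_mode, ")\n", sep = "")
  cat(sprintf("  global hit-ratio: %.1f%% (%d misclassified of %d)\n",
              x$global_hit_ratio, x$n_misclassified, x$n))
  cat("  per-group hit-ratio (%):\n")
  print(round(x$per_group_hit_ratio, 1))
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Hierarchical assignment cascade over nested reference datasets
#'
#' Runs the full placement pipeline -- superimposition, discriminant fit,
#' and a posteriori assignment of the unknown -- independently at each
#' stage of a cascade of reference datasets with successively finer
#' a-priori groupings (e.g. tribes, then genera within the winning clade,
#' then subgenera). Later stages are not gated on earlier outcomes: every
#' stage is evaluated and the whole chain reported.
#'
#' @param unknown a `landmark_config`.
#' @param stages list of stages, each a list with elements `dataset` (a
#'   [shape_dataset()]) and `level` (grouping level name); an optional
#'   `name` labels the stage in reports.
#' @param priors,shrinkage passed to [shape_lda()].
#' @param mirror mirror the unknown before every stage.
#' @return An object of class `assignment_chain`: list of `assignment`
#'   results, one per stage.
#' @export
hierarchical_assign <- function(unknown, stages,
                                priors = c("equal", "proportional"),
                                shrinkage = 0, mirror = FALSE) {
  priors <- match.arg(priors)
  if (!length(stages)) stop("need at least one stage")
  out <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    res <- tryCatch({
      fit <- gpa(st$dataset)
      model <- shape_lda(fit, st$level, priors = priors,
                         shrinkage = shrinkage)
      assign_unknown(model, unknown, fit, mirror = mirror)
    }, error = function(e)
      stop("assignment cascade failed at stage ", s,
           if (!is.null(st$name)) paste0(" ('", st$name, "')"),
           ": ", conditionMessage(e), call. = FALSE))
    out[[s]] <- res
  }
  names(out) <- vapply(seq_along(stages), function(s)
    stages[[s]]$name %||% stages[[s]]$level %||% paste0("stage_", s),
    character(1L))
  structure(out, class = "assignment_chain")
}

#' @export
print.assignment_chain <- function(x, ...) {
  cat("Hierarchical assignment chain (", length(x), " stages)\n", sep = "")
  for (s in seq_along(x)) {
    a <- x[[s]]
    best <- sort(a$posterior, decreasing = TRUE)
    cat(sprintf("  %d. %s -> %s (pp = %.3f, MD = %.3f)\n",
                s, names(x)[s], a$assigned_group, best[1L],
                a$mahalanobis[a$assigned_group]))
  }
  invisible(x)
}
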