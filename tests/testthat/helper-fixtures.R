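## Shared fixture builders. All randomness is seeded by the caller.

## one random non-degenerate configuration
random_config <- function(k = 18L, id = "r1") {
  landmark_config(matrix(stats::runif(k * 2L, -1, 1), k, 2L), id)
}

## a random dataset of n unrelated configurations
random_dataset <- function(n = 5L, k = 18L) {
  shape_dataset(lapply(seq_len(n), function(i)
    random_config(k, sprintf("r%02d", i))))
}

## apply a random similarity transform (proper rotation, scale, shift)
similarity_jitter <- function(m) {
  th <- stats::runif(1L, 0, 2 * pi)
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  sc <- exp(stats::runif(1L, -1, 1))
  sweep(m %*% R * sc, 2L, stats::runif(2L, -2, 2), `+`)
}

## brute-force superimposition residual: enumerate rotations on a grid
grid_search_residual <- function(A, B, step = 1e-4) {
  M <- crossprod(A, B)
  th <- seq(0, 2 * pi, by = step)
  ## ||A R(th) - B||^2 = ||A||^2 + ||B||^2 - 2 tr(R(th)' M)
  tr <- cos(th) * (M[1, 1] + M[2, 2]) + sin(th) * (M[1, 2] - M[2, 1])
  sqrt(max(0, sum(A^2) + sum(B^2) - 2 * max(tr)))
}

## dataset of g separated Gaussian groups directly in tangent-style form
separated_dataset <- function(n_groups = 4L, n_per = 25L, separation = 10,
                              within_sd = 0.01, seed = 1L) {
  spec <- synthetic_spec(hierarchy = c(group = n_groups),
                         n_per_group = n_per, within_sd = within_sd,
                         separation = separation, seed = seed)
  generate_dataset(spec)
}

cv_hit_ratio <- function(dataset, level = "group", ...) {
  loo_cv(gpa(dataset), level, ...)$global_hit_ratio
}
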