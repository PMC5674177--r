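## deterministic 2-group fixture with exactly isotropic within-group scatter
isotropic_two_groups <- function(mu_a = c(0, 0), mu_b = c(3, 1), a = 0.5) {
  X <- rbind(sweep(rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a)), 2, mu_a, `+`),
             sweep(rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a)), 2, mu_b, `+`))
  list(X = X, g = rep(c("a", "b"), each = 4L))
}

test_that("fit validates groups and degenerate covariances", {
  set.seed(31)
  X <- matrix(rnorm(40), 10L, 4L)
  expect_error(shape_lda(X, rep("a", 10L)), "at least 2 groups")
  expect_error(shape_lda(X, c(rep("a", 9L), "b")), "n >= 2.*b")
  ## zero within-group variance: two groups of identical points
  Xd <- rbind(matrix(0, 3L, 2L), matrix(1, 3L, 2L))
  expect_error(shape_lda(Xd, rep(c("a", "b"), each = 3L)), "singular")
})

test_that("with isotropic within-group scatter the canonical axis is the mean difference", {
  fx <- isotropic_two_groups()
  m <- shape_lda(fx$X, fx$g)
  expect_identical(ncol(m$axes), 1L)
  axis_full <- m$rotation %*% m$axes[, 1L]      # back to input basis
  delta <- c(3, 1)
  cosang <- abs(sum(axis_full * delta)) /
    (sqrt(sum(axis_full^2)) * sqrt(sum(delta^2)))
  expect_equal(cosang, 1, tolerance = 1e-6)
})

test_that("at most G - 1 canonical axes are returned", {
  set.seed(32)
  for (G in 2:4) {
    X <- matrix(rnorm(G * 20L * 6L), ncol = 6L)
    g <- rep(letters[1:G], each = 20L)
    X <- X + 5 * matrix(rep(seq_len(G), each = 20L), ncol = 1L)[, rep(1, 6)]
    m <- shape_lda(X, g)
    expect_lte(ncol(m$axes), G - 1L)
  }
})

test_that("priors follow the requested mode and sum to one", {
  set.seed(33)
  X <- matrix(rnorm(200), 40L, 5L)
  g <- rep(c("a", "b"), c(30L, 10L))
  me <- shape_lda(X, g, priors = "equal")
  mp <- shape_lda(X, g, priors = "proportional")
  expect_equal(unname(me$priors), c(0.5, 0.5))
  expect_equal(unname(mp$priors), c(0.75, 0.25))
  expect_equal(sum(me$priors), 1, tolerance = 1e-12)
})

test_that("posteriors agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(34)
  X <- rbind(matrix(rnorm(60, 0), 20L, 3L),
             matrix(rnorm(60, 1.5), 20L, 3L),
             matrix(rnorm(60, 3), 20L, 3L))
  g <- rep(c("a", "b", "c"), each = 20L)
  m <- shape_lda(X, g, priors = "equal")
  P1 <- predict(m, X, type = "posterior")
  P2 <- predict(MASS::lda(X, g, prior = rep(1, 3) / 3), X)$posterior
  expect_equal(unname(P1), unname(P2), tolerance = 1e-8)
  expect_equal(predict(m, X, type = "class"),
               unname(as.character(predict(MASS::lda(X, g,
                 prior = rep(1, 3) / 3), X)$class)),
               ignore_attr = TRUE)
})

test_that("Mahalanobis distances obey their closed forms", {
  set.seed(35)
  fx <- isotropic_two_groups(a = 1)
  m <- shape_lda(fx$X, fx$g)
  ## at a group mean the distance to that group is zero
  mu_full <- m$center + as.vector(m$rotation %*% m$group_means["a", ])
  expect_equal(unname(mahalanobis_to_groups(m, mu_full)["a"]), 0,
               tolerance = 1e-10)
  ## identity pooled covariance -> Euclidean distance
  for (i in 1:20) {
    X <- rbind(matrix(rnorm(40), 20L, 2L),
               matrix(rnorm(40, 4), 20L, 2L))
    g <- rep(c("a", "b"), each = 20L)
    mm <- shape_lda(X, g)
    x <- rnorm(2)
    ## whiten distances by hand through the pooled covariance
    z <- drop(crossprod(m_reduce <- mm$rotation, x - mm$center))
    d_manual <- sqrt(unname(stats::mahalanobis(rbind(z),
                                               mm$group_means["a", ],
                                               mm$pooled_cov)))
    expect_equal(unname(mahalanobis_to_groups(mm, x)["a"]), d_manual,
                 tolerance = 1e-8)
  }
})

test_that("MD via the Cholesky solve matches the explicit inverse", {
  set.seed(36)
  for (i in 1:10) {
    d <- sample(2:6, 1L)
    A <- matrix(rnorm(d * d * 4L), ncol = d)
    S <- crossprod(A) / (4L * d)              # random SPD
    mu <- rnorm(d); x <- rnorm(d)
    md2_inv <- drop(t(x - mu) %*% solve(S) %*% (x - mu))
    U <- backsolve(chol(S), x - mu, transpose = TRUE)
    expect_equal(sum(U^2), md2_inv, tolerance = 1e-8)
  }
})

test_that("posterior probabilities are a proper softmax of the scores", {
  fx <- isotropic_two_groups(mu_a = c(-1, 0), mu_b = c(1, 0))
  m <- shape_lda(fx$X, fx$g)
  ## equidistant point with equal priors -> (0.5, 0.5)
  mid <- c(0, 0)
  p <- posterior_probabilities(m, mid)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  ## at a well-separated group mean the posterior concentrates
  fx2 <- isotropic_two_groups(mu_a = c(0, 0), mu_b = c(20, 0), a = 0.5)
  m2 <- shape_lda(fx2$X, fx2$g)
  p2 <- posterior_probabilities(m2, c(0, 0))
  expect_gte(unname(p2["a"]), 0.99)
})

test_that("leave-one-out separates separated groups and not identical ones", {
  ## strong separation: near-perfect hit-ratio
  ds <- separated_dataset(4L, 25L, separation = 10, seed = 41L)
  cv <- loo_cv(gpa(ds), "group")
  expect_gte(cv$global_hit_ratio, 95)
  expect_equal(cv$global_hit_ratio,
               100 * (cv$n - cv$n_misclassified) / cv$n)
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.vector(table(taxon_labels(ds, "group")))))
  ## identical generating distributions: chance level for 2 groups
  spec0 <- synthetic_spec(hierarchy = c(group = 2L), n_per_group = 50L,
                          separation = 0, seed = 42L)
  cv0 <- loo_cv(gpa(generate_dataset(spec0)), "group")
  hits <- cv0$n - cv0$n_misclassified
  expect_gte(hits, qbinom(0.005, 100L, 0.5))
  expect_lte(hits, qbinom(0.995, 100L, 0.5))
})

test_that("duplicated specimens are always recovered by their twin", {
  set.seed(43)
  ds <- separated_dataset(3L, 6L, separation = 8, seed = 43L)
  arr <- coords_array(ds)
  twin <- array(c(arr, arr), c(dim(arr)[1:2], 2L * dim(arr)[3L]))
  dimnames(twin)[[3L]] <- c(dimnames(arr)[[3L]],
                            paste0(dimnames(arr)[[3L]], "_b"))
  g <- rep(taxon_labels(ds, "group"), 2L)
  cv <- loo_cv(gpa(twin), g, shrinkage = 0.1)
  expect_equal(cv$global_hit_ratio, 100)
})

test_that("LOO is invariant to specimen order and similarity nuisance", {
  set.seed(44)
  ds <- separated_dataset(2L, 12L, separation = 3, within_sd = 0.03,
                          seed = 44L)
  g <- taxon_labels(ds, "group")
  cv1 <- loo_cv(gpa(ds), g, shrinkage = 0.1)
  arr <- coords_array(ds)
  perm <- sample(dim(arr)[3L])
  arr2 <- arr[, , perm]
  for (i in seq_len(dim(arr2)[3L]))
    arr2[, , i] <- similarity_jitter(arr2[, , i])
  cv2 <- loo_cv(gpa(arr2), g[perm], shrinkage = 0.1)
  expect_equal(cv1$global_hit_ratio, cv2$global_hit_ratio)
  expect_equal(cv1$confusion, cv2$confusion)
})

test_that("LOO refuses folds that would leave a singleton group", {
  set.seed(45)
  X <- matrix(rnorm(24L), 12L, 2L)
  expect_error(loo_cv(X, rep(c("a", "b"), c(10L, 2L))), "n >= 3")
})

test_that("per-fold realignment is available and consistent when separable", {
  ds <- separated_dataset(2L, 8L, separation = 10, seed = 46L)
  fit <- gpa(ds)
  cv_fixed <- loo_cv(fit, "group", shrinkage = 0.1)
  cv_re <- loo_cv(fit, "group", realign = TRUE, dataset = ds,
                  shrinkage = 0.1)
  expect_equal(cv_fixed$global_hit_ratio, 100)
  expect_equal(cv_re$global_hit_ratio, 100)
})

test_that("assigning a training specimen recovers its own group", {
  spec <- synthetic_spec(hierarchy = c(group = 3L), n_per_group = 20L,
                         seed = 47L)
  ds <- generate_dataset(spec)
  fit <- gpa(ds)
  m <- shape_lda(fit, "group")
  g <- taxon_labels(ds, "group")
  for (i in c(1L, 25L, 50L)) {
    a <- assign_unknown(m, ds$configs[[i]])
    expect_identical(a$assigned_group, g[i])
    expect_equal(sum(a$posterior), 1, tolerance = 1e-12)
  }
})

test_that("unknowns drawn from a group are assigned to it with equal-prior coherence", {
  spec <- synthetic_spec(hierarchy = c(group = 4L), n_per_group = 25L,
                         seed = 48L)
  fit <- gpa(generate_dataset(spec))
  m <- shape_lda(fit, "group")
  hits <- 0L
  for (r in 1:100) {
    u <- make_unknown(spec, "group2", seed = 5000L + r)
    a <- assign_unknown(m, u)
    if (a$assigned_group == "group2") hits <- hits + 1L
    ## argmax posterior == argmin Mahalanobis under equal priors
    expect_identical(names(which.max(a$posterior)),
                     names(which.min(a$mahalanobis)))
  }
  expect_gte(hits, 99L)
})

test_that("a symmetric midpoint unknown splits its posterior 50/50", {
  ## two groups mirrored about the consensus: tangent means are +/- delta
  set.seed(49)
  fx <- isotropic_two_groups(mu_a = c(-2, 0), mu_b = c(2, 0))
  m <- shape_lda(fx$X, fx$g)
  p <- posterior_probabilities(m, c(0, 0))
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("exact posterior ties break to the alphabetically first group", {
  fx <- isotropic_two_groups(mu_a = c(-1, 0), mu_b = c(1, 0))
  m <- shape_lda(fx$X, fx$g)
  expect_warning(a <- wingmorph:::tangent_assignment(m, c(0, 0)),
                 "tie")
  expect_identical(a$assigned_group, "a")
})

test_that("scheme mismatch between unknown and reference errors clearly", {
  ds <- separated_dataset(2L, 5L, seed = 50L)
  fit <- gpa(ds)
  m <- shape_lda(fit, "group", shrinkage = 0.3)
  expect_error(assign_unknown(m, template_wing(12L)), "mismatch")
})

test_that("hit-ratio never degrades as group separation grows", {
  seps <- c(0.5, 2, 8)
  mean_hit <- vapply(seps, function(s) {
    hits <- vapply(1:20, function(r) {
      ds <- separated_dataset(2L, 25L, separation = s, within_sd = 0.02,
                              seed = 600L + 37L * r + round(100 * s))
      cv_hit_ratio(ds)
    }, numeric(1L))
    mean(hits)
  }, numeric(1L))
  expect_true(all(diff(mean_hit) >= 0))
})

test_that("group mean tangent vectors are recovered from generated data", {
  spec <- synthetic_spec(hierarchy = c(group = 3L), n_per_group = 30L,
                         seed = 51L)
  ds <- generate_dataset(spec)
  fit <- gpa(ds)
  m <- shape_lda(fit, "group")
  gm <- make_group_means(spec)
  se <- spec$within_sd / sqrt(spec$n_per_group)
  for (grp in m$groups) {
    truth <- align_to_consensus(fit,
               landmark_config(gm$means[[grp]], "mu"))$tangent
    est <- m$center + as.vector(m$rotation %*% m$group_means[grp, ])
    dev <- abs(est - truth)
    expect_lt(mean(dev), 2 * se)
    expect_lt(max(dev), 6 * se)
  }
})

test_that("hierarchical cascades report every stage and reduce to one", {
  spec <- synthetic_spec(hierarchy = c(tribe = 3L, genus = 2L,
                                       subgenus = 2L),
                         n_per_group = 25L, seed = 52L)
  ds <- generate_dataset(spec)
  target <- c("tribe2", "tribe2.genus1", "tribe2.genus1.subgenus2")
  u <- make_unknown(spec, target[3L], seed = 999L)
  ## nested stage datasets: full -> winning tribe -> winning genus
  stages <- list(
    list(dataset = ds, level = "tribe"),
    list(dataset = ds[taxon_labels(ds, "tribe") == target[1L]],
         level = "genus"),
    list(dataset = ds[taxon_labels(ds, "genus") == target[2L]],
         level = "subgenus"))
  chain <- hierarchical_assign(u, stages)
  expect_length(chain, 3L)
  expect_identical(vapply(chain, `[[`, character(1L), "assigned_group"),
                   setNames(target, c("tribe", "genus", "subgenus")))
  ## single-stage chain equals a direct assignment
  one <- hierarchical_assign(u, stages[1L])
  fit1 <- gpa(ds)
  m1 <- shape_lda(fit1, "tribe")
  direct <- assign_unknown(m1, u)
  expect_equal(one[[1L]]$posterior, direct$posterior, tolerance = 1e-10)
  ## shuffling specimen order changes nothing
  set.seed(53)
  stages_shuf <- lapply(stages, function(st) {
    st$dataset <- st$dataset[sample(length(st$dataset))]
    st
  })
  chain2 <- hierarchical_assign(u, stages_shuf)
  for (s in 1:3)
    expect_equal(chain2[[s]]$posterior, chain[[s]]$posterior,
                 tolerance = 1e-8)
})

test_that("a failing stage aborts the chain with its index", {
  ds <- separated_dataset(2L, 5L, seed = 54L)
  stages <- list(list(dataset = ds, level = "group"),
                 list(dataset = ds, level = "nonexistent"))
  u <- make_unknown(synthetic_spec(hierarchy = c(group = 2L),
                                   n_per_group = 5L, seed = 54L),
                    "group1")
  expect_error(hierarchical_assign(u, stages, shrinkage = 0.2), "stage 2")
})
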