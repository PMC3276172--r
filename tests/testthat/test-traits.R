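make_components <- function() {
  ## two components x three environments, four strains incl. reference
  grid <- expand.grid(strain = c("ref", "same", "double", "half"),
                      environment = c("e1", "e2", "e3"),
                      stringsAsFactors = FALSE)
  grid$lag_h <- 2
  grid$doubling_h <- 1.5
  grid$lag_h[grid$strain == "double"] <- 4
  grid$doubling_h[grid$strain == "half"] <- 0.75
  grid
}

test_that("trait matrices are log2 ratios against the reference", {
  tm <- build_trait_matrix(make_components(), reference = "ref",
                           component_cols = c("lag_h", "doubling_h"))
  expect_equal(dim(unclass(tm)), c(4L, 6L))       # 2 components x 3 envs
  expect_equal(unname(unclass(tm)["ref", ]), rep(0, 6))
  expect_equal(unname(unclass(tm)["same", ]), rep(0, 6))
  expect_equal(unname(unclass(tm)["double", grepl("lag", colnames(tm))]),
               rep(1, 3))
  expect_equal(unname(unclass(tm)["half", grepl("doubling", colnames(tm))]),
               rep(-1, 3))
  expect_error(build_trait_matrix(make_components(), reference = "nope"),
               "absent")
})

test_that("three components over 42 environments give 126 traits", {
  grid <- expand.grid(strain = c("ref", "s1"),
                      environment = sprintf("env%02d", 1:42),
                      stringsAsFactors = FALSE)
  grid$lag_h <- 2; grid$doubling_h <- 1.5; grid$efficiency <- 1.1
  tm <- build_trait_matrix(grid, reference = "ref",
                           component_cols = c("lag_h", "doubling_h",
                                              "efficiency"))
  expect_equal(ncol(tm), 126L)
})

test_that("profile clustering recovers planted structure deterministically", {
  tmx <- simulate_trait_matrix(trait_matrix_params(
    n_strains = 16, n_traits = 50, n_groups = 2, group_effect_sd = 1,
    noise_sd = 0.1, seed = 14))
  tree <- cluster_profiles(tmx$matrix)
  cut2 <- cutree(tree, 2)
  ## first bipartition equals the planted groups (up to label swap)
  expect_equal(length(unique(paste(cut2, tmx$group))), 2L)

  ## duplicated strains merge at height 0
  m <- tmx$matrix[c(1, 1, 5, 9), ]
  rownames(m) <- paste0("s", 1:4)
  tr2 <- cluster_profiles(m)
  expect_equal(min(tr2$height), 0, tolerance = 1e-12)

  ## anti-correlated profiles sit at distance 2
  v <- seq(-1, 1, length.out = 20)
  m2 <- rbind(a = v, b = -v, c = v + rnorm(20, 0, 0.01))
  tr3 <- cluster_profiles(m2)
  expect_equal(max(tr3$height), 2, tolerance = 0.01)

  ## invariance to trait order and strain order (same merge heights)
  perm_t <- tmx$matrix[, sample(ncol(tmx$matrix))]
  expect_equal(sort(cluster_profiles(perm_t)$height), sort(tree$height))
  perm_s <- tmx$matrix[sample(nrow(tmx$matrix)), ]
  expect_equal(sort(cluster_profiles(perm_s)$height), sort(tree$height))

  expect_error(cluster_profiles(tmx$matrix[1:2, ]), ">= 3")
})

test_that("within-group similarity exceeds between-group similarity", {
  ## noise-free: within-group correlations are exactly 1
  tm0 <- simulate_trait_matrix(trait_matrix_params(
    n_strains = 12, n_traits = 40, n_groups = 3, group_effect_sd = 1,
    noise_sd = 0, seed = 31))
  rep0 <- group_similarity(tm0$matrix, tm0$group)
  expect_equal(rep0$within_mean, 1, tolerance = 1e-12)
  expect_gt(rep0$within_mean, rep0$between_mean)

  ## planted structure at realistic noise: strongly significant
  tm1 <- simulate_trait_matrix(trait_matrix_params(
    n_strains = 40, n_traits = 126, n_groups = 4, group_effect_sd = 1,
    noise_sd = 0.3, seed = 32))
  rep1 <- group_similarity(tm1$matrix, tm1$group)
  expect_lt(rep1$p_value, 0.001)
  ## pooled-variance option also available
  rep1p <- group_similarity(tm1$matrix, tm1$group, var_equal = TRUE)
  expect_lt(rep1p$p_value, 0.001)

  one <- setNames(rep("g", 12), rownames(tm0$matrix))
  expect_error(group_similarity(tm0$matrix, one), "different-group")
})

test_that("atypicality ranking puts the mean-like strain last and outliers first", {
  set.seed(55)
  base <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("s", 1:10), paste0("t", 1:30)))
  base["s1", ] <- colMeans(base[2:10, ])  # close to the mean profile
  rk <- atypicality_ranking(base)
  expect_equal(rk$strain[nrow(rk)], "s1")
  expect_gt(rk$similarity[rk$strain == "s1"], 0.9)

  tmx <- simulate_trait_matrix(trait_matrix_params(
    n_strains = 20, n_traits = 80, n_groups = 1, group_effect_sd = 1,
    noise_sd = 0.2, outlier_ids = 13L, outlier_fraction = 0.25, seed = 6))
  rk2 <- atypicality_ranking(tmx$matrix)
  expect_equal(rk2$strain[1L], "strain13")
})

test_that("deviant-trait fractions respect the planted signal and the null", {
  set.seed(70)
  n_tr <- 60
  reps <- expand.grid(strain = sprintf("s%02d", 1:12),
                      trait = sprintf("t%02d", 1:n_tr), rep = 1:3,
                      stringsAsFactors = FALSE)
  reps$value <- rnorm(nrow(reps))
  shifted <- sprintf("t%02d", 1:12)      # 20% of traits, 5 SD shift
  sel <- reps$strain == "s01" & reps$trait %in% shifted
  reps$value[sel] <- reps$value[sel] + 5
  ## pooled-variance form: with few replicates the Welch df collapse,
  ## so the classical Student test is the powered choice here
  dv <- deviant_trait_fraction(reps, "s01", fdr = 0.05, var_equal = TRUE)
  expect_equal(dv$fraction, 0.2, tolerance = 0.25)
  expect_true(all(shifted %in% dv$tests$trait[dv$tests$significant]))

  ## zero-variance population with identical strain: nothing deviates
  reps0 <- reps; reps0$value <- 1
  dv0 <- deviant_trait_fraction(reps0, "s01")
  expect_equal(dv0$fraction, 0)

  ## strain with < 2 replicates is skipped with warning
  reps1 <- reps[!(reps$strain == "s01" & reps$rep > 1 &
                    reps$trait == "t01"), ]
  expect_warning(deviant_trait_fraction(reps1, "s01"), "skipped")
})
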