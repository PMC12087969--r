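test_that("screening keeps uncorrelated variables and collapses collinear
          groups by PC contribution", {
  set.seed(2)
  X <- matrix(rnorm(11 * 60), 60, 11,
              dimnames = list(NULL, paste0("v", 1:11)))
  scr <- screen_variables(X, threshold = 0.8)
  expect_setequal(scr$selected, colnames(X))
  # two perfectly collinear variables: one survives, by contribution
  Y <- data.frame(a = rnorm(30))
  Y$b <- 2 * Y$a
  Y$c <- rnorm(30)
  scr2 <- screen_variables(Y)
  expect_length(intersect(scr2$selected, c("a", "b")), 1L)
  expect_true("c" %in% scr2$selected)
  # hand-checked toy: contribution ranks from prcomp on 5 records
  Z <- data.frame(p = c(1, 2, 3, 4, 5), q = c(2, 4, 6, 8, 10),
                  r = c(5, 1, 4, 2, 3))
  pca <- prcomp(Z, scale. = TRUE)
  contrib <- colSums(t(pca$rotation)^2 * pca$sdev^2)
  scr3 <- screen_variables(Z)
  expect_equal(unname(scr3$contribution[names(contrib)]), unname(contrib))
  expect_identical(setdiff(c("p", "q"), scr3$selected),
                   c("p", "q")[which.min(contrib[c("p", "q")])])
})

test_that("a constant variable is excluded with a warning", {
  X <- data.frame(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  expect_warning(scr <- screen_variables(X), "constant")
  expect_false("b" %in% scr$selected)
})

test_that("greedy spatial thinning matches the brute-force rule", {
  recs <- data.frame(lon = c(0, 0.01, 0.5, 10), lat = c(0, 0.01, 0.5, 10))
  expect_identical(thin_records(recs, 0), recs)
  two <- data.frame(lon = c(0, 0.045), lat = c(0, 0)) # ~5 km apart
  expect_equal(nrow(thin_records(two, 6)), 1L)
  set.seed(4)
  pts <- data.frame(lon = rnorm(10, sd = 0.1), lat = rnorm(10, sd = 0.1))
  kept <- thin_records(pts, 8)
  # brute-force greedy: same rule evaluated by exhaustive pairwise distances
  keep_idx <- 1L
  for (i in 2:10) {
    dd <- geosphere::distHaversine(as.matrix(pts[keep_idx, ]),
                                   as.matrix(pts[i, ])) / 1000
    if (all(dd >= 8)) keep_idx <- c(keep_idx, i)
  }
  expect_identical(rownames(kept), as.character(keep_idx))
})

test_that("maxent: zero weights at matched means, grid-search oracle,
          KKT bound and normalization", {
  set.seed(7)
  bg <- data.frame(x = c(0, 0.5, 1, 0.2, 0.8))
  pres_matched <- bg[c(1:5, 5:1), , drop = FALSE]
  m0 <- fit_maxent_linear(pres_matched, bg, reg_multiplier = 1.5)
  expect_lt(max(abs(m0$weights)), 1e-4)
  # 3-cell toy, one variable: dense grid search of the objective
  bg3 <- data.frame(x = c(0, 1, 2))
  pr3 <- data.frame(x = c(2, 2, 1, 2))
  m <- fit_maxent_linear(pr3, bg3, reg_multiplier = 0.5)
  xs <- (bg3$x - 0) / 2
  pbar <- mean((pr3$x - 0) / 2)
  beta <- 0.5 * sd((pr3$x) / 2) / sqrt(4)
  obj <- function(w) log(sum(exp(w * xs))) - w * pbar + beta * abs(w)
  grid <- seq(-20, 20, by = 1e-4)
  w_star <- grid[which.min(vapply(grid, obj, numeric(1)))]
  expect_equal(unname(m$weights), w_star, tolerance = 1e-3)
  expect_lt(abs(obj(m$weights) - obj(w_star)), 1e-6)
  # KKT inequality and Gibbs normalization for a generic fit
  set.seed(8)
  bgn <- data.frame(a = runif(80), b = runif(80))
  prn <- bgn[sample(80, 25, prob = bgn$a + 0.1), ]
  mf <- fit_maxent_linear(prn, bgn, 1.5)
  expect_true(all(abs(mf$model_means - mf$presence_means) <=
                    mf$beta + 1e-6))
  q <- maxent_density(mf, bgn)
  expect_equal(sum(q), 1, tolerance = 1e-12)
})

test_that("increasing the regularization multiplier never grows weights", {
  set.seed(9)
  bg <- data.frame(a = runif(60), b = runif(60))
  pr <- bg[sample(60, 20, prob = exp(2 * bg$a)), ]
  w <- sapply(c(0.5, 1, 1.5, 2.5, 4), function(r)
    max(abs(fit_maxent_linear(pr, bg, r)$weights)))
  expect_true(all(diff(w) <= 1e-6))
})

test_that("projection: class bounds, constant map for zero weights,
          training identity", {
  expect_identical(classify_suitability(c(0.6, 0.4, 0.2)),
                   c("suitable", "less_suitable", "unsuitable"))
  expect_identical(classify_suitability(c(0.5, 0.3)),
                   c("less_suitable", "unsuitable"))
  set.seed(10)
  cl <- simulate_climate_history(1, 0, seed = 3)
  slice <- cl[[1]]
  bg <- data.frame(MAT = as.vector(slice$vars$MAT),
                   TS = as.vector(slice$vars$TS))
  pr <- bg[sample(nrow(bg), 30), ]
  m0 <- fit_maxent_linear(pr, bg, 1e6) # crushing penalty: weights 0
  expect_lt(max(abs(m0$weights)), 1e-8)
  map0 <- project_suitability(m0, slice)
  expect_equal(max(map0$P) - min(map0$P), 0, tolerance = 1e-12)
  pr2 <- bg[order(bg$MAT)[1:40], ]
  m <- fit_maxent_linear(pr2, bg, 1.5)
  map <- project_suitability(m, slice)
  direct <- .maxent_suitability(m, bg)
  expect_equal(as.vector(map$P), direct, tolerance = 1e-12)
  expect_error(project_suitability(m, list(vars = list(TS = slice$vars$TS),
                                           lon = slice$lon,
                                           lat = slice$lat)),
               "MAT")
})

test_that("AUC: separation gives 1, random scores give ~0.5, replicate
          evaluation is reproducible", {
  expect_equal(auc_presence_background(6:10, 1:5), 1)
  set.seed(11)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(auc_presence_background(a, b) - 0.5), 0.05)
  set.seed(12)
  bg <- data.frame(a = runif(80), b = runif(80))
  pr <- bg[sample(80, 30, prob = exp(3 * bg$a)), ]
  e1 <- evaluate_enm(pr, bg, 0.2, 5, seed = 99)
  e2 <- evaluate_enm(pr, bg, 0.2, 5, seed = 99)
  expect_identical(e1$auc_test, e2$auc_test)
  expect_error(evaluate_enm(pr[1:2, , drop = FALSE], bg, 0.5, 2),
               "too few")
})

test_that("training AUC on the planted synthetic niche exceeds 0.8", {
  cl <- simulate_climate_history(1, 0, seed = 21)
  slice <- cl[[1]]
  cfg <- sim_config(seed = 21, n_extant = 6, n_fossil = 0, root_age = 20,
                    birth_rate = 0.15, death_rate = 0,
                    fossil_sampling_rate = 0)
  tr <- simulate_fbd_tree(cfg)
  occ <- simulate_occurrences(tr, cl, n_per_slice = 120, seed = 22)
  vars <- c("MAT", "TS", "MAP")
  bg <- data.frame(lapply(slice$vars[vars], as.vector))
  ev <- evaluate_enm(occ[vars], bg, 0.2, 3, seed = 23)
  expect_gt(ev$auc_train, 0.8)
})
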