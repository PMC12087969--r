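test_that("lambda = 1 reproduces the untransformed BM likelihood and the
          profile matches a fine grid search", {
  set.seed(1)
  tr <- pb_tree(12)
  x <- simulate_bm_trait(tr, 0.5, 0, seed = 2)[tr$tip.label]
  C <- ape::vcv(tr)
  fit1 <- bm_loglik_C(C, x)
  res <- pagel_lambda(tr, x)
  C1 <- 1 * C; diag(C1) <- diag(C)
  expect_identical(bm_loglik_C(C1, x)$logL, fit1$logL)
  # grid-search oracle on a 5-tip tree, 1e-4 steps
  tr5 <- ape::read.tree(text = "((a:1,b:1):1,((c:0.5,d:0.5):0.5,e:1):1);")
  x5 <- c(a = 1.2, b = 0.9, c = 3.1, d = 2.8, e = 0.5)
  r5 <- pagel_lambda(tr5, x5)
  C5 <- ape::vcv(tr5)
  prof <- function(l) { M <- l * C5; diag(M) <- diag(C5)
    bm_loglik_C(M, x5)$logL }
  grid <- seq(0, r5$lambda_max, by = 1e-4)
  l_star <- grid[which.max(vapply(grid, prof, numeric(1)))]
  expect_equal(r5$lambda, l_star, tolerance = 2e-4)
})

test_that("lambda can exceed 1 on non-ultrametric trees when the data
          demand it", {
  set.seed(5)
  cfg <- sim_config(seed = 5, n_extant = 20, n_fossil = 12, root_age = 60,
                    birth_rate = 0.09, death_rate = 0.03,
                    fossil_sampling_rate = 0.01)
  tr <- simulate_fbd_tree(cfg)
  x <- simulate_bm_trait(tr, 0.4, 0, seed = 6)[tr$tip.label]
  r <- pagel_lambda(tr, x)
  expect_gt(r$lambda_max, 1)
  expect_true(r$lambda >= 0 && r$lambda <= r$lambda_max)
})

test_that("lambda and K are invariant to affine trait transforms", {
  set.seed(7)
  tr <- pb_tree(16)
  x <- simulate_bm_trait(tr, 1, 0, seed = 8)[tr$tip.label]
  y <- 3.7 * x - 11
  expect_equal(pagel_lambda(tr, x)$lambda, pagel_lambda(tr, y)$lambda,
               tolerance = 1e-8)
  expect_equal(blomberg_k(tr, x, n_perm = 0)$K,
               blomberg_k(tr, y, n_perm = 0)$K, tolerance = 1e-8)
})

test_that("likelihoods agree with the naive MVN oracle on small trees", {
  for (s in 1:4) {
    set.seed(s)
    tr <- pb_tree(6)
    x <- simulate_bm_trait(tr, 0.7, 2, seed = 10 + s)[tr$tip.label]
    C <- ape::vcv(tr)
    expect_equal(bm_loglik_C(C, x)$logL, mvn_profile_loglik(C, x),
                 tolerance = 1e-8)
    Cl <- 0.6 * C; diag(Cl) <- diag(C)
    expect_equal(bm_loglik_C(Cl, x)$logL, mvn_profile_loglik(Cl, x),
                 tolerance = 1e-8)
  }
})

test_that("our lambda and K agree with phytools on the same data", {
  skip_if_not_installed("phytools")
  set.seed(9)
  tr <- pb_tree(24)
  x <- simulate_bm_trait(tr, 0.3, 1, seed = 12)[tr$tip.label]
  ours_l <- pagel_lambda(tr, x)
  ref_l <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours_l$lambda, ref_l$lambda, tolerance = 1e-3)
  ours_k <- blomberg_k(tr, x, n_perm = 0)
  ref_k <- phytools::phylosig(tr, x, method = "K")
  expect_equal(ours_k$K, as.numeric(ref_k), tolerance = 1e-6)
})

test_that("shuffling tips destroys signal: K drops in nearly all replicates", {
  drops <- 0L
  for (r in 1:20) {
    set.seed(40 + r)
    tr <- pb_tree(32)
    x <- simulate_bm_trait(tr, 0.5, 0, seed = 140 + r)[tr$tip.label]
    k1 <- blomberg_k(tr, x, n_perm = 0)$K
    xs <- setNames(sample(x), names(x))
    k2 <- blomberg_k(tr, xs, n_perm = 0)$K
    if (k2 < k1) drops <- drops + 1L
  }
  expect_gte(drops, 19L)
})

test_that("constant trait is rejected for K", {
  tr <- pb_tree(8)
  expect_error(blomberg_k(tr, setNames(rep(1, 8), tr$tip.label)),
               "constant")
})

test_that("evolutionary model suite: nested transforms reproduce BM exactly
          and the OU small-alpha limit approaches BM", {
  set.seed(13)
  cfg <- sim_config(seed = 13, n_extant = 14, n_fossil = 6, root_age = 50,
                    birth_rate = 0.1, death_rate = 0.03,
                    fossil_sampling_rate = 0.008)
  tr <- simulate_fbd_tree(cfg)
  x <- simulate_bm_trait(tr, 0.3, 0, seed = 14)[tr$tip.label]
  S <- ape::vcv(tr); Dg <- diag(S); Tm <- max(Dg)
  bm <- bm_loglik_C(S, x)$logL
  lb1 <- .evo_cov$LB(S, Dg, Tm, 1); expect_equal(bm_loglik_C(lb1, x)$logL, bm)
  dt1 <- .evo_cov$DT(S, Dg, Tm, 1)
  expect_equal(bm_loglik_C(dt1, x)$logL, bm, tolerance = 1e-10)
  rt0 <- .evo_cov$RT(S, Dg, Tm, 0)
  expect_equal(bm_loglik_C(rt0, x)$logL, bm, tolerance = 1e-10)
  tr2 <- tr; tr2$edge.length <- tr$edge.length^1
  expect_equal(bm_loglik_C(ape::vcv(tr2), x)$logL, bm)
  ou <- .evo_cov$OU(S, Dg, Tm, 1e-8)
  expect_lt(abs(bm_loglik_C(ou, x)$logL - bm), 1e-4)
  eb <- .evo_cov$EB(S, Dg, Tm, -1e-9)
  expect_lt(abs(bm_loglik_C(eb, x)$logL - bm), 1e-4)
})

test_that("AICc identity holds and the table covers the nine models", {
  set.seed(15)
  cfg <- sim_config(seed = 15, n_extant = 12, n_fossil = 6, root_age = 50,
                    birth_rate = 0.1, death_rate = 0.03,
                    fossil_sampling_rate = 0.008)
  tr <- simulate_fbd_tree(cfg)
  x <- simulate_bm_trait(tr, 0.3, 0, seed = 16)[tr$tip.label]
  tab <- fit_evo_models(tr, x)
  expect_setequal(tab$model, c("WN", "BM", "RT", "MT", "DT", "LB", "KP",
                               "EB", "OU"))
  n <- ape::Ntip(tr)
  ok <- !is.na(tab$logL)
  expect_equal(tab$AICc[ok],
               -2 * tab$logL[ok] + 2 * tab$k[ok] +
                 2 * tab$k[ok] * (tab$k[ok] + 1) / (n - tab$k[ok] - 1))
  expect_true(any(ok))
})

test_that("BM data usually rank BM within 2 AICc of the best model", {
  wins <- 0L
  for (r in 1:25) {
    set.seed(200 + r)
    tr <- pb_tree(40)
    x <- simulate_bm_trait(tr, 0.5, 0, seed = 300 + r)[tr$tip.label]
    tab <- fit_evo_models(tr, x)
    d <- tab$delta_AICc[tab$model == "BM"]
    if (!is.na(d) && d <= 2) wins <- wins + 1L
  }
  expect_gte(wins, 20L) # >= 80% of replicates
})

test_that("PGLS: star tree equals OLS, small-matrix oracle, planted
          wing-length/shape association recovered", {
  # star tree: BM covariance is diagonal -> identical to OLS
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  y <- c(a = 1, b = 3, c = 2, d = 5, e = 4, f = 6)
  p <- data.frame(z = c(2, 6, 4, 10, 8, 12) + c(0.1, -0.2, 0.3, 0, -0.1, 0.2),
                  row.names = letters[1:6])
  g <- pgls(star, y, p)
  o <- lm(y ~ z, data = cbind(p, y = y[rownames(p)]))
  expect_equal(unname(g$coefficients$estimate), unname(coef(o)),
               tolerance = 1e-10)
  # 4-tip GLS oracle by explicit matrix algebra
  tr4 <- toy_tree()
  y4 <- c(a = 1, b = 2, c = 4, d = 3)
  x4 <- data.frame(w = c(0.5, 1, 2.5, 2), row.names = c("a", "b", "c", "d"))
  g4 <- pgls(tr4, y4, x4)
  C <- ape::vcv(tr4)
  X <- cbind(1, x4[tr4$tip.label, ])
  beta <- solve(t(X) %*% solve(C) %*% X) %*% t(X) %*% solve(C) %*%
    y4[tr4$tip.label]
  expect_equal(unname(g4$coefficients$estimate), drop(beta),
               tolerance = 1e-10)
  expect_error(pgls(tr4, y4, data.frame(a = 1:4, b = 2 * (1:4))),
               "collinear")
  # planted association: falcate lineages get longer wings
  hits <- 0L
  for (r in 1:25) {
    set.seed(400 + r)
    tr <- pb_tree(30)
    shp <- simulate_mk_trait(tr, 0.3, seed = 500 + r)[tr$tip.label]
    wl <- simulate_bm_trait(tr, 0.2, 5, seed = 600 + r)[tr$tip.label] +
      2 * (shp == "falcate")
    if (length(unique(shp)) < 2) next
    g <- pgls(tr, wl, data.frame(shape = factor(shp, c("oval", "falcate")),
                                 row.names = names(shp)))
    if (g$coefficients["shapefalcate", "estimate"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 23L)
})
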