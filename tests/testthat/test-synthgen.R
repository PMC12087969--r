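test_that("pure-birth degenerate rates give no fossil tips and extant ages 0", {
  cfg <- sim_config(seed = 7, n_extant = 12, n_fossil = 0, birth_rate = 0.2,
                    death_rate = 0, fossil_sampling_rate = 0, root_age = 25)
  tr <- simulate_fbd_tree(cfg)
  ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
  expect_equal(ape::Ntip(tr), 12)
  expect_true(all(ages < 1e-6))
  expect_identical(attr(tr, "n_fossil_samples"), 0L)
})

test_that("tree simulation is reproducible under a fixed seed", {
  cfg <- sim_config(seed = 11, n_extant = 10, n_fossil = 5, root_age = 60,
                    birth_rate = 0.08, death_rate = 0.02,
                    fossil_sampling_rate = 0.002)
  n1 <- ape::write.tree(simulate_fbd_tree(cfg))
  n2 <- ape::write.tree(simulate_fbd_tree(cfg))
  expect_identical(n1, n2)
})

test_that("fossil-tip count matches the Poisson expectation on realized trees", {
  psi <- 0.01
  counts <- numeric(200)
  expect_n <- numeric(200)
  for (i in seq_len(200)) {
    cfg <- sim_config(seed = 1000 + i, n_extant = 2, n_fossil = 5,
                      birth_rate = 0.1, death_rate = 0.05,
                      fossil_sampling_rate = psi, root_age = 30)
    tr <- simulate_fbd_tree(cfg)
    counts[i] <- attr(tr, "n_fossil_samples")
    expect_n[i] <- psi * attr(tr, "complete_length")
  }
  diffs <- counts - expect_n
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 1e-9)
})

test_that("BM simulation: degenerate variance, reproducibility, node truth", {
  tr <- toy_tree()
  v <- simulate_bm_trait(tr, 0, root_value = 3.5, seed = 1)
  expect_true(all(v == 3.5))
  expect_length(v, ape::Ntip(tr) + tr$Nnode)
  expect_identical(simulate_bm_trait(tr, 0.2, 1, seed = 9),
                   simulate_bm_trait(tr, 0.2, 1, seed = 9))
})

test_that("sister-tip covariance matches sigma2 x shared path length", {
  tr <- toy_tree() # a,b share depth 1 from root
  sigma2 <- 0.8
  reps <- 1000
  ab <- t(vapply(seq_len(reps), function(i) {
    v <- simulate_bm_trait(tr, sigma2, 0, seed = 5000 + i)
    v[c("a", "b")]
  }, numeric(2)))
  cv <- cov(ab[, 1], ab[, 2])
  truth <- sigma2 * 1
  se <- sigma2 * sqrt(2 / reps) # rough MC error scale
  expect_lt(abs(cv - truth), 4 * se)
})

test_that("climate history: cooling construction and gradient sign", {
  cl0 <- simulate_climate_history(5, cooling_slope = 0, seed = 2,
                                  noise_sd = 0)
  means <- vapply(cl0, slice_global_mean, numeric(1))
  expect_equal(max(means) - min(means), 0, tolerance = 1e-12)
  cl <- simulate_climate_history(18, cooling_slope = 0.05, seed = 2,
                                 noise_sd = 0)
  m <- vapply(cl, slice_global_mean, numeric(1))
  expect_equal(m[1] - m[18], 0.05 * 170, tolerance = 1e-9)
  for (s in cl[c(1, 9, 18)]) {
    eq <- which.min(abs(s$lat))
    pole <- which.max(abs(s$lat))
    expect_gt(mean(s$vars$MAT[eq, ]), mean(s$vars$MAT[pole, ]))
  }
})

test_that("occurrences: uniform suitability gives uniform cells, degenerate
          suitability concentrates, env vectors copy the cell", {
  cfg <- sim_config(seed = 3, n_extant = 8, n_fossil = 4, root_age = 40,
                    birth_rate = 0.09, death_rate = 0.02)
  tr <- simulate_fbd_tree(cfg)
  cl <- simulate_climate_history(5, 0.05, seed = 3)
  # uniformity: chi-square on cell counts passes at alpha = .01 mostly
  ncell <- length(cl[[1]]$vars$MAT)
  pass <- 0L
  for (r in 1:20) {
    occ <- simulate_occurrences(tr, cl, n_per_slice = 400,
                                suitability = function(env) rep(1, nrow(env)),
                                seed = 100 + r)
    o1 <- occ[occ$age_ma == occ$age_ma[1], ]
    counts <- table(factor(paste(o1$lon, o1$lat),
                           levels = unique(paste(
                             rep(cl[[1]]$lon, each = length(cl[[1]]$lat)),
                             rep(cl[[1]]$lat, length(cl[[1]]$lon))))))
    p <- suppressWarnings(stats::chisq.test(as.numeric(counts))$p.value)
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 17)
  # all mass in one cell
  occ1 <- simulate_occurrences(tr, cl, n_per_slice = 30,
                               suitability = function(env) {
                                 w <- rep(0, nrow(env)); w[17] <- 1; w
                               }, seed = 5)
  expect_equal(nrow(unique(occ1[c("lon", "lat")])), 1L)
  # env bookkeeping identity
  occ <- simulate_occurrences(tr, cl, n_per_slice = 10, seed = 6)
  s1 <- cl[[which(vapply(cl, `[[`, numeric(1), "age") == occ$age_ma[1])]]
  i_lat <- match(occ$lat[1], s1$lat); i_lon <- match(occ$lon[1], s1$lon)
  for (v in names(s1$vars))
    expect_identical(occ[[v]][1], s1$vars[[v]][i_lat, i_lon])
  # empty suitable region fails loudly
  expect_error(simulate_occurrences(tr, cl, 5,
                                    suitability = function(env)
                                      rep(0, nrow(env)), seed = 1),
               "empty suitable region")
})

test_that("scenario invariants hold and fixtures round-trip as text", {
  cfg <- sim_config(seed = 5, n_extant = 8, n_fossil = 5, root_age = 80,
                    birth_rate = 0.06, death_rate = 0.02, n_realms = 4)
  scen <- simulate_scenario(cfg, n_per_slice = 8, n_atmo = 10)
  expect_true(all(scen$occurrences$taxon %in% scen$tree$tip.label))
  expect_lte(max(scen$occurrences$age_ma), scen$climate[[1]]$age)
  d <- file.path(tempdir(), "scen_fixture")
  write_scenario(scen, d)
  tr2 <- ape::read.tree(file.path(d, "tree.nwk"))
  expect_identical(sort(tr2$tip.label), sort(scen$tree$tip.label))
  g <- read_ascii_grid(list.files(d, "climate_.*_MAT", full.names = TRUE)[1])
  expect_equal(dim(g$m), dim(scen$climate[[1]]$vars$MAT))
  unlink(d, recursive = TRUE)
})

test_that("range history plants more dispersal on high-modifier branches", {
  cfg <- sim_config(seed = 9, n_extant = 20, n_fossil = 0, root_age = 80,
                    birth_rate = 0.06, death_rate = 0,
                    fossil_sampling_rate = 0, n_realms = 4)
  tr <- simulate_fbd_tree(cfg)
  h <- default_realm_history(root_age(tr), 4)
  hi <- simulate_range_history(tr, h, d = 0.02, e = 0.005, seed = 2,
                               branch_modifier = rep(5, nrow(tr$edge)))
  lo <- simulate_range_history(tr, h, d = 0.02, e = 0.005, seed = 2,
                               branch_modifier = rep(0.2, nrow(tr$edge)))
  expect_gt(nrow(hi$events), nrow(lo$events))
  expect_true(all(hi$tip_ranges != ""))
})
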