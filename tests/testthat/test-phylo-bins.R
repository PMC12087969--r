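test_that("branch means: constant trait, hand-integrated two-bin branch,
          bins beyond the root flagged", {
  tr <- toy_tree()
  vals <- setNames(rep(7, 4 + tr$Nnode), node_labels(tr))
  sch <- uniform_bins(2, 1)
  bm <- branch_bin_means(tr, vals, sch)
  expect_true(all(abs(bm$mean - 7) < 1e-12))
  # single branch 2 -> 0 Ma with endpoint values 0 (old) and 10 (young):
  # linear segment, bin [2,1): mean 2.5, bin [1,0): mean 7.5
  t2 <- ape::read.tree(text = "(a:2,b:2);")
  attr(t2, "root_age") <- 2
  v2 <- c(a = 10, b = 10, node3 = 0)
  names(v2)[3] <- node_labels(t2)[3]
  bm2 <- branch_bin_means(t2, v2, uniform_bins(2, 1))
  expect_equal(bm2$mean, c(2.5, 7.5))
  sch4 <- structure(list(edges = c(4, 3, 2, 1, 0),
                         labels = paste(4:1, 3:0, sep = "-"),
                         scheme = "uniform"), class = "bin_scheme")
  bm3 <- branch_bin_means(t2, v2, sch4)
  expect_true(all(is.na(bm3$mean[1:2])))  # beyond the root: flagged NA
  expect_equal(bm3$total_length[1:2], c(0, 0))
})

test_that("niche thresholds: constant trait, exhaustive toy evaluation,
          monotone under a more extreme tip", {
  tr <- toy_tree()
  vals <- setNames(rep(3, 4 + tr$Nnode), node_labels(tr))
  th <- niche_thresholds_by_bin(tr, vals, uniform_bins(2, 1))
  occupied <- !is.na(th$min)
  expect_true(all(th$min[occupied] == 3 & th$max[occupied] == 3))
  # toy 4-tip: oracle evaluates every segment endpoint in each bin
  set.seed(1)
  v <- setNames(c(1, 5, -2, 3, 0, 2, 4), node_labels(tr))
  sch <- uniform_bins(2, 1)
  th2 <- niche_thresholds_by_bin(tr, v, sch)
  ages <- node_ages(tr)
  oracle_min <- rep(NA_real_, 2); oracle_max <- rep(NA_real_, 2)
  for (ei in seq_len(nrow(tr$edge))) {
    p <- tr$edge[ei, 1]; ch <- tr$edge[ei, 2]
    ap <- ages[p]; ac <- ages[ch]
    vp <- v[p]; vc <- v[ch]
    for (b in 1:2) {
      hi <- min(ap, sch$edges[b]); lo <- max(ac, sch$edges[b + 1])
      if (hi < lo) next
      at <- function(t) if (ap == ac) vc else
        vc + (vp - vc) * (t - ac) / (ap - ac)
      vals_b <- c(at(hi), at(lo))
      oracle_min[b] <- min(oracle_min[b], vals_b, na.rm = TRUE)
      oracle_max[b] <- max(oracle_max[b], vals_b, na.rm = TRUE)
    }
  }
  expect_equal(th2$min, oracle_min)
  expect_equal(th2$max, oracle_max)
  # adding a more extreme tip can only widen thresholds
  v3 <- v; v3["c"] <- -10
  th3 <- niche_thresholds_by_bin(tr, v3, sch)
  expect_true(all(th3$min <= th2$min + 1e-12, na.rm = TRUE))
  expect_true(all(th3$max >= th2$max - 1e-12, na.rm = TRUE))
})

test_that("LTT: two tips step 1 -> 2 at the root; counts stay >= 1;
          pure-birth slope recovers the birth rate", {
  t2 <- ape::read.tree(text = "(a:3,b:3);")
  attr(t2, "root_age") <- 3
  lt <- ltt(t2)
  expect_equal(lt$age, 3)
  expect_equal(lt$lineages, 2L)
  set.seed(2)
  tr <- pb_tree(200, birth = 0.1)
  lt2 <- ltt(tr)
  expect_true(all(lt2$lineages >= 1))
  expect_true(all(diff(lt2$lineages) >= 0))
  tmax <- max(ape::node.depth.edgelength(tr))
  times <- tmax - lt2$age
  fit <- lm(log(lt2$lineages) ~ times)
  expect_lt(abs(coef(fit)[2] - 0.1) / 0.1, 0.2)
})

test_that("LTT with extinct-lineage counting decrements at fossil deaths", {
  cfg <- sim_config(seed = 31, n_extant = 10, n_fossil = 8, root_age = 50,
                    birth_rate = 0.1, death_rate = 0.04,
                    fossil_sampling_rate = 0.02)
  tr <- simulate_fbd_tree(cfg)
  lt <- ltt(tr, count_extinct = TRUE)
  expect_true(any(diff(lt$lineages) < 0))
  expect_true(all(lt$lineages >= 1))
})

test_that("rate proxy: flat under constant-rate BM, declining under an
          early burst, single bin equals the mean squared contrast", {
  flat_ok <- 0L
  for (r in 1:20) {
    set.seed(50 + r)
    tr <- pb_tree(48)
    x <- simulate_bm_trait(tr, 0.5, 0, seed = 150 + r)[tr$tip.label]
    tmax <- max(ape::node.depth.edgelength(tr))
    sch <- uniform_bins(tmax, tmax / 5)
    rp <- rate_through_time_proxy(tr, x, sch, n_boot = 50, seed = r)
    ok <- !is.na(rp$rate) & rp$n >= 2
    if (sum(ok) < 3) { flat_ok <- flat_ok + 1L; next }
    ft <- lm(rate ~ bin, data = rp[ok, ])
    ci <- confint(ft)["bin", ]
    if (ci[1] <= 0 && ci[2] >= 0) flat_ok <- flat_ok + 1L
  }
  expect_gte(flat_ok, 18L)
  # early burst: simulate on an EB-rescaled tree, measure on the original
  neg <- 0L
  for (r in 1:20) {
    set.seed(250 + r)
    tr <- pb_tree(48)
    dep <- ape::node.depth.edgelength(tr)
    rr <- -4 / max(dep)
    tr_eb <- tr
    t1 <- dep[tr$edge[, 1]]; t2 <- dep[tr$edge[, 2]]
    tr_eb$edge.length <- (exp(rr * t2) - exp(rr * t1)) / rr
    x <- simulate_bm_trait(tr_eb, 0.5, 0, seed = 350 + r)[tr$tip.label]
    tmax <- max(dep)
    sch <- uniform_bins(tmax, tmax / 5)
    rp <- rate_through_time_proxy(tr, x, sch, n_boot = 10, seed = r)
    ok <- !is.na(rp$rate)
    # bins are ordered old -> young: early burst means rate falls with bin
    if (cor(rp$bin[ok], rp$rate[ok], method = "spearman") < 0)
      neg <- neg + 1L
  }
  expect_gte(neg, 18L)
  set.seed(77)
  tr <- pb_tree(30)
  x <- simulate_bm_trait(tr, 1, 0, seed = 78)[tr$tip.label]
  tmax <- max(ape::node.depth.edgelength(tr))
  one <- structure(list(edges = c(tmax, 0), labels = "all",
                        scheme = "uniform"), class = "bin_scheme")
  rp1 <- rate_through_time_proxy(tr, x, one, n_boot = 10, seed = 1)
  expect_equal(rp1$rate, mean(ape::pic(x, tr)^2), tolerance = 1e-12)
})
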