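# Phylogenetic signal and evolutionary-model fitting on dated trees with
# non-contemporaneous (fossil) tips. Everything works from the Brownian
# shared-path covariance matrix, so ultrametricity is never assumed.

#' Pagel's lambda with a data-dependent upper bound
#'
#' ML estimate of lambda by maximizing the Brownian likelihood on the
#' lambda-transformed covariance (off-diagonal shared paths scaled by
#' lambda, tip variances untouched). The search interval is \[0,
#' lambda_max\], where lambda_max is the largest lambda keeping the
#' transformed covariance positive definite - deliberately allowing
#' lambda > 1 on non-ultrametric trees. The p-value is a likelihood-ratio
#' test against lambda = 0 (no signal).
#'
#' @param tree dated ape `phylo`.
#' @param x named trait vector over tips.
#' @return list: `lambda`, `logL`, `logL0`, `p`, `sigma2`, `mu`,
#'   `lambda_max`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- match_tips(tree, x)
  n <- length(x)
  stopifnot(n >= 4)
  C <- ape::vcv(tree)
  D <- diag(C)
  C_l <- function(l) { M <- l * C; diag(M) <- D; M }
  feasible <- function(l) !is.null(tryCatch(chol(C_l(l)),
                                            error = function(e) NULL))
  hi <- 1
  while (feasible(hi * 1.5) && hi < 64) hi <- hi * 1.5
  lo_b <- hi; hi_b <- hi * 1.5
  for (i in 1:40) { # bisect the PD boundary
    mid <- (lo_b + hi_b) / 2
    if (feasible(mid)) lo_b <- mid else hi_b <- mid
  }
  lambda_max <- lo_b * (1 - 1e-6)
  f <- function(l) bm_loglik_C(C_l(l), x)$logL
  # the profile can be multimodal on small trees: coarse scan, then refine
  grid <- seq(0, lambda_max, length.out = 41)
  gl <- vapply(grid, f, numeric(1))
  i <- which.max(gl)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- optimize(f, bracket, maximum = TRUE, tol = 1e-7)
  cand <- c(opt$maximum, 0, lambda_max)
  lls <- vapply(cand, f, numeric(1))
  lambda <- cand[which.max(lls)]
  fit <- bm_loglik_C(C_l(lambda), x)
  logL0 <- f(0)
  p <- pchisq(2 * (fit$logL - logL0), df = 1, lower.tail = FALSE)
  list(lambda = lambda, logL = fit$logL, logL0 = logL0, p = p,
       sigma2 = fit$sigma2, mu = fit$mu, lambda_max = lambda_max)
}

#' Blomberg's K with a tip-shuffling permutation test
#'
#' K compares the observed ratio of the non-phylogenetic to the phylogenetic
#' mean squared error, MSE0/MSE (deviations from the GLS root estimate),
#' with its Brownian expectation `(tr(C) - n / sum(C^-1)) / (n - 1)`. The
#' p-value shuffles trait values across tips; with the default 10,000
#' permutations the smallest reportable p is 1e-4.
#'
#' @param tree dated ape `phylo`.
#' @param x named trait vector over tips (non-constant).
#' @param n_perm permutation count (default 10,000).
#' @param seed integer seed for the permutations.
#' @return list: `K`, `p`, `obs_ratio`, `expected_ratio`, `n_perm`.
#' @export
blomberg_k <- function(tree, x, n_perm = 10000L, seed = 1L) {
  x <- match_tips(tree, x)
  if (sd(x) == 0) stop("K is undefined for a constant trait")
  n <- length(x)
  C <- ape::vcv(tree)
  Ci <- solve(C)
  Ci1 <- drop(Ci %*% rep(1, n))
  s <- sum(Ci1)
  ratio_vec <- function(X) { # X: n x B matrix of trait columns
    a <- drop(crossprod(Ci1, X)) / s
    Xc <- sweep(X, 2L, a)
    CXc <- Ci %*% Xc
    colSums(Xc^2) / colSums(Xc * CXc)
  }
  obs <- ratio_vec(matrix(x, ncol = 1))
  expected <- (sum(diag(C)) - n / s) / (n - 1)
  K <- obs / expected
  set.seed(seed)
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    chunk <- 2000L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      Xp <- vapply(seq_len(b), function(i) x[sample.int(n)], numeric(n))
      exceed <- exceed + sum(ratio_vec(Xp) >= obs)
      done <- done + b
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(K = unname(K), p = p, obs_ratio = unname(obs),
       expected_ratio = expected, n_perm = n_perm)
}

# Covariance builders for the evolutionary-model suite. S = shared-path
# matrix (BM vcv), Dg = its diagonal (tip depths), Tm = max depth.
.evo_cov <- list(
  WN = function(S, Dg, Tm, th) diag(length(Dg)),
  BM = function(S, Dg, Tm, th) S,
  LB = function(S, Dg, Tm, th) { M <- th * S; diag(M) <- Dg; M },
  KP = NULL, # needs branch lengths, handled specially
  DT = function(S, Dg, Tm, th) Tm^(1 - th) * S^th,
  EB = function(S, Dg, Tm, th) (exp(th * S) - 1) / th,
  OU = function(S, Dg, Tm, th) {
    Dmat <- outer(Dg, Dg, "+") - 2 * S
    exp(-th * Dmat) * (1 - exp(-2 * th * S)) / (2 * th)
  },
  RT = function(S, Dg, Tm, th) S + th * S^2 / (2 * Tm)
)

.evo_bounds <- list(LB = c(0, 1), # upper replaced by feasible max
                    DT = c(1e-3, 3), EB = c(-1, -1e-6),
                    OU = c(1e-6, 10), RT = c(-0.99, 5))

#' Fit the nine-model evolutionary suite
#'
#' ML fits of white noise (WN), Brownian motion (BM), rate trend (RT: rate
#' changing linearly through time), mean trend (MT: BM with drift,
#' identifiable thanks to fossil tips), delta (DT), lambda (LB), kappa (KP),
#' early burst (EB) and Ornstein-Uhlenbeck (OU), compared by AICc. The
#' root mean and sigma2 are profiled analytically; each remaining parameter
#' is optimized on a bounded interval. A model whose optimizer fails is
#' reported as a failed row; the table is still returned.
#'
#' @param tree dated ape `phylo`.
#' @param x named trait vector over tips (n >= 5).
#' @return data.frame, one row per model: `logL`, `k`, `AICc`, `param`
#'   (extra parameter estimate), `sigma2`, `mu`, `delta_AICc`.
#' @export
fit_evo_models <- function(tree, x) {
  x <- match_tips(tree, x)
  n <- length(x)
  stopifnot(n >= 5)
  S <- ape::vcv(tree)
  Dg <- diag(S); Tm <- max(Dg)
  aicc <- function(logL, k) -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  rows <- list()
  add <- function(model, logL, k, param = NA_real_, sigma2 = NA_real_,
                  mu = NA_real_) {
    rows[[model]] <<- data.frame(model = model, logL = logL, k = k,
                                 AICc = aicc(logL, k), param = param,
                                 sigma2 = sigma2, mu = mu)
  }
  safe <- function(model, expr) {
    tryCatch(expr, error = function(e)
      add(model, NA_real_, NA_integer_))
  }
  for (m in c("WN", "BM")) {
    C <- .evo_cov[[m]](S, Dg, Tm, NA)
    fit <- bm_loglik_C(C, x)
    add(m, fit$logL, 2L, sigma2 = fit$sigma2, mu = fit$mu)
  }
  for (m in c("LB", "DT", "EB", "OU", "RT")) {
    safe(m, {
      b <- .evo_bounds[[m]]
      if (m == "LB") {
        feasible <- function(l) {
          M <- l * S; diag(M) <- Dg
          !is.null(tryCatch(chol(M), error = function(e) NULL))
        }
        hi <- 1
        while (feasible(hi * 1.5) && hi < 64) hi <- hi * 1.5
        b <- c(0, hi * (1 - 1e-6))
      }
      f <- function(th) bm_loglik_C(.evo_cov[[m]](S, Dg, Tm, th), x)$logL
      opt <- optimize(f, b, maximum = TRUE, tol = 1e-6)
      cand <- c(opt$maximum, b[1] + 1e-9, b[2] - 1e-9)
      lls <- vapply(cand, f, numeric(1))
      th <- cand[which.max(lls)]
      fit <- bm_loglik_C(.evo_cov[[m]](S, Dg, Tm, th), x)
      add(m, fit$logL, 3L, param = th, sigma2 = fit$sigma2, mu = fit$mu)
    })
  }
  safe("KP", {
    tr2 <- tree
    f <- function(kp) {
      tr2$edge.length <- tree$edge.length^kp
      bm_loglik_C(ape::vcv(tr2), x)$logL
    }
    opt <- optimize(f, c(1e-3, 3), maximum = TRUE, tol = 1e-6)
    kp <- opt$maximum
    tr2$edge.length <- tree$edge.length^kp
    fit <- bm_loglik_C(ape::vcv(tr2), x)
    add("KP", fit$logL, 3L, param = kp, sigma2 = fit$sigma2, mu = fit$mu)
  })
  safe("MT", {
    if (sd(Dg) < 1e-8 * Tm) stop("tip depths constant: trend unidentifiable")
    X <- cbind(1, Dg)
    g <- gls_fit(X, x, S)
    s2_ml <- g$rss / n
    logdet <- 2 * sum(log(diag(chol(S))))
    logL <- -0.5 * n * log(2 * pi * s2_ml) - 0.5 * logdet - 0.5 * n
    add("MT", logL, 3L, param = g$coefficients[2], sigma2 = s2_ml,
        mu = g$coefficients[1])
  })
  tab <- do.call(rbind, rows[c("WN", "BM", "RT", "MT", "DT", "LB", "KP",
                               "EB", "OU")])
  rownames(tab) <- NULL
  tab$delta_AICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab
}

#' Phylogenetic generalized least squares under Brownian correlation
#'
#' @param tree dated ape `phylo`.
#' @param response named numeric vector over tips.
#' @param predictors data.frame/matrix of predictors (rows = tips, in tree
#'   tip order or named); factors/characters are model-matrix expanded.
#' @return list: `coefficients` table (estimate, se, t, p), `sigma2`, `df`.
#' @export
pgls <- function(tree, response, predictors) {
  y <- match_tips(tree, response)
  Xdf <- as.data.frame(predictors)
  if (!is.null(rownames(Xdf)) &&
      all(tree$tip.label %in% rownames(Xdf)))
    Xdf <- Xdf[tree$tip.label, , drop = FALSE]
  X <- stats::model.matrix(~ ., data = Xdf)
  if (qr(X)$rank < ncol(X)) stop("collinear predictors")
  C <- ape::vcv(tree)
  g <- gls_fit(X, y, C)
  coefs <- data.frame(estimate = g$coefficients, se = g$se, t = g$t,
                      p = g$p, row.names = colnames(X))
  list(coefficients = coefs, sigma2 = g$sigma2, df = g$df)
}
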