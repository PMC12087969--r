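# Dispersal frequency vs wing length: mean-split binarization of the per-My
# dispersal-event series, a two-regime hidden Markov model with Gaussian
# wing-length emissions (Baum-Welch), simulation-based logistic regression
# with threshold extraction, kernel densities, and the wing-shape group
# contrasts (Welch t and exact rank-sum).

#' Binarize a dispersal-event series at its mean
#'
#' 1 ("frequent") where the count strictly exceeds the series mean, else 0.
#'
#' @param events numeric vector of per-bin dispersal-event counts (>= 2).
#' @return integer 0/1 vector.
#' @export
binarize_series <- function(events) {
  stopifnot(length(events) >= 2)
  as.integer(events > mean(events))
}

#' Forward log-likelihood of the regime HMM
#'
#' Emissions are Gaussian in wing length; if the model carries
#' `regime_prob` and a regime sequence is supplied, each state also emits
#' the observed 0/1 dispersal category with a Bernoulli probability.
#'
#' @param model an `hmm_model`.
#' @param obs numeric wing-length sequence.
#' @param regimes optional 0/1 category sequence (same length).
#' @return log-likelihood (scaled forward algorithm).
#' @export
hmm_forward <- function(model, obs, regimes = NULL) {
  .hmm_forward_backward(model, obs, regimes)$logL
}

.hmm_emission <- function(model, obs, regimes = NULL) {
  B <- vapply(seq_along(model$means), function(s)
    dnorm(obs, model$means[s], model$sds[s]), numeric(length(obs)))
  if (!is.null(regimes) && !is.null(model$regime_prob)) {
    for (s in seq_along(model$means)) {
      rp <- model$regime_prob[s]
      B[, s] <- B[, s] * ifelse(regimes == 1L, rp, 1 - rp)
    }
  }
  B
}

.hmm_forward_backward <- function(model, obs, regimes = NULL) {
  Tn <- length(obs)
  S <- length(model$means)
  B <- .hmm_emission(model, obs, regimes)        # T x S
  A <- model$transition
  alpha <- matrix(0, Tn, S); beta <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- model$initial * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  for (t in 2:Tn) {
    a <- drop(alpha[t - 1L, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[Tn, ] <- 1
  for (t in (Tn - 1L):1L) {
    beta[t, ] <- drop(A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, gamma = gamma, c = cvec, B = B,
       logL = sum(log(cvec)))
}

#' Fit a two-regime hidden Markov model by Baum-Welch
#'
#' Hidden states are the dispersal regimes (infrequent = 1, frequent = 2).
#' Each state emits the observed 0/1 dispersal category (Bernoulli) jointly
#' with a Gaussian wing length, integrating the categorized dispersal data
#' with the wing-length series and anchoring the hidden states to the
#' regimes. The EM is initialized from the observed binarized regimes
#' (means/sds per category, transition counts) and iterated to a
#' log-likelihood tolerance; the EM log-likelihood is asserted
#' non-decreasing at every step. Zero-variance clusters are floored with a
#' warning.
#'
#' @param regimes 0/1 vector from [binarize_series()] (initialization).
#' @param wl numeric wing-length series, same length (>= 10).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @param var_floor lower bound on emission SDs.
#' @return an `hmm_model`: `transition` (rows sum to 1), `means`, `sds`,
#'   `initial`, `logL`, `logL_trace`, `n_iter`.
#' @export
fit_hmm <- function(regimes, wl, tol = 1e-8, max_iter = 500L,
                    var_floor = 1e-3) {
  stopifnot(length(regimes) == length(wl), length(wl) >= 10)
  r <- as.integer(regimes) + 1L            # states 1/2
  Tn <- length(wl)
  means <- vapply(1:2, function(s)
    if (any(r == s)) mean(wl[r == s]) else mean(wl) + (s - 1.5), numeric(1))
  sds <- vapply(1:2, function(s)
    if (sum(r == s) > 1) sd(wl[r == s]) else sd(wl), numeric(1))
  sds[!is.finite(sds) | sds < var_floor] <- max(var_floor, sd(wl) / 4)
  trans <- matrix(1, 2, 2)
  for (t in 2:Tn) trans[r[t - 1L], r[t]] <- trans[r[t - 1L], r[t]] + 1
  A <- trans / rowSums(trans)
  init <- c(mean(r == 1L), mean(r == 2L))
  init <- (init + 1e-3) / sum(init + 1e-3)
  reg <- as.integer(regimes)
  rp <- pmin(pmax(c(mean(reg[r == 1L] %in% 1L),
                    if (any(r == 2L)) mean(reg[r == 2L] %in% 1L) else 0.95),
                  0.02, na.rm = TRUE), 0.98)
  model <- structure(list(transition = A, means = means, sds = sds,
                          initial = init, regime_prob = rp),
                     class = "hmm_model")
  trace <- numeric(0)
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- .hmm_forward_backward(model, wl, reg)
    trace <- c(trace, fb$logL)
    if (it > 1 && fb$logL < trace[it - 1L] - 1e-6)
      stop("EM log-likelihood decreased: internal error")
    if (it > 1 && fb$logL - trace[it - 1L] < tol) break
    # M step
    g <- fb$gamma
    xi_num <- matrix(0, 2, 2)
    for (t in 1:(Tn - 1L)) {
      x <- (fb$alpha[t, ] %o% (fb$B[t + 1L, ] * fb$beta[t + 1L, ])) *
        model$transition / fb$c[t + 1L]
      xi_num <- xi_num + x
    }
    A <- xi_num / rowSums(xi_num)
    means <- colSums(g * wl) / colSums(g)
    sds <- sqrt(colSums(g * (outer(wl, means, "-")^2)) / colSums(g))
    if (any(sds < var_floor)) {
      sds <- pmax(sds, var_floor)
      floored <- TRUE
    }
    model$transition <- A; model$means <- means; model$sds <- sds
    model$regime_prob <- pmin(pmax(colSums(g * reg) / colSums(g),
                                   1e-3), 1 - 1e-3)
    model$initial <- (g[1L, ] + 1e-12) / sum(g[1L, ] + 1e-12)
  }
  if (floored) warning("degenerate emission cluster: variance floored")
  model$logL <- trace[length(trace)]
  model$logL_trace <- trace
  model$n_iter <- length(trace)
  model
}

#' Simulate one (regime, wing-length) sequence from an HMM
#'
#' The `state` column is the emitted dispersal category: Bernoulli from
#' `regime_prob` when the model carries it, otherwise the hidden state
#' itself.
#'
#' @param model an `hmm_model`.
#' @param n sequence length.
#' @return data.frame with `state` (0/1) and `wl`.
#' @export
simulate_hmm <- function(model, n) {
  s <- integer(n)
  s[1L] <- sample(1:2, 1L, prob = model$initial)
  for (t in 2:n) s[t] <- sample(1:2, 1L, prob = model$transition[s[t - 1L], ])
  emitted <- if (!is.null(model$regime_prob))
    rbinom(n, 1L, model$regime_prob[s]) else s - 1L
  data.frame(state = emitted, wl = rnorm(n, model$means[s], model$sds[s]))
}

#' Simulated logistic regression and wing-length threshold
#'
#' Simulates `n_iter` (regime, wing length) sequences from the fitted HMM,
#' pools them, regresses regime on wing length by logistic regression
#' (IRLS via `glm`), and extracts the P = 0.5 crossing
#' `threshold = -b0 / b1` in mm. Kernel density estimates (Silverman
#' bandwidth) of wing length per regime are returned for both the raw and
#' the simulated data. Perfect separation is detected and flagged; the
#' threshold then falls back to the midpoint of the separating gap.
#'
#' @param model an `hmm_model`.
#' @param n_iter number of simulated sequences (default 10,000).
#' @param seq_length length of each sequence (defaults to 50).
#' @param seed integer seed.
#' @param raw optional data.frame(state, wl) of the observed series for the
#'   raw-data densities.
#' @return a `threshold_result`: `wl_threshold`, `coefficients` (b0, b1),
#'   `separation` flag, `kde_sim`, `kde_raw` (per-regime densities).
#' @export
simulate_and_regress <- function(model, n_iter = 10000L, seq_length = 50L,
                                 seed = 1L, raw = NULL) {
  set.seed(seed)
  # pooling n_iter simulated sequences = one long simulation restarted at
  # the initial distribution; simulate in blocks for speed
  sims <- vector("list", n_iter)
  for (i in seq_len(n_iter)) sims[[i]] <- simulate_hmm(model, seq_length)
  pooled <- do.call(rbind, sims)
  sep <- FALSE
  b <- tryCatch({
    fit <- suppressWarnings(glm(state ~ wl, binomial(), data = pooled))
    if (!fit$converged || max(abs(coef(fit))) > 1e3) sep <- TRUE
    coef(fit)
  }, error = function(e) { sep <<- TRUE; c(0, 0) })
  if (sep) {
    hi <- pooled$wl[pooled$state == 1L]; lo <- pooled$wl[pooled$state == 0L]
    thr <- if (length(hi) && length(lo)) (min(hi) + max(lo)) / 2 else NA_real_
  } else {
    thr <- -b[1] / b[2]
  }
  kde_of <- function(df) {
    out <- list()
    for (s in 0:1) {
      w <- df$wl[df$state == s]
      if (length(w) >= 2 && sd(w) > 0)
        out[[as.character(s)]] <- density(w, bw = "nrd0")
    }
    out
  }
  structure(list(wl_threshold = unname(thr),
                 coefficients = c(b0 = unname(b[1]), b1 = unname(b[2])),
                 separation = sep, n_iter = n_iter,
                 kde_sim = kde_of(pooled),
                 kde_raw = if (!is.null(raw)) kde_of(raw) else NULL),
            class = "threshold_result")
}

# Exact two-sided rank-sum p-value by enumeration over all assignments.
.ranksum_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(n, n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Wing-shape group contrasts: Welch t and rank-sum
#'
#' Welch's unequal-variance t test plus the Wilcoxon-Mann-Whitney rank-sum
#' test; for small samples (both groups <= 10) the rank-sum null is the
#' exact enumeration over all group assignments (ties handled by average
#' ranks), otherwise the normal approximation with tie correction. Two
#' zero-variance groups with equal means return p = 1 by convention.
#'
#' @param values_a,values_b numeric group samples (Welch needs >= 2 each).
#' @return list: `welch` (statistic, df, p), `ranksum` (W, p, exact flag),
#'   `difference` of means.
#' @export
group_contrast <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  diff_means <- mean(values_a) - mean(values_b)
  if (sd(c(values_a, values_b)) == 0) {
    return(list(welch = list(statistic = 0, df = NA, p = 1),
                ranksum = list(W = NA, p = 1, exact = TRUE),
                difference = 0))
  }
  welch <- if (length(values_a) >= 2 && length(values_b) >= 2 &&
               (sd(values_a) > 0 || sd(values_b) > 0)) {
    tt <- t.test(values_a, values_b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  } else list(statistic = NA, df = NA, p = NA)
  n <- length(values_a) + length(values_b)
  if (length(values_a) <= 10 && length(values_b) <= 10) {
    p <- .ranksum_exact_p(values_a, values_b)
    exact <- TRUE
  } else {
    wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE,
                                       correct = TRUE))
    p <- wt$p.value
    exact <- FALSE
  }
  r <- rank(c(values_a, values_b))
  W <- sum(r[seq_along(values_a)]) -
    length(values_a) * (length(values_a) + 1) / 2
  list(welch = welch, ranksum = list(W = W, p = p, exact = exact),
       difference = diff_means)
}
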