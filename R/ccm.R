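# Convergent cross-mapping between a forcing series (e.g. global mean
# annual temperature) and a biological response series (NB, NP, LTT, NDR),
# plus plain correlation tests. Causation x -> y is inferred when y's
# time-delay embedding cross-maps x with a skill that rises with library
# size and beats a phase-surrogate null.

#' CCM configuration
#'
#' @param E embedding dimension (>= 2).
#' @param tau embedding lag (>= 1).
#' @param library_sizes increasing vector of library sizes; `NULL` picks a
#'   spread from the minimum feasible to the maximum.
#' @param n_samples random library draws per size.
#' @param n_surrogates phase-randomized surrogates for the p-value.
#' @param null_quantile surrogate-skill quantile the final skill must beat
#'   for the `convergent` flag (the stated null level).
#' @param min_skill minimum final skill for convergence: a cross-map
#'   explaining under `min_skill^2` of the variance is never called
#'   convergent, whatever the surrogates say (default 0.2, the conventional
#'   noise-level benchmark).
#' @param seed integer seed.
#' @return a `ccm_config` list.
#' @export
ccm_config <- function(E = 2L, tau = 1L, library_sizes = NULL,
                       n_samples = 50L, n_surrogates = 100L,
                       null_quantile = 0.99, min_skill = 0.2, seed = 1L) {
  stopifnot(E >= 2, tau >= 1, null_quantile > 0, null_quantile < 1,
            min_skill >= 0)
  structure(list(E = as.integer(E), tau = as.integer(tau),
                 library_sizes = library_sizes,
                 n_samples = as.integer(n_samples),
                 n_surrogates = as.integer(n_surrogates),
                 null_quantile = null_quantile, min_skill = min_skill,
                 seed = as.integer(seed)),
            class = "ccm_config")
}

#' Heuristic embedding parameters
#'
#' tau from the first lag where the autocorrelation drops below 1/e
#' (capped at 5); E from a simplex-projection sweep (the E in 2..6 with the
#' best univariate self-prediction skill).
#'
#' @param series numeric series.
#' @return list with `E` and `tau`.
#' @export
select_embedding <- function(series) {
  ac <- drop(stats::acf(series, lag.max = 10, plot = FALSE)$acf)[-1]
  tau <- which(ac < exp(-1))
  tau <- if (length(tau)) min(tau[1], 5L) else 1L
  best_E <- 2L; best_s <- -Inf
  for (E in 2:6) {
    emb <- .embed_series(series, E, tau)
    if (is.null(emb) || nrow(emb$M) < 2 * (E + 2)) next
    # leave-one-out self prediction one step ahead
    idx <- seq_len(nrow(emb$M) - 1L)
    pred <- .simplex_predict(emb$M[idx, , drop = FALSE],
                             series[emb$t[idx] + 1L],
                             emb$M[idx, , drop = FALSE], exclude_self = TRUE)
    s <- suppressWarnings(cor(pred, series[emb$t[idx] + 1L],
                              use = "complete.obs"))
    if (!is.na(s) && s > best_s) { best_s <- s; best_E <- E }
  }
  list(E = best_E, tau = as.integer(tau))
}

# Time-delay embedding: rows are (y_t, y_{t-tau}, ..., y_{t-(E-1)tau}).
.embed_series <- function(y, E, tau) {
  T <- length(y)
  start <- (E - 1L) * tau + 1L
  if (start + 1L > T) return(NULL)
  t_idx <- start:T
  M <- vapply(0:(E - 1L), function(j) y[t_idx - j * tau],
              numeric(length(t_idx)))
  list(M = matrix(M, ncol = E), t = t_idx)
}

# Simplex projection: predict target values at every row of `query` from
# the E+1 nearest library rows, exponential distance weights. Distances are
# computed directly per query (numerically stable, so neighbour order is
# invariant to affine rescaling of the embedded series).
.simplex_predict <- function(library_M, library_target, query_M,
                             exclude_self = FALSE) {
  nq <- nrow(query_M)
  E <- ncol(query_M)
  k <- E + 1L
  pred <- rep(NA_real_, nq)
  d2 <- matrix(0, nq, nrow(library_M))
  for (e in seq_len(E))
    d2 <- d2 + outer(query_M[, e], library_M[, e], "-")^2
  for (i in seq_len(nq)) {
    d <- sqrt(d2[i, ])
    if (exclude_self) d[d < 1e-12] <- Inf
    if (all(!is.finite(d))) next
    nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    dn <- d[nb]
    w <- if (dn[1] > 0) exp(-dn / dn[1]) else as.numeric(dn == 0)
    w <- w / sum(w)
    pred[i] <- sum(w * library_target[nb])
  }
  pred
}

# Amplitude-preserving surrogate: randomize Fourier phases, keep the power
# spectrum, enforce Hermitian symmetry so the inverse transform is real.
.phase_surrogate <- function(y) {
  n <- length(y)
  z <- fft(y - mean(y))
  m <- floor((n - 1) / 2)
  if (m >= 1) {
    k <- 2:(m + 1)
    ph <- runif(m, 0, 2 * pi)
    z[k] <- Mod(z[k]) * exp(1i * ph)
    z[n + 2L - k] <- Conj(z[k])
  }
  if (n %% 2 == 0) z[n / 2 + 1] <- Mod(z[n / 2 + 1])
  Re(fft(z, inverse = TRUE)) / n + mean(y)
}

#' Convergent cross-mapping
#'
#' Tests the direction "x causes y" by cross-mapping from y's shadow
#' manifold to x: y is embedded with (E, tau), and for each library size L
#' random subsets of L embedding points predict x by simplex projection
#' (E+1 neighbours, exponential weights); the skill is the Pearson
#' correlation between predicted and observed x. The p-value compares the
#' maximum-library skill with skills of phase-randomized surrogates of y.
#'
#' @param x_series putative cause.
#' @param y_series putative effect (embedded side).
#' @param cfg a [ccm_config()].
#' @return a `ccm_result`: `skill_curve` data.frame (library_size, skill),
#'   `skill` (at max library), `p_value`, `convergent`, `direction`, and
#'   the config used (embedding parameters are always logged).
#' @export
ccm <- function(x_series, y_series, cfg = ccm_config()) {
  x <- as.numeric(x_series); y <- as.numeric(y_series)
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0) stop("constant series: skill undefined")
  E <- cfg$E; tau <- cfg$tau
  if (length(x) < (E - 1) * tau + E + 2) stop("series too short for (E, tau)")
  emb <- .embed_series(y, E, tau)
  M <- emb$M; targets <- x[emb$t]
  np <- nrow(M)
  libs <- cfg$library_sizes
  if (is.null(libs)) {
    lmin <- E + 2L
    libs <- unique(round(seq(lmin, np, length.out = 8)))
  }
  libs <- sort(unique(pmin(libs, np)))
  set.seed(cfg$seed)
  skill_for <- function(M, targets, L, n_samples) {
    mean(vapply(seq_len(n_samples), function(s) {
      lib <- sample.int(nrow(M), L)
      pred <- .simplex_predict(M[lib, , drop = FALSE], targets[lib], M,
                               exclude_self = TRUE)
      ok <- is.finite(pred)
      if (sum(ok) < 3 || sd(pred[ok]) == 0 || sd(targets[ok]) == 0)
        return(NA_real_)
      cor(pred[ok], targets[ok])
    }, numeric(1)), na.rm = TRUE)
  }
  curve <- vapply(libs, function(L)
    skill_for(M, targets, L, if (L == np) 1L else cfg$n_samples),
    numeric(1))
  obs <- curve[length(curve)]
  p <- NA_real_
  null_q <- NA_real_
  if (cfg$n_surrogates > 0) {
    nulls <- vapply(seq_len(cfg$n_surrogates), function(s) {
      ys <- .phase_surrogate(y)
      es <- .embed_series(ys, E, tau)
      skill_for(es$M, x[es$t], max(libs), 1L)
    }, numeric(1))
    p <- (1 + sum(nulls >= obs, na.rm = TRUE)) / (cfg$n_surrogates + 1)
    null_q <- quantile(nulls, cfg$null_quantile, na.rm = TRUE,
                       names = FALSE)
  }
  # convergence needs a genuine monotone rise of skill with library size,
  # not just a positive end-to-end difference
  increasing <- length(curve) > 2 &&
    suppressWarnings(cor(libs, curve, method = "spearman")) >= 0.8 &&
    curve[length(curve)] > curve[1]
  convergent <- isTRUE(increasing && !is.na(null_q) &&
                         obs > max(null_q, cfg$min_skill))
  structure(list(skill_curve = data.frame(library_size = libs,
                                          skill = curve),
                 skill = obs, p_value = p, null_q = null_q,
                 convergent = convergent,
                 direction = "x -> y (cross-map y's manifold to x)",
                 E = E, tau = tau, n_points = np),
            class = "ccm_result")
}

#' Correlation test between two aligned series
#'
#' @param series_a,series_b paired numeric vectors (>= 4 points).
#' @param method `"pearson"` or `"spearman"` (average ranks for ties).
#' @return list: `r`, `p`, `method`, `n`.
#' @export
correlate <- function(series_a, series_b,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(series_a) & is.finite(series_b)
  a <- series_a[ok]; b <- series_b[ok]
  stopifnot(length(a) >= 4)
  if (sd(a) == 0 || sd(b) == 0) stop("constant input: correlation undefined")
  ct <- suppressWarnings(cor.test(a, b, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(a))
}
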