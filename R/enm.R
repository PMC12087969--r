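# Ecological niche modelling: variable screening (Pearson grouping + PCA
# contribution), great-circle spatial thinning, linear-feature maximum-
# entropy fitting, replicate-averaged AUC evaluation, and cross-era
# projection with the three-class suitability mapping (P > 0.5 suitable,
# 0.3 < P <= 0.5 less suitable, P <= 0.3 unsuitable).

#' Screen environmental variables by correlation groups and PCA contribution
#'
#' Variables whose pairwise Pearson |r| reaches `threshold` are grouped
#' (graph components of the thresholded correlation matrix); within each
#' group only the variable contributing most to the principal components is
#' retained. Contribution is the variance-weighted sum of squared loadings
#' from a PCA of the standardized table. Constant variables are excluded
#' with a warning (their correlation is undefined).
#'
#' @param records data.frame or matrix of records x variables.
#' @param threshold grouping cutoff on |r| (default 0.8).
#' @return list: `selected` (names kept), `groups`, `correlation` matrix,
#'   `contribution` per variable.
#' @export
screen_variables <- function(records, threshold = 0.8) {
  X <- as.matrix(records)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning("excluding constant variables: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  R <- cor(X)
  pca <- prcomp(X, scale. = TRUE)
  ev <- pca$sdev^2
  contrib <- colSums((t(pca$rotation)^2) * ev) # per-variable, weighted
  names(contrib) <- colnames(X)
  # connected components of |r| >= threshold
  adj <- abs(R) >= threshold
  grp <- rep(NA_integer_, p)
  g <- 0L
  for (i in seq_len(p)) {
    if (!is.na(grp[i])) next
    g <- g + 1L
    frontier <- i
    while (length(frontier)) {
      grp[frontier] <- g
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & is.na(grp))
      frontier <- nxt
    }
  }
  keep <- vapply(seq_len(g), function(k) {
    members <- which(grp == k)
    members[which.max(contrib[members])]
  }, integer(1))
  groups <- split(colnames(X), grp)
  list(selected = colnames(X)[sort(keep)], groups = groups,
       correlation = R, contribution = contrib)
}

#' Spatially thin records by a great-circle buffer
#'
#' Greedy thinning in input order: a record is kept unless it lies within
#' `radius_km` of an already-kept record (first kept wins, so the result is
#' deterministic given the input order).
#'
#' @param records data.frame with `lon` and `lat` columns (degrees).
#' @param radius_km buffer radius in km; 0 returns the input unchanged.
#' @return the retained rows of `records`.
#' @export
thin_records <- function(records, radius_km) {
  stopifnot(radius_km >= 0, all(c("lon", "lat") %in% names(records)))
  if (radius_km == 0 || nrow(records) <= 1) return(records)
  pts <- as.matrix(records[, c("lon", "lat")])
  kept <- 1L
  for (i in 2:nrow(pts)) {
    dists <- geosphere::distHaversine(pts[kept, , drop = FALSE],
                                      pts[i, , drop = FALSE]) / 1000
    if (all(dists >= radius_km)) kept <- c(kept, i)
  }
  records[kept, , drop = FALSE]
}

#' Fit a linear-feature maximum-entropy niche model
#'
#' Finds the Gibbs distribution over background cells whose linear-feature
#' expectations match the presence means to within an L1 regularization
#' bound. Features are the selected variables scaled to \[0, 1\] by
#' background min/max; the per-feature bound is
#' `beta_f = reg_multiplier * sd_f(presence features) / sqrt(n_presence)`.
#' The convex objective `log Z(w) - w . presence_means + sum(beta |w|)` is
#' minimized by L-BFGS-B on the positive/negative split `w = a - b`.
#'
#' @param presences matrix/data.frame of presence-record variables.
#' @param background matrix/data.frame of background-cell variables (same
#'   columns).
#' @param reg_multiplier regularization multiplier (default 1.5).
#' @param output_transform `"cloglog"` (default) or `"raw"`.
#' @param maxit iteration cap for the optimizer.
#' @return a `niche_model` object: weights, feature bounds, regularization,
#'   entropy of the fitted distribution, convergence diagnostics.
#' @export
fit_maxent_linear <- function(presences, background, reg_multiplier = 1.5,
                              output_transform = c("cloglog", "raw"),
                              maxit = 500L) {
  output_transform <- match.arg(output_transform)
  P <- as.matrix(presences); B <- as.matrix(background)
  stopifnot(nrow(P) >= 2, reg_multiplier > 0,
            identical(colnames(P), colnames(B)))
  lo <- apply(B, 2L, min); hi <- apply(B, 2L, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  # clamp to the background range (standard maxent behaviour: presence or
  # projection values beyond the training range are truncated, otherwise
  # the KKT feature-matching conditions can be unattainable)
  scale01 <- function(M) pmin(pmax(sweep(sweep(M, 2L, lo), 2L, span, "/"),
                                   0), 1)
  Ps <- scale01(P); Bs <- scale01(B)
  pbar <- colMeans(Ps)
  # per-feature L1 bound; the floor (2% of the scaled feature range) keeps
  # the matching target attainable when presence values concentrate at a
  # background extreme (small samples, clamped features)
  beta <- reg_multiplier * apply(Ps, 2L, sd) / sqrt(nrow(Ps))
  beta <- pmax(beta, 0.02 * reg_multiplier)
  k <- ncol(Bs)
  obj <- function(ab) {
    w <- ab[1:k] - ab[k + 1:k]
    eta <- drop(Bs %*% w)
    mx <- max(eta)
    lz <- mx + log(sum(exp(eta - mx)))
    lz - sum(w * pbar) + sum(beta * (ab[1:k] + ab[k + 1:k]))
  }
  grad <- function(ab) {
    w <- ab[1:k] - ab[k + 1:k]
    eta <- drop(Bs %*% w)
    q <- exp(eta - max(eta)); q <- q / sum(q)
    gE <- drop(crossprod(Bs, q)) - pbar
    c(gE + beta, -gE + beta)
  }
  # weights live in a generous box: on the [0,1] feature scale |w| = 60 is
  # an e^60 density ratio, so the bound only binds under degenerate
  # separation of presences from the background, where it keeps the
  # optimization finite
  w_box <- 60
  fit <- optim(rep(0, 2 * k), obj, grad, method = "L-BFGS-B",
               lower = rep(0, 2 * k), upper = rep(w_box, 2 * k),
               control = list(maxit = maxit, factr = 1e4))
  w <- fit$par[1:k] - fit$par[k + 1:k]
  names(w) <- colnames(Bs)
  eta <- drop(Bs %*% w)
  q <- exp(eta - max(eta)); q <- q / sum(q)
  Emodel <- drop(crossprod(Bs, q))
  kkt_gap <- abs(Emodel - pbar) - beta
  kkt_ok <- kkt_gap <= 1e-3 | abs(w) >= w_box - 1e-6
  kkt <- max(kkt_gap)
  if (fit$convergence != 0 && !all(kkt_ok))
    stop("maxent fit did not converge; max KKT violation = ",
         signif(kkt, 3), "; gradient norm = ",
         signif(sqrt(sum(grad(fit$par)^2)), 3))
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  mx <- max(eta)
  structure(list(selected_variables = colnames(Bs), weights = w,
                 feature_bounds = rbind(min = lo, max = hi),
                 reg_multiplier = reg_multiplier, beta = beta,
                 entropy = H, presence_means = pbar,
                 model_means = Emodel, kkt_gap = kkt,
                 log_z = mx + log(sum(exp(eta - mx))),
                 output_transform = output_transform,
                 n_background = nrow(Bs), replicate_models = NULL),
            class = "niche_model")
}

#' Raw Gibbs density of a fitted maxent model
#'
#' Normalized over the training background: evaluated on that background it
#' sums to exactly 1.
#'
#' @param model a `niche_model`.
#' @param X variable table of cells to score.
#' @return numeric densities.
#' @export
maxent_density <- function(model, X) {
  tf <- model$output_transform
  model$output_transform <- "raw"
  .maxent_suitability(model, X)
}

# Raw Gibbs density (normalized over the training background) and the
# chosen output transform.
.maxent_suitability <- function(model, X) {
  X <- as.matrix(X)[, model$selected_variables, drop = FALSE]
  lo <- model$feature_bounds["min", ]; hi <- model$feature_bounds["max", ]
  span <- ifelse(hi > lo, hi - lo, 1)
  Xs <- pmin(pmax(sweep(sweep(X, 2L, lo), 2L, span, "/"), 0), 1)
  eta <- drop(Xs %*% model$weights)
  q <- exp(eta - model$log_z)
  if (model$output_transform == "raw") q
  else 1 - exp(-exp(model$entropy) * q)
}

#' Classify a suitability probability into the three classes
#' @param p numeric vector/matrix of P in \[0, 1\].
#' @return character same shape: `"suitable"` (P > 0.5), `"less_suitable"`
#'   (0.3 < P <= 0.5), `"unsuitable"` (P <= 0.3).
#' @export
classify_suitability <- function(p) {
  cl <- ifelse(p > 0.5, "suitable",
               ifelse(p > 0.3, "less_suitable", "unsuitable"))
  if (is.matrix(p)) dim(cl) <- dim(p)
  cl
}

#' Project a niche model onto a climate slice
#'
#' Per-cell suitability through the model's output transform, plus the
#' three-class map. A list of replicate models is averaged cell-wise before
#' classing.
#'
#' @param model a `niche_model`, or list of them (replicates).
#' @param slice a `climate_slice` (must provide every selected variable).
#' @return a `suitability_map`: matrices `P` and `class`, plus `lon`/`lat`.
#' @export
project_suitability <- function(model, slice) {
  models <- if (inherits(model, "niche_model")) list(model) else model
  vars <- models[[1L]]$selected_variables
  missing_vars <- setdiff(vars, names(slice$vars))
  if (length(missing_vars))
    stop("slice is missing variable(s): ", paste(missing_vars, collapse = ", "))
  X <- do.call(cbind, lapply(vars, function(v) as.vector(slice$vars[[v]])))
  colnames(X) <- vars
  Ps <- vapply(models, function(m) .maxent_suitability(m, X),
               numeric(nrow(X)))
  P <- rowMeans(Ps)
  dim(P) <- dim(slice$vars[[1L]])
  structure(list(P = P, class = classify_suitability(P),
                 lon = slice$lon, lat = slice$lat, age = slice$age),
            class = "suitability_map")
}

#' Score-based AUC of presences against background
#' @param scores_presence,scores_background numeric score vectors.
#' @return Mann-Whitney AUC in \[0, 1\].
#' @export
auc_presence_background <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n2 <- length(scores_background)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Replicate-averaged AUC evaluation of a maxent model
#'
#' Per replicate the presences are split at random into training and test
#' fractions, the model is refit on the training part, and training/test AUC
#' against the background are computed; the replicate averages are reported
#' (the study's setting: 20% random test, ten replicates).
#'
#' @param presences,background variable tables as in [fit_maxent_linear()].
#' @param test_fraction fraction of presences held out (0 < f < 1).
#' @param n_replicates number of random splits (default 10).
#' @param reg_multiplier passed to the fit.
#' @param seed integer seed.
#' @return an `enm_evaluation`: `auc_train`, `auc_test` (replicate means),
#'   `per_replicate` data.frame, `models` (the replicate fits).
#' @export
evaluate_enm <- function(presences, background, test_fraction = 0.2,
                         n_replicates = 10L, reg_multiplier = 1.5,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  P <- as.matrix(presences); B <- as.matrix(background)
  n <- nrow(P)
  n_test <- max(1L, round(test_fraction * n))
  if (n - n_test < 2) stop("too few presences to split")
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(i) {
    test <- sample(n, n_test)
    m <- fit_maxent_linear(P[-test, , drop = FALSE], B, reg_multiplier)
    sp_tr <- .maxent_suitability(m, P[-test, , drop = FALSE])
    sp_te <- .maxent_suitability(m, P[test, , drop = FALSE])
    sb <- .maxent_suitability(m, B)
    list(model = m,
         auc_train = auc_presence_background(sp_tr, sb),
         auc_test = auc_presence_background(sp_te, sb))
  })
  per <- data.frame(
    replicate = seq_len(n_replicates),
    auc_train = vapply(reps, `[[`, numeric(1), "auc_train"),
    auc_test = vapply(reps, `[[`, numeric(1), "auc_test"))
  structure(list(auc_train = mean(per$auc_train),
                 auc_test = mean(per$auc_test),
                 test_fraction = test_fraction, per_replicate = per,
                 models = lapply(reps, `[[`, "model")),
            class = "enm_evaluation")
}
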