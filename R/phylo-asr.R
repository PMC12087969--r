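# Ancestral-state reconstruction: GLS/ML states for continuous traits under
# Brownian motion (with prediction intervals that account for root-estimate
# uncertainty) and marginal posteriors under a symmetric Mk model for
# discrete traits.

#' Brownian-motion ancestral states (GLS)
#'
#' The tips and internal nodes are jointly multivariate normal under BM;
#' ancestral states are the conditional expectations given the tips, with
#' the GLS root estimate plugged in for the mean. Prediction variances
#' include the root-uncertainty correction term, so the 95% CIs are
#' calibrated. Fossil tips need no special handling: the shared-path
#' covariance encodes them.
#'
#' @param tree dated ape `phylo`.
#' @param tip_values named trait vector over every tip.
#' @return an `asr_result`: `node_values` (named, internal nodes incl.
#'   root), `ci` (2-column matrix), `var` (prediction variances), `mu`,
#'   `sigma2` (ML), `logL`.
#' @export
asr_bm <- function(tree, tip_values) {
  x <- match_tips(tree, tip_values)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  all_idx <- seq_len(n + m)
  Cfull <- full_vcv(tree, all_idx)
  Ct <- Cfull[seq_len(n), seq_len(n), drop = FALSE]
  Cnt <- Cfull[n + seq_len(m), seq_len(n), drop = FALSE]
  Cnn <- Cfull[n + seq_len(m), n + seq_len(m), drop = FALSE]
  fit <- bm_loglik_C(Ct, x)
  L <- chol(Ct)
  solveC <- function(v) backsolve(L, forwardsolve(t(L), v))
  A <- t(solveC(t(Cnt)))              # Cnt %*% Ct^-1
  est <- fit$mu + drop(A %*% (x - fit$mu))
  ones <- rep(1, n)
  Ci1 <- solveC(ones)
  s11 <- sum(Ci1)
  h <- 1 - drop(A %*% ones)           # root-mean sensitivity per node
  var_rel <- diag(Cnn - A %*% t(Cnt)) + h^2 / s11
  var_rel <- pmax(var_rel, 0)
  v <- fit$sigma2 * var_rel
  labs <- node_labels(tree)[n + seq_len(m)]
  names(est) <- labs
  ci <- cbind(lower = est - 1.96 * sqrt(v), upper = est + 1.96 * sqrt(v))
  rownames(ci) <- labs
  structure(list(node_values = est, ci = ci, var = setNames(v, labs),
                 mu = fit$mu, sigma2 = fit$sigma2, logL = fit$logL,
                 method = "GLS-BM"),
            class = "asr_result")
}

# Symmetric-Mk transition probabilities: k states, rate q between each
# ordered pair. Closed form from the spectral decomposition.
mk_transition <- function(q, t, k) {
  e <- exp(-k * q * t)
  stay <- 1 / k + (k - 1) / k * e
  move <- 1 / k - e / k
  M <- matrix(move, k, k)
  diag(M) <- stay
  M
}

#' Discrete ancestral states under a symmetric Mk model
#'
#' Fits the single symmetric rate by ML (pruning), then computes marginal
#' posterior state probabilities at every internal node by the standard
#' inside-outside pass (equivalent to rerooting at each node). Posteriors
#' sum to 1 at every node; a trait observed in a single state drives the
#' rate to the boundary and the root posterior to 1 for that state.
#'
#' @param tree dated ape `phylo`.
#' @param tip_states named character/factor vector over tips.
#' @param k_states optional number of states (defaults to the observed
#'   levels).
#' @return an `asr_result`: `node_posterior` (internal nodes x states),
#'   `rate` (ML), `logL`, `states`.
#' @export
asr_mk <- function(tree, tip_states, k_states = NULL) {
  n <- ape::Ntip(tree)
  sts <- tip_states[tree$tip.label]
  if (anyNA(sts)) stop("missing tip states")
  levs <- if (is.factor(tip_states)) levels(tip_states) else
    sort(unique(as.character(tip_states)))
  if (!is.null(k_states) && k_states > length(levs))
    levs <- c(levs, paste0("state", seq_len(k_states - length(levs))))
  k <- length(levs)
  stopifnot(k >= 2)
  si <- match(as.character(sts), levs)
  post_edges <- ape::postorder(tree)
  n_all <- n + tree$Nnode
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  down <- function(q) { # conditional likelihoods + log scalers
    Lk <- matrix(0, n_all, k)
    Lk[cbind(seq_len(n), si)] <- 1
    scl <- numeric(n_all)
    # postorder over edges guarantees children are finished first
    done <- rep(FALSE, n_all); done[seq_len(n)] <- TRUE
    for (ei in post_edges) {
      p <- tree$edge[ei, 1L]
      if (done[p]) next
      kids <- children[[as.character(p)]]
      if (!all(done[tree$edge[kids, 2L]])) next
      v <- rep(1, k); sc <- 0
      for (e2 in kids) {
        ch <- tree$edge[e2, 2L]
        P <- mk_transition(q, tree$edge.length[e2], k)
        v <- v * drop(P %*% Lk[ch, ])
        sc <- sc + scl[ch]
      }
      mx <- max(v)
      Lk[p, ] <- v / mx
      scl[p] <- sc + log(mx)
      done[p] <- TRUE
    }
    list(L = Lk, scl = scl)
  }
  loglik <- function(q) {
    d <- down(q)
    root <- n + 1L
    log(sum(d$L[root, ] / k)) + d$scl[root]
  }
  opt <- optimize(function(lq) loglik(exp(lq)), c(log(1e-8), log(100)),
                  maximum = TRUE, tol = 1e-8)
  q <- exp(opt$maximum)
  d <- down(q)
  # outside pass
  O <- matrix(0, n_all, k)
  root <- n + 1L
  O[root, ] <- 1 / k
  pre <- rev(post_edges)
  for (ei in pre) {
    p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
    P <- mk_transition(q, tree$edge.length[ei], k)
    sib_prod <- rep(1, k)
    for (e2 in children[[as.character(p)]]) {
      if (e2 == ei) next
      s <- tree$edge[e2, 2L]
      Ps <- mk_transition(q, tree$edge.length[e2], k)
      sib_prod <- sib_prod * drop(Ps %*% d$L[s, ])
    }
    ov <- drop(t(P) %*% (O[p, ] * sib_prod))
    mx <- max(ov)
    O[ch, ] <- if (mx > 0) ov / mx else ov
  }
  post <- d$L * O
  post <- post / rowSums(post)
  nodes <- n + seq_len(tree$Nnode)
  pm <- post[nodes, , drop = FALSE]
  dimnames(pm) <- list(node_labels(tree)[nodes], levs)
  structure(list(node_posterior = pm, rate = q, logL = opt$objective,
                 states = levs),
            class = "asr_result")
}
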