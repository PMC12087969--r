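# Time-stratified dispersal-extinction-cladogenesis family: DEC, DIVALIKE
# and BAYAREALIKE anagenetic/cladogenetic models (each with an optional
# founder-event +j term), pruning likelihoods with per-epoch matrix
# exponentials spliced along branches, ML fitting with AICc comparison, and
# biogeographic stochastic mapping with dispersal-event counting.

# --- range state space (bitmask representation) ------------------------------

# All nonempty realm subsets up to max_range_size, ordered by size then value.
states_for <- function(n_realms, max_range_size) {
  masks <- seq_len(2^n_realms - 1L)
  sizes <- vapply(masks, .popcount, integer(1))
  masks <- masks[sizes <= max_range_size]
  masks[order(vapply(masks, .popcount, integer(1)), masks)]
}

.popcount <- function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:7)) != 0L)

.mask_bits <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:7)) != 0L)

#' Convert range strings to bitmasks and back
#'
#' Ranges are written as `"PA+OR"` style strings over the realm labels.
#'
#' @param range_str character vector of range strings.
#' @param realms realm labels in order.
#' @return integer bitmask vector.
#' @export
range_to_mask <- function(range_str, realms) {
  vapply(strsplit(range_str, "\\+"), function(parts) {
    idx <- match(parts, realms)
    if (anyNA(idx)) stop("unknown realm in range: ",
                         paste(parts[is.na(idx)], collapse = ","))
    as.integer(sum(bitwShiftL(1L, idx - 1L)))
  }, integer(1))
}

#' @rdname range_to_mask
#' @param mask integer bitmask vector.
#' @export
mask_to_range <- function(mask, realms) {
  vapply(mask, function(m)
    paste(realms[.mask_bits(m)], collapse = "+"), character(1))
}

#' Biogeographic model specification
#'
#' @param scheme cladogenesis scheme: `"DEC"`, `"DIVALIKE"` or
#'   `"BAYAREALIKE"`.
#' @param d,e anagenetic dispersal (range gain) and extirpation (range
#'   loss) rates per My.
#' @param j founder-event weight (0 = no founder events; 0 <= j < 3).
#' @param max_range_size largest allowed range (default 2 keeps the 8-realm
#'   state space at 36 states).
#' @return a `biogeo_model` list.
#' @export
biogeo_model <- function(scheme = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                         d = 0.01, e = 0.005, j = 0, max_range_size = 2L) {
  scheme <- match.arg(scheme)
  stopifnot(d >= 0, e >= 0, j >= 0, j < 3, max_range_size >= 1)
  structure(list(scheme = scheme, d = d, e = e, j = j,
                 max_range_size = as.integer(max_range_size)),
            class = "biogeo_model")
}

#' Anagenetic rate generator for one epoch
#'
#' Off-diagonal entries: gain of realm b from range R at rate
#' `d * sum_{a in R} m[a, b]` (if the enlarged range stays in the state
#' space); loss of a resident realm at rate `e` per realm for ranges larger
#' than one. Rows sum to zero.
#'
#' @param model a [biogeo_model()].
#' @param m symmetric multiplier matrix for the epoch.
#' @param states optional state-space masks (computed if missing).
#' @return K x K generator matrix with range-string dimnames.
#' @export
build_Q <- function(model, m, states = NULL) {
  n <- nrow(m)
  if (is.null(states)) states <- states_for(n, model$max_range_size)
  K <- length(states)
  idx <- integer(2^n); idx[states] <- seq_len(K)
  Q <- matrix(0, K, K)
  for (si in seq_len(K)) {
    R <- .mask_bits(states[si])
    if (length(R) < model$max_range_size) {
      for (b in setdiff(seq_len(n), R)) {
        tgt <- states[si] + bitwShiftL(1L, b - 1L)
        ti <- idx[tgt]
        if (ti > 0) Q[si, ti] <- Q[si, ti] + model$d * sum(m[R, b])
      }
    }
    if (length(R) > 1L) {
      for (a in R) {
        tgt <- states[si] - bitwShiftL(1L, a - 1L)
        Q[si, idx[tgt]] <- Q[si, idx[tgt]] + model$e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  labs <- mask_to_range(states, rownames(m) %||% paste0("r", seq_len(n)))
  dimnames(Q) <- list(labs, labs)
  Q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cladogenetic event table for ancestral state s (mask): data.frame of
# daughter masks (left, right) and normalized weights. Non-founder events
# carry weight 1 before normalization, founder events weight j.
.clado_events <- function(smask, scheme, j, states, n_realms) {
  in_space <- function(m) m %in% states
  bits <- .mask_bits(smask)
  ev <- list()
  add <- function(l, r, w) ev[[length(ev) + 1L]] <<- c(l, r, w)
  if (length(bits) == 1L) {
    add(smask, smask, 1)                                   # sympatry
  } else {
    if (scheme == "DEC") {
      for (a in bits) {                                    # subset sympatry
        am <- bitwShiftL(1L, a - 1L)
        add(smask, am, 1); add(am, smask, 1)
      }
    }
    if (scheme %in% c("DEC", "DIVALIKE")) {                # vicariance
      subs <- .proper_subsets(smask)
      for (A in subs) {
        B <- smask - A
        if (A >= B) next                                   # unordered once
        if (scheme == "DEC" && min(.popcount(A), .popcount(B)) != 1L) next
        if (!in_space(A) || !in_space(B)) next
        add(A, B, 1); add(B, A, 1)
      }
    }
    if (scheme == "BAYAREALIKE") add(smask, smask, 1)      # identical copy
  }
  if (j > 0) {
    for (b in setdiff(seq_len(n_realms), bits)) {          # founder event
      bm <- bitwShiftL(1L, b - 1L)
      add(smask, bm, j); add(bm, smask, j)
    }
  }
  M <- do.call(rbind, ev)
  data.frame(left = M[, 1], right = M[, 2], w = M[, 3] / sum(M[, 3]))
}

.proper_subsets <- function(smask) {
  bits <- .mask_bits(smask)
  k <- length(bits)
  out <- integer(0)
  for (pat in 1:(2^k - 2L))
    out <- c(out, sum(bitwShiftL(1L, bits[.mask_bits(pat)] - 1L)))
  unique(out)
}

# Per-branch transition matrices spliced across epoch boundaries. Returns
# the per-segment matrices (oldest first) and their product.
.branch_P <- function(age_top, age_bot, Qs, history) {
  segs <- list()
  t_now <- age_top
  while (t_now > age_bot + 1e-12) {
    ep_i <- .epoch_index(history, t_now)
    seg_end <- max(age_bot, history$epochs[[ep_i]]$end)
    dt <- t_now - seg_end
    if (dt > 0)
      segs[[length(segs) + 1L]] <- list(P = .expm_cached(Qs[[ep_i]], dt),
                                        epoch = ep_i, age_top = t_now,
                                        age_bot = seg_end)
    t_now <- seg_end
  }
  if (!length(segs)) {
    K <- nrow(Qs[[1L]])
    return(list(segs = list(), Ptot = diag(K)))
  }
  Ptot <- segs[[1L]]$P
  if (length(segs) > 1) for (i in 2:length(segs)) Ptot <- Ptot %*% segs[[i]]$P
  list(segs = segs, Ptot = Ptot)
}

.epoch_index <- function(history, age) {
  eps <- history$epochs
  if (age > eps[[1L]]$start) return(1L)
  for (i in seq_along(eps))
    if (age <= eps[[i]]$start + 1e-9 && age > eps[[i]]$end + 1e-9) return(i)
  length(eps)
}

.expm_cached <- function(Q, dt) {
  as.matrix(Matrix::expm(Q * dt))
}

# Pruning machinery shared by likelihood and stochastic mapping. Computes
# per-node conditional likelihood arrays (scaled) and per-edge branch data.
.biogeo_prune <- function(tree, tip_masks, model, history) {
  n_realms <- length(history$realms)
  states <- states_for(n_realms, model$max_range_size)
  K <- length(states)
  sidx <- integer(2^n_realms); sidx[states] <- seq_len(K)
  if (any(!(tip_masks %in% states)))
    stop("tip range larger than max_range_size (or empty)")
  Qs <- lapply(history$epochs, function(ep) build_Q(model, ep$m, states))
  clado <- lapply(states, .clado_events, scheme = model$scheme,
                  j = model$j, states = states, n_realms = n_realms)
  clado <- lapply(clado, function(tb) {
    tb$li <- sidx[tb$left]; tb$ri <- sidx[tb$right]; tb
  })
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  n_all <- n_tip + tree$Nnode
  L <- matrix(0, n_all, K)
  L[cbind(seq_len(n_tip), sidx[tip_masks])] <- 1
  scl <- numeric(n_all)
  edge_data <- vector("list", nrow(tree$edge))
  B <- matrix(0, n_all, K)    # branch-top conditional likelihood per child
  post_edges <- ape::postorder(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  done <- c(rep(TRUE, n_tip), rep(FALSE, tree$Nnode))
  for (ei in post_edges) {
    p <- tree$edge[ei, 1L]
    kids <- children[[as.character(p)]]
    if (done[p] || !all(done[tree$edge[kids, 2L]])) next
    v <- rep(1, K); sc <- 0
    for (e2 in kids) {
      ch <- tree$edge[e2, 2L]
      bp <- .branch_P(ages[p], ages[ch], Qs, history)
      edge_data[[e2]] <- bp
      B[ch, ] <- drop(bp$Ptot %*% L[ch, ])
      sc <- sc + scl[ch]
    }
    # cladogenesis: combine the two daughters' branch-top arrays
    k2 <- tree$edge[kids, 2L]
    for (si in seq_len(K)) {
      tb <- clado[[si]]
      v[si] <- sum(tb$w * B[k2[1L], tb$li] * B[k2[2L], tb$ri])
    }
    mx <- max(v)
    if (mx <= 0) { L[p, ] <- 0; scl[p] <- sc - 745 } # impossible data
    else { L[p, ] <- v / mx; scl[p] <- sc + log(mx) }
    done[p] <- TRUE
  }
  root <- n_tip + 1L
  logL <- log(sum(L[root, ] / K)) + scl[root]
  list(logL = logL, L = L, scl = scl, B = B, states = states, sidx = sidx,
       Qs = Qs, clado = clado, edge_data = edge_data, ages = ages,
       children = children, n_tip = n_tip)
}

#' Log-likelihood of tip ranges under a time-stratified model
#'
#' Felsenstein pruning over the range state space, with per-epoch matrix
#' exponentials spliced along every branch that crosses an epoch boundary
#' and the scheme's cladogenetic weight table applied at nodes. The root
#' prior is uniform over states.
#'
#' @param tree dated ape `phylo`.
#' @param tip_ranges named range strings per tip (e.g. `"PA+OR"`).
#' @param model a [biogeo_model()].
#' @param history a `realm_history`.
#' @return log-likelihood.
#' @export
biogeo_loglik <- function(tree, tip_ranges, model, history) {
  tm <- range_to_mask(tip_ranges[tree$tip.label], history$realms)
  .biogeo_prune(tree, tm, model, history)$logL
}

#' Fit the DEC-family models by maximum likelihood
#'
#' Bounded ML optimization of (d, e) - and j for the founder variants -
#' per scheme, compared by AICc. Boundary convergence is flagged.
#'
#' @param tree dated ape `phylo`.
#' @param tip_ranges named range strings per tip.
#' @param history a `realm_history`.
#' @param schemes cladogenesis schemes to fit.
#' @param jump also fit the +j variant of each scheme (default TRUE).
#' @param max_range_size passed to [biogeo_model()].
#' @return a `biogeo_fit`: `table` (model, d, e, j, logL, k, AICc,
#'   delta_AICc, boundary), `models` (fitted `biogeo_model`s), `best` name.
#' @export
biogeo_fit <- function(tree, tip_ranges, history,
                       schemes = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                       jump = TRUE, max_range_size = 2L) {
  tm <- range_to_mask(tip_ranges[tree$tip.label], history$realms)
  n <- ape::Ntip(tree)
  rows <- list(); models <- list()
  for (scheme in schemes) for (withj in (if (jump) c(FALSE, TRUE) else FALSE)) {
    nm <- paste0(scheme, if (withj) "+j" else "")
    obj <- function(par) {
      mod <- biogeo_model(scheme, d = exp(par[1]), e = exp(par[2]),
                          j = if (withj) par[3] else 0,
                          max_range_size = max_range_size)
      ll <- tryCatch(.biogeo_prune(tree, tm, mod, history)$logL,
                     error = function(er) -Inf)
      if (!is.finite(ll)) 1e10 else -ll
    }
    p0 <- c(log(0.01), log(0.005), if (withj) 0.1)
    lower <- c(log(1e-7), log(1e-7), if (withj) 1e-6)
    upper <- c(log(5), log(5), if (withj) 2.99)
    opt <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 200))
    d <- exp(opt$par[1]); e <- exp(opt$par[2])
    jj <- if (withj) opt$par[3] else 0
    k <- if (withj) 3L else 2L
    logL <- -opt$value
    boundary <- any(abs(opt$par - lower) < 1e-6) ||
      any(abs(opt$par - upper) < 1e-6)
    rows[[nm]] <- data.frame(model = nm, d = d, e = e, j = jj, logL = logL,
                             k = k,
                             AICc = -2 * logL + 2 * k +
                               2 * k * (k + 1) / (n - k - 1),
                             boundary = boundary)
    models[[nm]] <- biogeo_model(scheme, d = d, e = e, j = jj,
                                 max_range_size = max_range_size)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  structure(list(table = tab, models = models,
                 best = tab$model[which.min(tab$AICc)]),
            class = "biogeo_fit")
}
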