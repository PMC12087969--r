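# Biogeographic stochastic mapping: joint range histories sampled
# conditional on the tips and a fitted model, yielding explicit per-branch
# event lists, per-My dispersal-event series and realm-pair percentages.
# Branch paths are endpoint-conditioned by rejection sampling with a
# uniformization fallback. Also the unconditional forward simulator used
# for simulation-likelihood agreement checks.

# Endpoint-conditioned CTMC path in one epoch segment. Returns a data.frame
# (tau from segment start, from, to state indices).
.sample_path_segment <- function(Q, P, i, j, dt, max_reject = 1000L) {
  for (try in seq_len(max_reject)) {
    s <- i; t <- 0; ev <- list()
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      t <- t + rexp(1, rate)
      if (t >= dt) break
      probs <- Q[s, ]; probs[s] <- 0
      nxt <- sample.int(length(probs), 1L, prob = probs)
      ev[[length(ev) + 1L]] <- c(t, s, nxt)
      s <- nxt
    }
    if (s == j) {
      if (!length(ev)) return(NULL)
      M <- do.call(rbind, ev)
      return(data.frame(tau = M[, 1], from = M[, 2], to = M[, 3]))
    }
  }
  .uniformization_path(Q, P, i, j, dt)
}

# Uniformization sampler (exact given the transition matrix P = expm(Q dt)).
.uniformization_path <- function(Q, P, i, j, dt, n_max = 200L) {
  lam <- max(-diag(Q))
  if (lam <= 0) return(NULL)
  K <- nrow(Q)
  R <- diag(K) + Q / lam
  p_ij <- P[i, j]
  Rpow <- list(diag(K))                  # Rpow[[m+1]] = R^m
  u <- runif(1)
  cum <- 0; n <- -1L
  repeat {
    n <- n + 1L
    if (n + 1L > length(Rpow)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
    term <- stats::dpois(n, lam * dt) * Rpow[[n + 1L]][i, j] / p_ij
    cum <- cum + term
    if (u <= cum || n >= n_max) break
  }
  if (n == 0L) return(NULL)
  states <- integer(n)
  prev <- i
  for (k in seq_len(n)) {
    w <- R[prev, ] * Rpow[[n - k + 1L]][, j]
    states[k] <- sample.int(K, 1L, prob = w)
    prev <- states[k]
  }
  taus <- sort(runif(n, 0, dt))
  keep <- c(states[1] != i, diff(states) != 0)
  if (!any(keep)) return(NULL)
  from <- c(i, states)[c(keep, FALSE)]
  data.frame(tau = taus[keep], from = from, to = states[keep])
}

#' Biogeographic stochastic mapping
#'
#' Samples `n_maps` joint range histories conditional on the tip ranges and
#' the fitted model: node states from the conditional likelihoods,
#' cladogenetic outcomes from the scheme's weighted table, branch histories
#' by endpoint-conditioned event sampling (rejection with a uniformization
#' fallback), with epoch boundaries splitting branches deterministically.
#' Anagenetic range gains and founder events are dispersal events; the
#' source realm of a gain is drawn proportionally to the epoch's
#' multipliers from the occupied realms.
#'
#' @param tree dated ape `phylo`.
#' @param tip_ranges named range strings per tip.
#' @param model a fitted [biogeo_model()].
#' @param history a `realm_history`.
#' @param n_maps number of maps (default 200).
#' @param seed integer seed.
#' @return a `bsm_result`: `maps` (per-map event data.frames: age, type in
#'   \{dispersal, extirpation, founder\}, from/to range strings, realm_from,
#'   realm_to), `per_my` (bin table with mean dispersal events per My over
#'   maps), `realm_pair_pct` (percentages over directed realm pairs, sums
#'   to 100), `node_states` (per-map matrix of sampled node range strings).
#' @export
bsm <- function(tree, tip_ranges, model, history, n_maps = 200L, seed = 1L) {
  set.seed(seed)
  tm <- range_to_mask(tip_ranges[tree$tip.label], history$realms)
  pr <- .biogeo_prune(tree, tm, model, history)
  if (!is.finite(pr$logL)) stop("model has non-finite likelihood")
  states <- pr$states
  K <- length(states)
  n_tip <- pr$n_tip
  ages <- pr$ages
  root <- n_tip + 1L
  realms <- history$realms
  pre_edges <- rev(ape::postorder(tree))
  maps <- vector("list", n_maps)
  node_states <- matrix(NA_character_, n_maps, tree$Nnode)
  for (mi in seq_len(n_maps)) {
    ev_rows <- list()
    note <- function(age, type, from_m, to_m, rf, rt)
      ev_rows[[length(ev_rows) + 1L]] <<- data.frame(
        age = age, type = type, from = mask_to_range(from_m, realms),
        to = mask_to_range(to_m, realms),
        realm_from = rf, realm_to = rt, stringsAsFactors = FALSE)
    st <- integer(n_tip + tree$Nnode)   # state index at each node
    st[root] <- sample.int(K, 1L, prob = pr$L[root, ])
    # top-of-branch states after cladogenesis, keyed by child node
    top <- integer(n_tip + tree$Nnode)
    assign_clado <- function(p) {
      kids_e <- pr$children[[as.character(p)]]
      k2 <- tree$edge[kids_e, 2L]
      tb <- pr$clado[[st[p]]]
      w <- tb$w * pr$B[k2[1L], tb$li] * pr$B[k2[2L], tb$ri]
      ei <- sample.int(nrow(tb), 1L, prob = w)
      top[k2[1L]] <<- tb$li[ei]; top[k2[2L]] <<- tb$ri[ei]
      pm <- states[st[p]]
      for (cn in k2) {
        dm <- states[top[cn]]
        if (bitwAnd(dm, pm) != dm) {     # daughter outside parent: founder
          b <- .mask_bits(dm)
          m_ep <- epoch_at(history, ages[p])$m
          src <- .mask_bits(pm)
          a <- if (length(src) == 1L) src else
            sample(src, 1L, prob = m_ep[src, b] + 1e-12)
          note(ages[p], "founder", pm, dm, realms[a], realms[b])
        }
      }
    }
    assign_clado(root)
    for (ei in pre_edges) {
      p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
      bp <- pr$edge_data[[ei]]
      c_top <- top[ch]
      # bottom state given top state and subtree data
      wbot <- bp$Ptot[c_top, ] * pr$L[ch, ]
      s_bot <- sample.int(K, 1L, prob = wbot)
      st[ch] <- s_bot
      # intermediate states at epoch boundaries, then per-segment paths
      segs <- bp$segs
      if (length(segs)) {
        ns <- length(segs)
        suffix <- vector("list", ns)
        suffix[[ns]] <- segs[[ns]]$P
        if (ns > 1) for (k in (ns - 1):1)
          suffix[[k]] <- segs[[k]]$P %*% suffix[[k + 1L]]
        bnd <- integer(ns + 1L); bnd[1L] <- c_top; bnd[ns + 1L] <- s_bot
        if (ns > 1) for (k in 1:(ns - 1L)) {
          w <- segs[[k]]$P[bnd[k], ] * suffix[[k + 1L]][, s_bot]
          bnd[k + 1L] <- sample.int(K, 1L, prob = w)
        }
        for (k in seq_len(ns)) {
          sg <- segs[[k]]
          dt <- sg$age_top - sg$age_bot
          path <- .sample_path_segment(pr$Qs[[sg$epoch]], sg$P,
                                       bnd[k], bnd[k + 1L], dt)
          if (!is.null(path)) for (ri in seq_len(nrow(path))) {
            fm <- states[path$from[ri]]; tmk <- states[path$to[ri]]
            age_ev <- sg$age_top - path$tau[ri]
            if (.popcount(tmk) > .popcount(fm)) {
              b <- .mask_bits(tmk - bitwAnd(tmk, fm))
              m_ep <- epoch_at(history, age_ev)$m
              src <- .mask_bits(fm)
              a <- if (length(src) == 1L) src else
                sample(src, 1L, prob = m_ep[src, b] + 1e-12)
              note(age_ev, "dispersal", fm, tmk, realms[a], realms[b])
            } else {
              lost <- .mask_bits(fm - bitwAnd(tmk, fm))
              note(age_ev, "extirpation", fm, tmk, realms[lost], NA_character_)
            }
          }
        }
      }
      if (ch > n_tip) assign_clado(ch)
    }
    maps[[mi]] <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(age = numeric(0), type = character(0), from = character(0),
                 to = character(0), realm_from = character(0),
                 realm_to = character(0))
    node_states[mi, ] <- mask_to_range(states[st[n_tip + seq_len(tree$Nnode)]],
                                       realms)
  }
  ra <- root_age(tree)
  bins <- uniform_bins(ra, 1)
  disp_counts <- matrix(0, n_maps, n_bins(bins))
  pair_tab <- list()
  for (mi in seq_len(n_maps)) {
    mp <- maps[[mi]]
    dd <- mp[mp$type %in% c("dispersal", "founder"), , drop = FALSE]
    if (nrow(dd)) {
      bi <- assign_bin(pmin(dd$age, ra), bins)
      for (b in bi[!is.na(bi)]) disp_counts[mi, b] <- disp_counts[mi, b] + 1
      pair_tab[[mi]] <- paste(dd$realm_from, dd$realm_to, sep = "->")
    }
  }
  per_my <- data.frame(bin = seq_len(n_bins(bins)), label = bins$labels,
                       age_older = head(bins$edges, -1),
                       events = colMeans(disp_counts))
  pairs <- unlist(pair_tab)
  pct <- if (length(pairs)) 100 * table(pairs) / length(pairs) else table(NULL)
  structure(list(maps = maps, per_my = per_my,
                 realm_pair_pct = pct, node_states = node_states,
                 n_maps = n_maps, logL = pr$logL, bins = bins),
            class = "bsm_result")
}

#' Unconditional forward simulation of tip ranges
#'
#' Root state uniform over the state space, anagenetic CTMC along branches
#' (epoch-stratified) and cladogenetic outcomes drawn from the scheme's
#' weight table: the probability of any tip-range pattern equals the
#' pruning likelihood with its uniform root prior, which makes this the
#' simulation side of simulation-likelihood agreement checks.
#'
#' @param tree dated ape `phylo`.
#' @param model a [biogeo_model()].
#' @param history a `realm_history`.
#' @return named range strings per tip.
#' @export
simulate_biogeo_tips <- function(tree, model, history) {
  n_realms <- length(history$realms)
  states <- states_for(n_realms, model$max_range_size)
  K <- length(states)
  sidx <- integer(2^n_realms); sidx[states] <- seq_len(K)
  Qs <- lapply(history$epochs, function(ep) build_Q(model, ep$m, states))
  clado <- lapply(states, .clado_events, scheme = model$scheme,
                  j = model$j, states = states, n_realms = n_realms)
  ages <- node_ages(tree)
  n_tip <- ape::Ntip(tree)
  st <- integer(n_tip + tree$Nnode)
  top <- integer(n_tip + tree$Nnode)
  root <- n_tip + 1L
  st[root] <- sample.int(K, 1L)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  draw_clado <- function(p) {
    tb <- clado[[st[p]]]
    ei <- sample.int(nrow(tb), 1L, prob = tb$w)
    k2 <- tree$edge[children[[as.character(p)]], 2L]
    top[k2[1L]] <<- sidx[tb$left[ei]]; top[k2[2L]] <<- sidx[tb$right[ei]]
  }
  draw_clado(root)
  for (ei in rev(ape::postorder(tree))) {
    p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
    s <- top[ch]
    t_now <- ages[p]; t_stop <- ages[ch]
    while (t_now > t_stop + 1e-12) {
      epi <- .epoch_index(history, t_now)
      seg_end <- max(t_stop, history$epochs[[epi]]$end)
      Q <- Qs[[epi]]
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) { t_now <- seg_end; break }
        w <- rexp(1, rate)
        if (t_now - w <= seg_end) { t_now <- seg_end; break }
        t_now <- t_now - w
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample.int(K, 1L, prob = probs)
      }
    }
    st[ch] <- s
    if (ch > n_tip) draw_clado(ch)
  }
  out <- mask_to_range(states[st[seq_len(n_tip)]], history$realms)
  names(out) <- tree$tip.label
  out
}
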