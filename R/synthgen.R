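# Scenario generator: every input the downstream stages consume, with the
# statistical structure the analysis assumes (fossilized birth-death tree,
# Brownian niche traits, cooling latitudinal climate grids, presence records
# sampled from a planted suitability surface, an epoch-stratified realm
# adjacency history, and a planted wing-length/dispersal coupling).

#' Simulation configuration
#'
#' Bundle of the knobs that define a synthetic study scenario. Defaults are
#' the study conditions emulated throughout the package: a clade of ~50
#' genera rooted in the Early Jurassic, a secular global cooling trend, and a
#' positive wing-length effect on dispersal rate.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_extant,n_fossil target number of extant tips and (approximate)
#'   expected number of fossil tips.
#' @param birth_rate,death_rate speciation and extinction rates per My.
#' @param fossil_sampling_rate Poisson fossil sampling rate per lineage-My;
#'   `NULL` picks a rate aimed at `n_fossil` expected samples.
#' @param root_age age of the root divergence, Ma.
#' @param bm_sigma2 Brownian trait variance accrued per My.
#' @param cooling_slope secular trend of global mean annual temperature,
#'   degrees C per My (positive = past warmer than present).
#' @param n_realms number of biogeographic realms (at most 8).
#' @param coupling_beta planted log-linear effect of wing length (mm) on the
#'   per-My dispersal rate: longer-winged lineages disperse more.
#' @param wl_root,wl_drift root forewing length (mm) and its directional
#'   trend per My (wing elongation toward the present, default 0.05 mm/My).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_extant = 25L, n_fossil = 25L,
                       birth_rate = 0.035, death_rate = 0.015,
                       fossil_sampling_rate = NULL, root_age = 175,
                       bm_sigma2 = 0.05, cooling_slope = 0.05,
                       n_realms = 8L, coupling_beta = 0.4,
                       wl_root = 3, wl_drift = 0.05) {
  stopifnot(birth_rate >= 0, death_rate >= 0, root_age > 0,
            n_realms >= 1, n_realms <= 8, bm_sigma2 >= 0)
  if (!is.null(fossil_sampling_rate)) stopifnot(fossil_sampling_rate >= 0)
  structure(list(seed = as.integer(seed), n_extant = as.integer(n_extant),
                 n_fossil = as.integer(n_fossil), birth_rate = birth_rate,
                 death_rate = death_rate,
                 fossil_sampling_rate = fossil_sampling_rate,
                 root_age = root_age, bm_sigma2 = bm_sigma2,
                 cooling_slope = cooling_slope, n_realms = as.integer(n_realms),
                 coupling_beta = coupling_beta, wl_root = wl_root,
                 wl_drift = wl_drift),
            class = "sim_config")
}

#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from the root age, with constant-rate
#' Poisson fossil sampling along every branch of the complete tree. The
#' returned tree spans the extant tips (subsampled to `n_extant` if the
#' process leaves more) plus one fossil tip per Poisson sample. A sample on a
#' lineage with retained descendants is attached as a pendant tip on a
#' 1e-8 My stem so all branch lengths stay positive while its age is kept; a
#' sample below which nothing is retained truncates the lineage and becomes a
#' tip at its exact age.
#'
#' @param cfg a [sim_config()].
#' @param max_attempts retries before giving up when the clade dies or too
#'   few extant tips survive.
#' @param max_lineages abort threshold for runaway radiations.
#' @return an ape `phylo` with attributes `root_age`, `complete_length`
#'   (total branch length of the underlying complete tree, My) and
#'   `n_fossil_samples`.
#' @export
simulate_fbd_tree <- function(cfg, max_attempts = 100L, max_lineages = 20000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$birth_rate <= cfg$death_rate)
    warning("birth_rate <= death_rate: survival conditioning may be slow")
  set.seed(cfg$seed)
  psi <- cfg$fossil_sampling_rate
  for (attempt in seq_len(max_attempts)) {
    sim <- .fbd_forward(cfg$root_age, cfg$birth_rate, cfg$death_rate,
                        max_lineages)
    if (is.null(sim)) next
    extant <- which(sim$fate == "present")
    if (length(extant) < max(2L, cfg$n_extant)) next
    keep_extant <- sort(sample(extant, cfg$n_extant))
    total_len <- sum(sim$t_start - sim$t_end)
    if (is.null(psi)) psi <- cfg$n_fossil / total_len
    n_samp <- rpois(nrow(sim), psi * (sim$t_start - sim$t_end))
    samples <- lapply(seq_len(nrow(sim)), function(i) {
      if (n_samp[i] == 0) return(numeric(0))
      sort(runif(n_samp[i], sim$t_end[i], sim$t_start[i]), decreasing = TRUE)
    })
    tree <- .fbd_reconstruct(sim, keep_extant, samples)
    if (is.null(tree)) next
    attr(tree, "complete_length") <- total_len
    attr(tree, "n_fossil_samples") <- sum(n_samp)
    attr(tree, "psi") <- psi
    return(tree)
  }
  stop("FBD simulation failed after ", max_attempts,
       " attempts (clade extinction or too few survivors)")
}

# Forward simulation of the complete birth-death tree. Returns a data.frame
# of lineages (t_start/t_end ages in Ma, fate, children ids) or NULL if the
# process exceeds max_lineages.
.fbd_forward <- function(root_age_ma, b, d, max_lineages) {
  t_start <- c(root_age_ma, root_age_ma)
  t_end <- c(NA_real_, NA_real_)
  fate <- c(NA_character_, NA_character_)
  child1 <- c(NA_integer_, NA_integer_)
  child2 <- c(NA_integer_, NA_integer_)
  open <- c(1L, 2L)
  while (length(open)) {
    i <- open[1L]; open <- open[-1L]
    rate <- b + d
    wait <- if (rate > 0) rexp(1, rate) else Inf
    if (wait >= t_start[i]) {
      t_end[i] <- 0; fate[i] <- "present"
    } else {
      te <- t_start[i] - wait
      t_end[i] <- te
      if (runif(1) < b / rate) {
        fate[i] <- "split"
        n <- length(t_start)
        if (n + 2L > max_lineages) return(NULL)
        t_start <- c(t_start, te, te)
        t_end <- c(t_end, NA, NA); fate <- c(fate, NA, NA)
        child1 <- c(child1, NA, NA); child2 <- c(child2, NA, NA)
        child1[i] <- n + 1L; child2[i] <- n + 2L
        open <- c(open, n + 1L, n + 2L)
      } else fate[i] <- "death"
    }
  }
  data.frame(t_start = t_start, t_end = t_end, fate = fate,
             child1 = child1, child2 = child2, stringsAsFactors = FALSE)
}

# Build the reconstructed (observed) tree as a Newick string, then parse.
# keep_extant: lineage ids whose extant tip is retained. samples: per-lineage
# fossil sample ages, sorted decreasing (oldest first).
.fbd_reconstruct <- function(sim, keep_extant, samples) {
  eps <- 1e-8
  tip_i <- 0L; fos_i <- 0L
  build <- function(i) {
    base <- NULL  # list(str, age)
    if (sim$fate[i] == "present" && i %in% keep_extant) {
      tip_i <<- tip_i + 1L
      base <- list(str = paste0("t", tip_i), age = 0)
    } else if (sim$fate[i] == "split") {
      b1 <- build(sim$child1[i]); b2 <- build(sim$child2[i])
      if (!is.null(b1) && !is.null(b2)) {
        base <- list(str = paste0("(", b1$str, ":", sim$t_end[i] - b1$age, ",",
                                  b2$str, ":", sim$t_end[i] - b2$age, ")"),
                     age = sim$t_end[i])
      } else if (!is.null(b1)) base <- b1 else if (!is.null(b2)) base <- b2
    }
    ss <- samples[[i]]
    for (s in rev(ss)) {  # youngest first
      fos_i <<- fos_i + 1L
      lab <- paste0("f", fos_i)
      if (is.null(base)) {
        base <- list(str = lab, age = s)
      } else {
        base <- list(str = paste0("(", base$str, ":", s - base$age, ",",
                                  lab, ":", eps, ")"), age = s)
      }
    }
    base
  }
  b1 <- build(1L); b2 <- build(2L)
  ra <- sim$t_start[1L]
  if (!is.null(b1) && !is.null(b2)) {
    nwk <- paste0("(", b1$str, ":", ra - b1$age, ",",
                  b2$str, ":", ra - b2$age, ");")
    root <- ra
  } else {
    only <- if (!is.null(b1)) b1 else b2
    if (is.null(only) || substr(only$str, 1, 1) != "(") return(NULL)
    nwk <- paste0(only$str, ";")
    root <- only$age
  }
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree) || ape::Ntip(tree) < 2) return(NULL)
  attr(tree, "root_age") <- root
  tree
}

#' Simulate a Brownian trait on a dated tree
#'
#' Gaussian increments along every branch; values at internal nodes are
#' returned too, as ground truth for ancestral-state recovery tests.
#'
#' @param tree ape `phylo`.
#' @param sigma2 variance accrued per My (>= 0).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @param drift optional directional trend per My (mean-trend model).
#' @return named numeric vector over tips then internal nodes.
#' @export
simulate_bm_trait <- function(tree, sigma2, root_value = 0, seed = 1L,
                              drift = 0) {
  stopifnot(sigma2 >= 0)
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  val <- numeric(n_all)
  val[n_tip + 1L] <- root_value
  pre <- rev(ape::postorder(tree))  # parent visited before child
  for (ei in pre) {
    p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
    len <- tree$edge.length[ei]
    val[ch] <- val[p] + drift * len + rnorm(1, 0, sqrt(sigma2 * len))
  }
  names(val) <- node_labels(tree)
  val
}

#' Simulate a symmetric Mk discrete trait on a tree
#'
#' @param tree ape `phylo`.
#' @param rate transition rate between each ordered state pair, per My.
#' @param states character state labels (k >= 2).
#' @param seed integer seed.
#' @param root_state state at the root (defaults to the first).
#' @return named character vector over tips then internal nodes.
#' @export
simulate_mk_trait <- function(tree, rate, states = c("oval", "falcate"),
                              seed = 1L, root_state = states[1L]) {
  k <- length(states)
  stopifnot(k >= 2, rate >= 0, root_state %in% states)
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  val <- character(n_tip + tree$Nnode)
  val[n_tip + 1L] <- root_state
  pre <- rev(ape::postorder(tree))
  for (ei in pre) {
    p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
    t <- tree$edge.length[ei]
    stay <- 1 / k + (1 - 1 / k) * exp(-k * rate * t)
    if (runif(1) < stay) val[ch] <- val[p]
    else val[ch] <- sample(setdiff(states, val[p]), 1L)
  }
  names(val) <- node_labels(tree)
  val
}

# Spatially autocorrelated unit field: white noise smoothed by a separable
# moving-average kernel, wrapping in longitude, rescaled to sd 1.
.smooth_field <- function(nlat, nlon, half_width = 2L) {
  z <- matrix(rnorm(nlat * nlon), nlat, nlon)
  w <- half_width
  out <- matrix(0, nlat, nlon)
  for (di in -w:w) for (dj in -w:w) {
    rows <- pmin(pmax(seq_len(nlat) + di, 1L), nlat)
    cols <- ((seq_len(nlon) + dj - 1L) %% nlon) + 1L
    out <- out + z[rows, cols]
  }
  out / sd(out)
}

#' Simulate a cooling climate history on a coarse grid
#'
#' One multi-variable grid per time slice. Every slice carries a latitudinal
#' temperature gradient; the global mean annual temperature decreases toward
#' the present at `cooling_slope` degrees C per My. Precipitation and
#' elevation fields are spatially autocorrelated (smoothed noise).
#'
#' @param n_slices number of slices (oldest to present).
#' @param cooling_slope degrees C per My.
#' @param seed integer seed.
#' @param slice_step My between slices (default 10, matching 10-My bins).
#' @param nlon,nlat grid size (defaults 36 x 18, i.e. 10-degree cells).
#' @param noise_sd sd of the per-slice temperature noise; 0 gives the pure
#'   deterministic construction.
#' @return list of `climate_slice` objects (fields `age`, `lon`, `lat`,
#'   `vars`: 11 named matrices), oldest first; class `climate_history`.
#' @export
simulate_climate_history <- function(n_slices, cooling_slope, seed = 1L,
                                     slice_step = 10, nlon = 36L, nlat = 18L,
                                     noise_sd = 0.5) {
  stopifnot(n_slices >= 1)
  set.seed(seed)
  lat <- seq(-90 + 180 / nlat / 2, 90 - 180 / nlat / 2, length.out = nlat)
  lon <- seq(-180 + 360 / nlon / 2, 180 - 360 / nlon / 2, length.out = nlon)
  latm <- matrix(lat, nlat, nlon)
  ages <- seq((n_slices - 1) * slice_step, 0, by = -slice_step)
  elev_base <- .smooth_field(nlat, nlon)  # static continents
  slices <- lapply(ages, function(a) {
    nz <- function(s = 1) if (noise_sd > 0)
      noise_sd * s * .smooth_field(nlat, nlon) else matrix(0, nlat, nlon)
    MAT <- 28 - 25 * sin(latm * pi / 180)^2 + cooling_slope * a + nz()
    TS <- pmax(4 + 18 * abs(latm) / 90 + nz(0.5), 0.1)
    MAP <- pmax(400 + 1400 * exp(-(latm / 25)^2) + 200 * nz(), 0)
    WMP <- pmax(0.30 * MAP * (1 + 0.1 * nz()), 0)
    DMP <- pmax(0.03 * MAP * (1 + 0.2 * nz()), 0)
    PS <- pmax(20 + 60 * abs(sin(latm * pi / 180)) + 5 * nz(), 0)
    EQ <- 30 - 0.8 * TS + nz()
    CI <- 10 + 1.5 * TS + nz()
    WMT <- MAT + TS / 2 + 0.2 * nz()
    CMT <- MAT - TS / 2 + 0.2 * nz()
    EL <- pmax(300 + 400 * elev_base + 50 * nz(), 0)
    structure(list(age = a, lon = lon, lat = lat,
                   vars = list(MAT = MAT, TS = TS, MAP = MAP, WMP = WMP,
                               DMP = DMP, PS = PS, EQ = EQ, CI = CI,
                               WMT = WMT, CMT = CMT, EL = EL)),
              class = "climate_slice")
  })
  structure(slices, class = "climate_history")
}

#' Global mean of a climate variable in one slice
#' @param slice a `climate_slice`.
#' @param var variable name (e.g. `"MAT"`).
#' @return mean over grid cells.
#' @export
slice_global_mean <- function(slice, var = "MAT") {
  mean(slice$vars[[var]])
}

#' Sample presence records from a planted suitability surface
#'
#' For each climate slice whose age lies within the tree span, cells are
#' sampled with probability proportional to `suitability` evaluated on the
#' cell environment; each record copies its cell's 11-variable environment
#' vector exactly and is assigned to a tip whose terminal branch spans the
#' slice age (nearest tip age as fallback).
#'
#' @param tree dated ape `phylo`.
#' @param climate a `climate_history`.
#' @param n_per_slice records drawn per slice.
#' @param suitability function(env data.frame of cells) -> nonnegative
#'   weights; default is a planted Gaussian niche in MAT centred at 15 C.
#' @param seed integer seed.
#' @return data.frame: taxon, status, lon, lat, paleo_lon, paleo_lat, age_ma,
#'   then the 11 environmental variables.
#' @export
simulate_occurrences <- function(tree, climate, n_per_slice = 30L,
                                 suitability = NULL, seed = 1L) {
  if (is.null(suitability))
    suitability <- function(env) stats::plogis((6 - env$MAT) / 2)
  set.seed(seed)
  ra <- root_age(tree)
  ages <- node_ages(tree)
  n_tip <- ape::Ntip(tree)
  tip_age <- ages[seq_len(n_tip)]
  parent_age <- ages[tree$edge[match(seq_len(n_tip), tree$edge[, 2L]), 1L]]
  recs <- list()
  for (slice in climate) {
    if (slice$age > ra + 1e-9) next
    env <- data.frame(lapply(slice$vars, as.vector))
    grid <- expand.grid(lat = slice$lat, lon = slice$lon,
                        KEEP.OUT.ATTRS = FALSE)  # column-major: lat fastest
    w <- suitability(env)
    if (!any(w > 0)) stop("empty suitable region in slice at ", slice$age,
                          " Ma")
    cells <- sample(length(w), n_per_slice, replace = TRUE, prob = w)
    alive <- which(tip_age <= slice$age + 1e-9 & parent_age >= slice$age - 1e-9)
    if (!length(alive)) alive <- which.min(abs(tip_age - slice$age))
    taxa <- tree$tip.label[sample(alive, n_per_slice, replace = TRUE)]
    status <- ifelse(slice$age > 0, "fossil", "extant")
    recs[[length(recs) + 1L]] <- cbind(
      data.frame(taxon = taxa, status = status, lon = grid$lon[cells],
                 lat = grid$lat[cells], paleo_lon = grid$lon[cells],
                 paleo_lat = grid$lat[cells], age_ma = slice$age,
                 stringsAsFactors = FALSE),
      env[cells, , drop = FALSE])
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Epoch-stratified realm adjacency history
#'
#' @param realms character vector of realm labels (<= 8).
#' @param epochs list of `list(start, end, m)`: start/end ages in Ma
#'   (start > end) and a symmetric multiplier matrix with entries in
#'   \{0.75, 0.5, 1e-6\} (adjacent / one barrier / two or more barriers).
#' @return a `realm_history` object.
#' @export
realm_history <- function(realms, epochs) {
  stopifnot(length(realms) <= 8, length(realms) >= 1)
  for (ep in epochs) {
    stopifnot(ep$start > ep$end, is.matrix(ep$m),
              nrow(ep$m) == length(realms), ncol(ep$m) == length(realms))
    if (max(abs(ep$m - t(ep$m))) > 1e-12) stop("multiplier matrix not symmetric")
  }
  starts <- vapply(epochs, `[[`, numeric(1), "start")
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  o <- order(starts, decreasing = TRUE)
  epochs <- epochs[o]
  if (any(abs(ends[o][-length(o)] - starts[o][-1L]) > 1e-9))
    stop("epochs must tile the time span without gaps or overlap")
  structure(list(realms = realms, epochs = epochs), class = "realm_history")
}

# Multiplier matrix in force at a given age. Epochs are half-open
# (end, start]; the youngest epoch also covers its end (usually 0 Ma).
epoch_at <- function(history, age) {
  eps <- history$epochs
  if (age > eps[[1L]]$start) return(eps[[1L]])
  for (ep in eps)
    if (age <= ep$start + 1e-9 && age > ep$end + 1e-9) return(ep)
  eps[[length(eps)]]
}

#' A plausible synthetic default realm history
#'
#' Three epochs over the tree span for up to eight realms (PA, OR, IN, SA,
#' AT, AU, NA, NT): a supercontinental phase with two connected blocks, a
#' fragmentation phase with many barriers, and a modern phase where the
#' northern realms reconnect and AU approaches OR. Entirely synthetic: no
#' attempt to mimic real plate rotations.
#'
#' @param root_age_ma span start, Ma.
#' @param n_realms how many of the 8 realm labels to use.
#' @return a `realm_history`.
#' @export
default_realm_history <- function(root_age_ma = 175, n_realms = 8L) {
  labs <- c("PA", "OR", "IN", "SA", "AT", "AU", "NA", "NT")[seq_len(n_realms)]
  n <- length(labs)
  mk <- function(pairs75, pairs50) {
    m <- matrix(1e-6, n, n, dimnames = list(labs, labs))
    set_ <- function(pairs, v) for (p in pairs)
      if (all(p %in% labs)) m[p[1], p[2]] <<- m[p[2], p[1]] <<- v
    set_(pairs75, 0.75); set_(pairs50, 0.5)
    diag(m) <- 1
    m
  }
  # Laurasia: PA-NA-OR; Gondwana: SA-AT-NT-AU-IN
  m1 <- mk(list(c("PA", "NA"), c("PA", "OR"), c("SA", "AT"), c("AT", "NT"),
                c("AT", "AU"), c("IN", "AU")),
           list(c("OR", "NA"), c("SA", "IN"), c("NT", "AU"), c("PA", "SA")))
  # fragmentation: Gondwana breaks up, IN adrift
  m2 <- mk(list(c("PA", "NA"), c("PA", "OR"), c("SA", "AT")),
           list(c("OR", "NA"), c("AT", "NT"), c("PA", "SA"), c("IN", "OR")))
  # modern: IN docked to PA/OR, AU near OR, Americas joined
  m3 <- mk(list(c("PA", "OR"), c("PA", "SA"), c("SA", "AT"), c("IN", "OR"),
                c("IN", "PA"), c("NA", "NT")),
           list(c("PA", "NA"), c("OR", "AU"), c("AT", "OR")))
  b1 <- min(max(root_age_ma * 0.55, 40), root_age_ma * 0.8)
  realm_history(labs, list(list(start = root_age_ma, end = b1, m = m1),
                           list(start = b1, end = 30, m = m2),
                           list(start = 30, end = 0, m = m3)))
}

#' Simulate a range history on the tree (ground truth for biogeography)
#'
#' Anagenetic gain/loss CTMC per branch with epoch-specific dispersal
#' multipliers; cladogenesis copies single-realm ranges to both daughters and
#' splits wider ranges at random (vicariance). An optional per-branch rate
#' modifier plants a coupling between a trait (wing length) and dispersal.
#'
#' @param tree dated ape `phylo`.
#' @param history a `realm_history`.
#' @param d,e dispersal and extirpation rates per My.
#' @param seed integer seed.
#' @param branch_modifier numeric vector over edge rows multiplying `d`
#'   (default all 1).
#' @param max_range_size largest simulated range.
#' @param root_realm index of the realm occupied at the root.
#' @return list: `tip_ranges` (named range strings, e.g. `"PA+OR"`),
#'   `node_ranges`, `events` data.frame of true dispersal events
#'   (age, from, to, realm gained).
#' @export
simulate_range_history <- function(tree, history, d = 0.02, e = 0.01,
                                   seed = 1L, branch_modifier = NULL,
                                   max_range_size = 2L, root_realm = 1L) {
  set.seed(seed)
  n <- length(history$realms)
  if (is.null(branch_modifier)) branch_modifier <- rep(1, nrow(tree$edge))
  n_tip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  state <- vector("list", n_tip + tree$Nnode)
  state[[n_tip + 1L]] <- root_realm
  events <- list()
  pre <- rev(ape::postorder(tree))
  for (ei in pre) {
    p <- tree$edge[ei, 1L]; ch <- tree$edge[ei, 2L]
    R <- state[[p]]
    # cladogenesis at the parent: decide this daughter's starting range
    if (length(R) > 1L) {
      # vicariance: deterministic-in-randomness split per node; split once
      # and cache on the parent so the two daughters get complementary parts
      key <- paste0("split", p)
      sp <- attr(state, key)
      if (is.null(sp)) {
        one <- sample(R, 1L)
        sp <- list(list(one), list(setdiff(R, one)))
        sp <- sample(sp)  # random side assignment
        attr(state, key) <- sp
        start <- sp[[1L]][[1L]]
      } else start <- sp[[2L]][[1L]]
    } else start <- R
    cur <- start
    t_now <- ages[p]; t_stop <- ages[ch]
    dmod <- d * branch_modifier[ei]
    while (t_now > t_stop + 1e-12) {
      m <- epoch_at(history, t_now)$m
      seg_end <- max(t_stop, epoch_at(history, t_now)$end)
      gain_r <- if (length(cur) < max_range_size) {
        vapply(seq_len(n), function(b) {
          if (b %in% cur) 0 else dmod * sum(m[cur, b])
        }, numeric(1))
      } else rep(0, n)
      loss_r <- if (length(cur) > 1L) rep(e, length(cur)) else numeric(0)
      tot <- sum(gain_r) + sum(loss_r)
      if (tot <= 0) { t_now <- seg_end; if (seg_end <= t_stop + 1e-12) break; next }
      wait <- rexp(1, tot)
      if (t_now - wait < seg_end) { t_now <- seg_end
        if (seg_end <= t_stop + 1e-12) break else next }
      t_now <- t_now - wait
      if (runif(1) < sum(gain_r) / tot) {
        b <- sample(n, 1L, prob = gain_r)
        events[[length(events) + 1L]] <- data.frame(
          age = t_now, from = paste(history$realms[cur], collapse = "+"),
          to = paste(history$realms[sort(c(cur, b))], collapse = "+"),
          realm = history$realms[b], stringsAsFactors = FALSE)
        cur <- sort(c(cur, b))
      } else {
        a <- if (length(cur) == 1L) cur else sample(cur, 1L)
        cur <- setdiff(cur, a)
      }
    }
    state[[ch]] <- cur
  }
  fmt <- function(idx) paste(history$realms[idx], collapse = "+")
  labs <- node_labels(tree)
  tips <- vapply(seq_len(n_tip), function(i) fmt(state[[i]]), character(1))
  names(tips) <- labs[seq_len(n_tip)]
  nodes <- vapply(n_tip + seq_len(tree$Nnode), function(i) fmt(state[[i]]),
                  character(1))
  names(nodes) <- labs[n_tip + seq_len(tree$Nnode)]
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(age = numeric(0), from = character(0), to = character(0),
               realm = character(0))
  list(tip_ranges = tips, node_ranges = nodes, events = ev)
}

#' Assemble a complete synthetic scenario
#'
#' Ties every generator together under one seed: FBD tree, Brownian niche
#' trait and trended wing length (with node ground truth), Mk wing shape,
#' cooling climate history, presence records, realm history, a range history
#' whose dispersal rate is log-linearly coupled to wing length
#' (`coupling_beta`), and atmospheric records.
#'
#' @param cfg a [sim_config()].
#' @param n_per_slice occurrence records per climate slice.
#' @param n_atmo number of atmospheric habitat records.
#' @return a `dn_scenario` list.
#' @export
simulate_scenario <- function(cfg = sim_config(), n_per_slice = 30L,
                              n_atmo = 60L) {
  tree <- simulate_fbd_tree(cfg)
  ra <- root_age(tree)
  wl_all <- simulate_bm_trait(tree, cfg$bm_sigma2, cfg$wl_root,
                              seed = cfg$seed + 11L, drift = cfg$wl_drift)
  wl_all <- pmax(wl_all, 0.5)
  niche_all <- simulate_bm_trait(tree, cfg$bm_sigma2 * 4, 15,
                                 seed = cfg$seed + 13L)
  shape_all <- simulate_mk_trait(tree, 0.004, seed = cfg$seed + 17L)
  n_slices <- floor(ra / 10) + 1L
  climate <- simulate_climate_history(n_slices, cfg$cooling_slope,
                                      seed = cfg$seed + 19L)
  occ <- simulate_occurrences(tree, climate, n_per_slice,
                              seed = cfg$seed + 23L)
  history <- default_realm_history(ra, cfg$n_realms)
  # plant wing-length -> dispersal coupling through a per-branch rate factor
  ages <- node_ages(tree)
  mid_wl <- (wl_all[tree$edge[, 1L]] + wl_all[tree$edge[, 2L]]) / 2
  mod <- exp(cfg$coupling_beta * (mid_wl - mean(wl_all)))
  ranges <- simulate_range_history(tree, history, d = 0.015, e = 0.005,
                                   seed = cfg$seed + 29L,
                                   branch_modifier = mod)
  set.seed(cfg$seed + 31L)
  Tk <- rnorm(n_atmo, 288, 8)
  P <- rnorm(n_atmo, 101325, 600)
  Pv <- pmin(runif(n_atmo, 0, 0.9) * 2500, 0.9 * P)
  v <- exp(rnorm(n_atmo, log(3), 0.4))
  atmo <- data.frame(P = P, Pv = Pv, T = Tk, v = v)
  atmo$rho <- air_density(atmo$P, atmo$Pv, atmo$T)
  atmo$mu <- air_viscosity(atmo$T)
  n_tip <- ape::Ntip(tree)
  scen <- structure(list(
    cfg = cfg, tree = tree,
    traits = list(wing_length = wl_all[seq_len(n_tip)],
                  niche = niche_all[seq_len(n_tip)]),
    truth = list(wing_length = wl_all, niche = niche_all,
                 wing_shape = shape_all, range_events = ranges$events,
                 node_ranges = ranges$node_ranges),
    wing_shape = shape_all[seq_len(n_tip)],
    occurrences = occ, climate = climate, realm_history = history,
    tip_ranges = ranges$tip_ranges, atmo = atmo), class = "dn_scenario")
  stopifnot(all(scen$occurrences$taxon %in% tree$tip.label),
            max(scen$occurrences$age_ma) <= climate[[1L]]$age + 1e-9)
  scen
}

#' Write a scenario to plain-text files
#'
#' Newick tree, CSV tables (occurrences, traits, tip ranges, atmospheric
#' records), one ESRI-ASCII-style grid per variable per slice, a key-value
#' config file, and the realm history as CSV matrices.
#'
#' @param scen a `dn_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(scen$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(scen$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  tr <- data.frame(taxon = names(scen$traits$wing_length),
                   wing_length = unname(scen$traits$wing_length),
                   niche = unname(scen$traits$niche),
                   wing_shape = unname(scen$wing_shape))
  utils::write.csv(tr, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(data.frame(taxon = names(scen$tip_ranges),
                              range = unname(scen$tip_ranges)),
                   file.path(dir, "tip_ranges.csv"), row.names = FALSE)
  utils::write.csv(scen$atmo, file.path(dir, "atmo.csv"), row.names = FALSE)
  for (slice in scen$climate) for (v in names(slice$vars))
    write_ascii_grid(slice$vars[[v]], slice$lon, slice$lat,
                     file.path(dir, sprintf("climate_%03d_%s.asc",
                                            round(slice$age), v)))
  for (i in seq_along(scen$realm_history$epochs)) {
    ep <- scen$realm_history$epochs[[i]]
    utils::write.csv(ep$m, file.path(dir, sprintf("realm_epoch_%d.csv", i)))
  }
  cfgl <- scen$cfg
  writeLines(paste(names(cfgl),
                   vapply(cfgl, function(x) paste(format(x), collapse = " "),
                          character(1)), sep = " = "),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write one grid as an ESRI-ASCII raster
#' @param m matrix (rows = latitudes south to north, cols = longitudes).
#' @param lon,lat cell-centre coordinates.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, lon, lat, path) {
  cs <- if (length(lon) > 1) lon[2] - lon[1] else 1
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", min(lon) - cs / 2),
           paste("yllcorner", min(lat) - cs / 2),
           paste("cellsize", cs), "NODATA_value -9999")
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1L, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI-ASCII raster written by [write_ascii_grid()]
#' @param path file path.
#' @return list with `m`, `lon`, `lat`.
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:6], " +")
  hv <- setNames(as.numeric(vapply(hdr, `[[`, character(1), 2L)),
                 tolower(vapply(hdr, `[[`, character(1), 1L)))
  body <- do.call(rbind, lapply(ln[-(1:6)],
                                function(s) as.numeric(strsplit(s, " +")[[1]])))
  m <- body[rev(seq_len(nrow(body))), , drop = FALSE]
  lon <- hv["xllcorner"] + hv["cellsize"] * (seq_len(hv["ncols"]) - 0.5)
  lat <- hv["yllcorner"] + hv["cellsize"] * (seq_len(hv["nrows"]) - 0.5)
  list(m = m, lon = unname(lon), lat = unname(lat))
}
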