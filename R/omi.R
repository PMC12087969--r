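# Outlying Mean Index analysis: niche position (marginality) and niche
# breadth (tolerance) per species from a site-by-environment table and a
# species-by-site abundance table, plus the two time-binning aggregation
# schemes used to trace both through the clade's history.

#' Outlying Mean Index analysis
#'
#' The environment table is centred and standardized using site weights
#' proportional to total abundance per site. For each species, the
#' abundance-weighted centroid of its used sites is computed in that
#' standardized space: the marginality (niche position, NP) is the squared
#' distance of the centroid from the origin (the average environment), and
#' the tolerance (niche breadth, NB) is the abundance-weighted variance of
#' the used sites around the centroid. Canonical weights come from the
#' eigen-decomposition of the species-weighted marginality cross-product
#' matrix.
#'
#' @param site_env sites x variables table.
#' @param abundance species x sites nonnegative table (rows may be named).
#' @return an `omi_result`: per-species `NP`, `NB` (= `tol` + `rtol`),
#'   `inertia`, `centroids`, `canonical_weights`, `eigenvalues`,
#'   `site_scores`, `species_scores`, `site_weights`.
#' @export
omi <- function(site_env, abundance) {
  Z0 <- as.matrix(site_env)
  A <- as.matrix(abundance)
  stopifnot(ncol(A) == nrow(Z0), all(A >= 0))
  if (is.null(rownames(A))) rownames(A) <- paste0("sp", seq_len(nrow(A)))
  tot <- rowSums(A)
  if (any(tot == 0)) {
    warning("excluding species with zero total abundance: ",
            paste(rownames(A)[tot == 0], collapse = ", "))
    A <- A[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(A)) stop("no species with positive abundance")
  sw <- colSums(A) / sum(A)                 # site weights
  mu <- drop(sw %*% Z0)
  sd_w <- sqrt(drop(sw %*% sweep(Z0, 2L, mu)^2))
  sd_w[sd_w == 0] <- 1
  Z <- sweep(sweep(Z0, 2L, mu), 2L, sd_w, "/")  # standardized environment
  prof <- sweep(A, 1L, tot, "/")            # species site profiles
  centroids <- prof %*% Z
  NP <- rowSums(centroids^2)
  inertia <- drop(prof %*% rowSums(Z^2))
  NB <- inertia - NP                        # total weighted variance
  spw <- tot / sum(tot)                     # species weights
  M <- crossprod(centroids * sqrt(spw))     # marginality cross-product
  eig <- eigen(M, symmetric = TRUE)
  cw <- eig$vectors
  rownames(cw) <- colnames(Z0)
  colnames(cw) <- paste0("OMI", seq_len(ncol(cw)))
  # per-species variance along the first canonical axes (tol) vs residual
  ax1 <- cw[, 1L]
  tol <- vapply(seq_len(nrow(A)), function(s) {
    dev <- sweep(Z, 2L, centroids[s, ])
    proj <- drop(dev %*% ax1)
    sum(prof[s, ] * proj^2)
  }, numeric(1))
  structure(list(NP = setNames(NP, rownames(A)),
                 NB = setNames(NB, rownames(A)),
                 tol = setNames(tol, rownames(A)),
                 rtol = setNames(NB - tol, rownames(A)),
                 inertia = setNames(inertia, rownames(A)),
                 centroids = centroids, canonical_weights = cw,
                 eigenvalues = eig$values,
                 site_scores = Z %*% cw, species_scores = centroids %*% cw,
                 site_weights = sw, species_weights = spw),
            class = "omi_result")
}

#' Time-bin schemes for through-time aggregation
#'
#' Two schemes: `"sixteen"` uses 10-My bins throughout except the 105-65 Ma
#' window, which is covered by two 20-My bins (sparse record interval); the
#' 10-My edges are anchored at ...115, 105 above the window and 65, 55, ...,
#' 5, 0 below it, topped by the root age, which yields exactly 16 bins for a
#' 170-0 Ma span. `"five"` uses five geochronological intervals with default
#' boundaries at 145, 100, 66 and 23 Ma (configurable; the exact interval
#' table is a data-dependent choice).
#'
#' @param root_age_ma span start, Ma (> 65).
#' @param scheme `"sixteen"` or `"five"`.
#' @param five_edges optional custom descending edges for the five-interval
#'   scheme (length 6, from `root_age_ma` to 0).
#' @return a `bin_scheme`: descending `edges` (Ma) and `labels`; bins are
#'   half-open `[older, younger)` and labelled by their older edge.
#' @export
bin_scheme <- function(root_age_ma, scheme = c("sixteen", "five"),
                       five_edges = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(root_age_ma > 65)
  if (scheme == "five") {
    edges <- if (!is.null(five_edges)) five_edges else
      c(root_age_ma, 145, 100, 66, 23, 0)
    edges <- sort(unique(pmin(edges, root_age_ma)), decreasing = TRUE)
  } else {
    upper <- if (root_age_ma > 105)
      seq(105, root_age_ma - 1e-9, by = 10) else numeric(0)  # 105, 115, ...
    mid <- c(85, 65)
    edges <- c(root_age_ma, rev(upper), mid[mid < root_age_ma],
               seq(55, 5, by = -10), 0)
    edges <- sort(unique(edges), decreasing = TRUE)
  }
  structure(list(edges = edges,
                 labels = paste0(head(edges, -1), "-", tail(edges, -1), "Ma"),
                 scheme = scheme),
            class = "bin_scheme")
}

#' Number of bins in a scheme
#' @param scheme a `bin_scheme`.
#' @return integer.
#' @export
n_bins <- function(scheme) length(scheme$edges) - 1L

#' Assign ages to bins
#'
#' Half-open convention: a record at exactly an edge age goes to the bin
#' whose *older* edge it is.
#'
#' @param ages_ma numeric ages.
#' @param scheme a `bin_scheme`.
#' @return integer bin index (1 = oldest) or NA outside the span.
#' @export
assign_bin <- function(ages_ma, scheme) {
  e <- scheme$edges
  idx <- rep(NA_integer_, length(ages_ma))
  for (b in seq_len(length(e) - 1L))
    idx[ages_ma <= e[b] & ages_ma > e[b + 1L]] <- b
  idx[ages_ma == e[length(e)]] <- length(e) - 1L
  idx
}

#' Niche position and breadth through time
#'
#' Runs an OMI analysis independently within each time bin of a scheme.
#' Records are occurrence rows with an age, a site (grid cell) id, a species
#' id and environment columns; abundance is the record count per species and
#' site within the bin. Bins with fewer than `min_records` records or fewer
#' than 2 distinct sites are reported as undefined (NA), never fabricated.
#'
#' @param records data.frame with columns `age_ma`, `taxon`, a `site`
#'   identifier, and the environment variables named in `env_vars`.
#' @param scheme a [bin_scheme()].
#' @param env_vars character vector of environment column names.
#' @param min_records minimum records per bin (default 2).
#' @return data.frame per bin: label, n records, `NP_centroid` (mean species
#'   marginality), `NP_centroid_dist` (marginality of the bin's pooled
#'   centroid), `NB` (mean species tolerance); plus the per-bin `omi_result`s
#'   as the `"omi"` attribute.
#' @export
np_nb_through_time <- function(records, scheme, env_vars,
                               min_records = 2L) {
  stopifnot(all(env_vars %in% names(records)))
  if (!"site" %in% names(records))
    records$site <- interaction(records$lon, records$lat, records$age_ma,
                                drop = TRUE)
  bins <- assign_bin(records$age_ma, scheme)
  if (anyNA(bins)) stop("records outside the bin-scheme span")
  out <- data.frame(bin = seq_len(n_bins(scheme)),
                    label = scheme$labels, n = 0L, NP_centroid = NA_real_,
                    NP_pooled = NA_real_, NB = NA_real_)
  fits <- vector("list", n_bins(scheme))
  for (b in seq_len(n_bins(scheme))) {
    rb <- records[which(bins == b), , drop = FALSE]
    out$n[b] <- nrow(rb)
    if (nrow(rb) < min_records) next
    site <- factor(as.character(rb$site))
    if (nlevels(site) < 2L) next
    sp <- factor(as.character(rb$taxon))
    A <- table(sp, site)
    env <- aggregate(rb[env_vars], by = list(site = site), FUN = mean)
    Z <- as.matrix(env[match(colnames(A), env$site), env_vars, drop = FALSE])
    keepv <- apply(Z, 2L, function(v) sd(v) > 0)
    if (sum(keepv) < 1L) next
    fit <- omi(Z[, keepv, drop = FALSE], unclass(A))
    fits[[b]] <- fit
    out$NP_centroid[b] <- mean(fit$NP)
    pooled <- colSums(fit$centroids * fit$species_weights)
    out$NP_pooled[b] <- sum(pooled^2)
    out$NB[b] <- mean(fit$NB)
  }
  attr(out, "omi") <- fits
  out
}
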