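# Habitability projection: per-bin niche thresholds mapped onto climate
# slices, partitioned into habitable / habitable-but-inaccessible /
# uninhabitable cells using realm reachability through the epoch's
# dispersal-multiplier graph.

#' Project niche thresholds onto a climate slice
#'
#' A cell is habitable for a variable iff its value lies inside the
#' \[min, max\] threshold for the bin; with several variables the masks are
#' intersected. Single-variable mode (habitat mean annual temperature, as
#' in the deep-time habitability maps) is the default.
#'
#' @param thresholds named list `variable -> c(min, max)` for one bin.
#' @param slice a `climate_slice`.
#' @return logical matrix, TRUE = habitable.
#' @export
project_thresholds <- function(thresholds, slice) {
  vars <- names(thresholds)
  missing_vars <- setdiff(vars, names(slice$vars))
  if (length(missing_vars))
    stop("slice is missing variable(s): ", paste(missing_vars, collapse = ", "))
  mask <- matrix(TRUE, nrow(slice$vars[[1L]]), ncol(slice$vars[[1L]]))
  for (v in vars) {
    th <- thresholds[[v]]
    mask <- mask & slice$vars[[v]] >= th[1] & slice$vars[[v]] <= th[2]
  }
  mask
}

# Realms reachable from `occupied` over edges with multiplier > cutoff.
.reachable_realms <- function(m, occupied, cutoff = 1e-6) {
  n <- nrow(m)
  seen <- logical(n)
  seen[occupied] <- TRUE
  frontier <- occupied
  while (length(frontier)) {
    nxt <- which(apply(m[frontier, , drop = FALSE] > cutoff, 2L, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Partition habitable cells by accessibility
#'
#' Habitable cells lying in realms reachable from the occupied realms
#' through adjacency edges whose dispersal multiplier exceeds the barrier
#' cutoff stay `habitable`; habitable cells beyond every such path are
#' `inaccessible`; everything else is `uninhabitable`. Reachability is
#' graph traversal on the epoch's multiplier matrix.
#'
#' @param habitable logical matrix from [project_thresholds()].
#' @param realm_map integer matrix (same shape) of realm indices per cell;
#'   NA = sea (excluded from land classes).
#' @param occupied_realms integer/character realms occupied in the bin.
#' @param history a `realm_history`.
#' @param age_ma bin age, picks the epoch.
#' @param barrier_cutoff edges at or below this multiplier are severed
#'   (default 1e-6, the "two or more barriers" class).
#' @return a `habitability_map`: `class` character matrix in
#'   \{habitable, inaccessible, uninhabitable\} (NA over sea),
#'   `area_fractions` (sums to 1 over land), `reachable` realm indices.
#' @export
partition_accessibility <- function(habitable, realm_map, occupied_realms,
                                    history, age_ma,
                                    barrier_cutoff = 1e-6) {
  m <- epoch_at(history, age_ma)$m
  if (is.character(occupied_realms))
    occupied_realms <- match(occupied_realms, history$realms)
  occupied_realms <- occupied_realms[!is.na(occupied_realms)]
  if (!length(occupied_realms)) {
    warning("no occupied realm: all habitable cells are inaccessible")
    reach <- integer(0)
  } else {
    reach <- .reachable_realms(m, occupied_realms, barrier_cutoff)
  }
  cls <- matrix(NA_character_, nrow(habitable), ncol(habitable))
  land <- !is.na(realm_map)
  cls[land] <- "uninhabitable"
  hab <- land & habitable
  cls[hab] <- ifelse(realm_map[hab] %in% reach, "habitable", "inaccessible")
  counts <- table(factor(cls[land],
                         c("habitable", "inaccessible", "uninhabitable")))
  fr <- as.numeric(counts) / max(sum(counts), 1L)
  names(fr) <- names(counts)
  structure(list(class = cls, area_fractions = fr, reachable = reach,
                 age = age_ma),
            class = "habitability_map")
}

#' A synthetic realm map for a grid
#'
#' Deterministically tiles the grid into `n_realms` longitude-latitude
#' blocks (northern realms in the northern hemisphere), so habitability
#' partitions can be exercised without real coastlines. Cells are all land.
#'
#' @param nlat,nlon grid shape.
#' @param n_realms number of realms (<= 8).
#' @return integer matrix of realm indices.
#' @export
synthetic_realm_map <- function(nlat, nlon, n_realms = 8L) {
  ncol_blocks <- ceiling(n_realms / 2)
  north <- matrix(rep(seq_len(ncol_blocks),
                      each = ceiling(nlon / ncol_blocks))[seq_len(nlon)],
                  nlat %/% 2, nlon, byrow = TRUE)
  south_ids <- ((seq_len(ncol_blocks) + ncol_blocks - 1L) %% n_realms) + 1L
  south <- matrix(rep(south_ids,
                      each = ceiling(nlon / ncol_blocks))[seq_len(nlon)],
                  nlat - nlat %/% 2, nlon, byrow = TRUE)
  rbind(south, north)  # row 1 = southernmost latitude
}
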