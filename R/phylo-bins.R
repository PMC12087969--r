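# Through-time summaries on the tree: length-weighted branch means per time
# bin, per-bin niche thresholds (ecological min/max), lineage-through-time
# curves, and a contrast-based rate-through-time proxy.

#' Uniform time bins
#'
#' Convenience constructor for evenly spaced bins (e.g. the 1-My bins the
#' dispersal-frequency series uses).
#'
#' @param root_age_ma span start, Ma.
#' @param width bin width in My.
#' @return a `bin_scheme`.
#' @export
uniform_bins <- function(root_age_ma, width = 1) {
  edges <- unique(c(seq(ceiling(root_age_ma / width) * width, 0, by = -width), 0))
  edges[1] <- max(edges[1], root_age_ma)
  structure(list(edges = edges,
                 labels = paste0(head(edges, -1), "-", tail(edges, -1), "Ma"),
                 scheme = "uniform"),
            class = "bin_scheme")
}

# Per-edge endpoint ages and trait values from a full tips+nodes vector.
.edge_segments <- function(tree, values) {
  ages <- node_ages(tree)
  v <- values[node_labels(tree)]
  if (anyNA(v)) stop("values must cover every tip and internal node")
  data.frame(age_top = ages[tree$edge[, 1L]], age_bot = ages[tree$edge[, 2L]],
             v_top = as.numeric(v[tree$edge[, 1L]]),
             v_bot = as.numeric(v[tree$edge[, 2L]]))
}

#' Length-weighted branch means per time bin
#'
#' Each branch is linearly interpolated between its endpoint values (tip or
#' reconstructed node); the per-bin mean is the branch-length-weighted
#' average of the segment portions falling inside the bin.
#'
#' @param tree dated ape `phylo`.
#' @param values named vector over tips and internal nodes (tips + ASR).
#' @param scheme a [bin_scheme()] / [uniform_bins()].
#' @return data.frame per bin: `label`, `total_length` (My of branch in the
#'   bin), `mean` (NA for bins with no branch, e.g. beyond the root).
#' @export
branch_bin_means <- function(tree, values, scheme) {
  seg <- .edge_segments(tree, values)
  e <- scheme$edges
  nb <- length(e) - 1L
  wsum <- numeric(nb); vsum <- numeric(nb)
  for (i in seq_len(nrow(seg))) {
    at <- seg$age_top[i]; ab <- seg$age_bot[i]
    if (at - ab <= 0) next
    for (b in seq_len(nb)) {
      hi <- min(at, e[b]); lo <- max(ab, e[b + 1L])
      if (hi <= lo) next
      midv <- seg$v_bot[i] +
        (seg$v_top[i] - seg$v_bot[i]) * ((hi + lo) / 2 - ab) / (at - ab)
      wsum[b] <- wsum[b] + (hi - lo)
      vsum[b] <- vsum[b] + (hi - lo) * midv
    }
  }
  data.frame(bin = seq_len(nb), label = scheme$labels,
             total_length = wsum,
             mean = ifelse(wsum > 0, vsum / wsum, NA_real_))
}

#' Per-bin niche thresholds (ecological min/max)
#'
#' For each bin, the minimum and maximum of the trait over every branch
#' portion and tip present in the bin. Linear segments attain their extremes
#' at interval endpoints, so the thresholds are exact.
#'
#' @inheritParams branch_bin_means
#' @return data.frame per bin: `label`, `min`, `max` (NA for empty bins).
#' @export
niche_thresholds_by_bin <- function(tree, values, scheme) {
  seg <- .edge_segments(tree, values)
  e <- scheme$edges
  nb <- length(e) - 1L
  mn <- rep(NA_real_, nb); mx <- rep(NA_real_, nb)
  val_at <- function(i, t) {
    at <- seg$age_top[i]; ab <- seg$age_bot[i]
    if (at == ab) return(seg$v_bot[i])
    seg$v_bot[i] + (seg$v_top[i] - seg$v_bot[i]) * (t - ab) / (at - ab)
  }
  for (i in seq_len(nrow(seg))) {
    at <- seg$age_top[i]; ab <- seg$age_bot[i]
    for (b in seq_len(nb)) {
      hi <- min(at, e[b]); lo <- max(ab, e[b + 1L])
      inc_lo <- ab == e[b + 1L] && b == nb # closed youngest edge
      if (hi < lo || (hi == lo && !inc_lo)) next
      vals <- c(val_at(i, hi), val_at(i, lo))
      mn[b] <- min(mn[b], vals, na.rm = TRUE)
      mx[b] <- max(mx[b], vals, na.rm = TRUE)
    }
  }
  data.frame(bin = seq_len(nb), label = scheme$labels, min = mn, max = mx)
}

#' Lineage-through-time curve
#'
#' Count of lineages crossing each time point, stepping up at every
#' branching. With `count_extinct = TRUE` fossil tips (age > 0) decrement
#' the count at their age, giving the complete-process curve.
#'
#' @param tree dated ape `phylo`.
#' @param count_extinct decrement at fossil tip deaths (default FALSE).
#' @return data.frame: `age` (Ma, decreasing) and `lineages` after the
#'   event at that age.
#' @export
ltt <- function(tree, count_extinct = FALSE) {
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  ev <- data.frame(age = ages[n + seq_len(tree$Nnode)], d = +1L)
  if (count_extinct) {
    fos <- which(ages[seq_len(n)] > 0)
    if (length(fos))
      ev <- rbind(ev, data.frame(age = ages[fos], d = -1L))
  }
  ev <- ev[order(-ev$age, -ev$d), , drop = FALSE]
  data.frame(age = ev$age, lineages = 1L + cumsum(ev$d))
}

#' Contrast-based evolutionary-rate proxy through time
#'
#' Squared standardized phylogenetically independent contrasts, each
#' anchored at the age of its node, averaged per time bin with a bootstrap
#' CI. Under constant-rate BM the curve is flat at sigma2; an early burst
#' shows as a declining curve. This is a deliberately simple stand-in for
#' full rate-shift inference, and is labelled as a proxy in the output.
#'
#' @param tree dated ape `phylo` (n >= 10).
#' @param x named trait vector over tips.
#' @param scheme a [bin_scheme()].
#' @param n_boot bootstrap replicates for the CI (default 200).
#' @param seed integer seed.
#' @return data.frame per bin: `label`, `n` contrasts, `rate` (mean squared
#'   contrast), `lo`, `hi` (95% bootstrap CI), plus attribute
#'   `"proxy" = "squared standardized contrasts"`.
#' @export
rate_through_time_proxy <- function(tree, x, scheme, n_boot = 200L,
                                    seed = 1L) {
  x <- match_tips(tree, x)
  stopifnot(length(x) >= 10)
  names(x) <- tree$tip.label
  pic <- ape::pic(x, tree)
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)[n + seq_len(tree$Nnode)]
  s2 <- pic^2
  bins <- assign_bin(ages, scheme)
  set.seed(seed)
  nb <- n_bins(scheme)
  out <- data.frame(bin = seq_len(nb), label = scheme$labels, n = 0L,
                    rate = NA_real_, lo = NA_real_, hi = NA_real_)
  for (b in seq_len(nb)) {
    v <- s2[which(bins == b)]
    out$n[b] <- length(v)
    if (!length(v)) next
    out$rate[b] <- mean(v)
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(sample(v, replace = TRUE)), numeric(1))
    q <- quantile(bm, c(0.025, 0.975), names = FALSE)
    out$lo[b] <- q[1]; out$hi[b] <- q[2]
  }
  attr(out, "proxy") <- "squared standardized contrasts"
  out
}
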