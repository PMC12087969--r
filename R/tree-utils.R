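# Shared helpers for dated trees. Trees are ape "phylo" objects with branch
# lengths in My; ages are Ma before present. The root age is taken as the
# maximum root-to-tip path length (i.e. at least one tip is extant) unless the
# tree carries a "root_age" attribute.

#' Node ages of a dated tree
#'
#' Ages (Ma before present) for every tip and internal node. Tips at age 0
#' are extant; tips at positive age are fossils.
#'
#' @param tree an ape `phylo` with branch lengths in My.
#' @return numeric vector of length `Ntip + Nnode`, in ape node order.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  root_age <- attr(tree, "root_age")
  if (is.null(root_age)) root_age <- max(depths)
  ages <- root_age - depths
  ages[abs(ages) < 1e-9] <- 0
  ages
}

#' Root age of a dated tree
#' @param tree an ape `phylo`.
#' @return age of the root in Ma.
#' @export
root_age <- function(tree) {
  ra <- attr(tree, "root_age")
  if (is.null(ra)) ra <- max(ape::node.depth.edgelength(tree))
  ra
}

# Shared-path-length (Brownian covariance) matrix for an arbitrary set of
# nodes. Entry (i, j) is the depth of the MRCA of nodes i and j measured from
# the root; the diagonal is each node's own depth. Works for non-ultrametric
# trees (fossil tips) and for internal nodes.
full_vcv <- function(tree, nodes = NULL) {
  n_tip <- ape::Ntip(tree)
  if (is.null(nodes)) nodes <- seq_len(n_tip)
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  mat <- matrix(depths[mr[nodes, nodes, drop = FALSE]],
                nrow = length(nodes), ncol = length(nodes))
  labs <- node_labels(tree)[nodes]
  dimnames(mat) <- list(labs, labs)
  mat
}

node_labels <- function(tree) {
  n_tip <- ape::Ntip(tree)
  nl <- tree$node.label
  if (is.null(nl) || !length(nl)) nl <- paste0("node", n_tip + seq_len(tree$Nnode))
  c(tree$tip.label, nl)
}

# Match a named trait vector to the tree's tips; error on missing tips.
match_tips <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree))
      stop("trait vector has no names and wrong length")
    return(as.numeric(x))
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("missing trait values for tips: ",
                         paste(head(miss, 5), collapse = ", "))
  as.numeric(x[tree$tip.label])
}

# Profiled Brownian-motion ML log-likelihood for a trait x with covariance
# proportional to C (mean = mu * 1 profiled analytically, sigma2 profiled
# analytically). Returns logL, mu-hat, sigma2-hat. Cholesky-based; returns
# -Inf for a non-positive-definite C.
bm_loglik_C <- function(C, x) {
  n <- length(x)
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) return(list(logL = -Inf, mu = NA_real_, sigma2 = NA_real_))
  # solve C^{-1} v through the factorization
  ones <- rep(1, n)
  Ci_x <- backsolve(L, forwardsolve(t(L), x))
  Ci_1 <- backsolve(L, forwardsolve(t(L), ones))
  s11 <- sum(ones * Ci_1)
  mu <- sum(ones * Ci_x) / s11
  r <- x - mu
  Ci_r <- Ci_x - mu * Ci_1
  Q <- sum(r * Ci_r)
  if (Q <= 0) Q <- .Machine$double.eps
  sigma2 <- Q / n
  logdetC <- 2 * sum(log(diag(L)))
  logL <- -0.5 * n * log(2 * pi * sigma2) - 0.5 * logdetC - 0.5 * n
  list(logL = logL, mu = mu, sigma2 = sigma2, logdetC = logdetC, s11 = s11)
}

# Generalized least squares under covariance C: y = X b + e, e ~ N(0, s2 C).
gls_fit <- function(X, y, C) {
  L <- chol(C)
  Xi <- backsolve(L, forwardsolve(t(L), X))
  yi <- backsolve(L, forwardsolve(t(L), y))
  XtCiX <- crossprod(X, Xi)
  XtCiy <- crossprod(X, yi)
  XtCiX_inv <- solve(XtCiX)
  beta <- drop(XtCiX_inv %*% XtCiy)
  resid <- drop(y - X %*% beta)
  Ci_r <- backsolve(L, forwardsolve(t(L), resid))
  rss <- sum(resid * Ci_r)
  n <- length(y); p <- ncol(X)
  s2 <- rss / (n - p)
  se <- sqrt(diag(XtCiX_inv) * s2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  list(coefficients = beta, se = se, t = tval, p = pval, sigma2 = s2,
       df = n - p, rss = rss)
}
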