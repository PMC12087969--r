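# Small fixed trees and generators shared across tests.

toy_tree <- function() {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:0.5):0.5);")
  attr(tr, "root_age") <- 2
  tr
}

# Random pure-birth tree with n extant tips, unit-ish depth, via ape.
pb_tree <- function(n, birth = 0.1) {
  ape::rphylo(n, birth = birth, death = 0)
}

# Naive multivariate-normal ML log-likelihood (solve/det route), the
# independent oracle against the package's Cholesky-based profiling.
mvn_profile_loglik <- function(C, x) {
  n <- length(x)
  Ci <- solve(C)
  ones <- rep(1, n)
  mu <- sum(Ci %*% x) / sum(Ci)
  r <- x - mu
  Q <- drop(t(r) %*% Ci %*% r)
  s2 <- Q / n
  -0.5 * n * log(2 * pi * s2) - 0.5 * determinant(C)$modulus[1] - 0.5 * n
}
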