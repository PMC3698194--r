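# Independent brute-force oracles used to validate the fast implementations.
# These deliberately re-derive everything from first principles and stay
# naive: path enumeration for covariances, exhaustive sums over internal
# state assignments for likelihood and parsimony, and direct numerical
# likelihood maximization for GLS.

# edges on the root-to-node path, as row indices of tree$edge
path_edges <- function(tree, node) {
  e <- tree$edge
  out <- integer(0)
  repeat {
    r <- which(e[, 2] == node)
    if (!length(r)) break
    out <- c(out, r)
    node <- e[r, 1]
  }
  out
}

# covariance by explicit intersection of root paths
bf_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  paths <- lapply(seq_len(ntip), function(i) path_edges(tree, i))
  V <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  V
}

# Mk1 likelihood by summing over all internal-state assignments
bf_mk1_lik <- function(tree, states, q, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- as.integer(states[tree$tip.label])
  pswitch <- function(t) (1 - exp(-2 * q * t)) / 2
  total <- 0
  for (code in 0:(2^nnode - 1)) {
    assign <- c(states, as.integer(intToBits(code))[seq_len(nnode)])
    pr <- prior[assign[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign[tree$edge[e, 1]]; b <- assign[tree$edge[e, 2]]
      ps <- pswitch(tree$edge.length[e])
      pr <- pr * if (a == b) 1 - ps else ps
    }
    total <- total + pr
  }
  total
}

# Mk1 marginal (unnormalized) likelihood of each state at one node
bf_mk1_marginal <- function(tree, states, q, node, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- as.integer(states[tree$tip.label])
  pswitch <- function(t) (1 - exp(-2 * q * t)) / 2
  m <- c(0, 0)
  for (code in 0:(2^nnode - 1)) {
    assign <- c(states, as.integer(intToBits(code))[seq_len(nnode)])
    pr <- prior[assign[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign[tree$edge[e, 1]]; b <- assign[tree$edge[e, 2]]
      ps <- pswitch(tree$edge.length[e])
      pr <- pr * if (a == b) 1 - ps else ps
    }
    m[assign[node] + 1] <- m[assign[node] + 1] + pr
  }
  m
}

# minimum number of state changes by exhaustive assignment
bf_parsimony <- function(tree, states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- as.integer(states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^nnode - 1)) {
    assign <- c(states, as.integer(intToBits(code))[seq_len(nnode)])
    ch <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# GLS by direct numerical maximization of the Gaussian likelihood
bf_gls_ml <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  logdetV <- determinant(V, logarithm = TRUE)$modulus
  nll <- function(par) {
    beta <- par[-length(par)]
    s2 <- exp(par[length(par)])
    r <- y - X %*% beta
    0.5 * (n * log(2 * pi * s2) + logdetV + crossprod(r, Vi %*% r) / s2)
  }
  init <- c(qr.coef(qr(X), y), 0)
  op <- optim(init, nll, method = "BFGS", control = list(maxit = 2000,
                                                         reltol = 1e-14))
  list(coefficients = op$par[-length(op$par)],
       sigma2 = exp(op$par[length(op$par)]),
       logLik = -op$value)
}

random_binary_states <- function(tree) {
  repeat {
    s <- setNames(sample(0:1, ape::Ntip(tree), replace = TRUE),
                  tree$tip.label)
    if (length(unique(s)) == 2) return(s)
  }
}
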