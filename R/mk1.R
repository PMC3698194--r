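#' Transition probabilities of the symmetric binary Markov (Mk1) model
#'
#' One rate `q` governs both directions of change, so over a branch of
#' length `t` the chance of staying is `(1 + exp(-2qt))/2` and of
#' switching `(1 - exp(-2qt))/2`.  Rows index the starting state (0, 1).
#'
#' @param q transition rate per unit branch length (>= 0).
#' @param t branch length (>= 0).
#' @return 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @examples
#' mk1_transition(1, 1)[1, 2]   # (1 - exp(-2))/2
#' @export
mk1_transition <- function(q, t) {
  if (!is.finite(q) || !is.finite(t) || q < 0 || t < 0)
    stop("q and t must be finite and non-negative", call. = FALSE)
  stay <- (1 + exp(-2 * q * t)) / 2
  switch <- (1 - exp(-2 * q * t)) / 2
  matrix(c(stay, switch, switch, stay), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

check_tip_states <- function(tree, tip_states) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != ape::Ntip(tree))
      stop("unnamed tip_states must have one entry per tip", call. = FALSE)
    names(tip_states) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stop("missing tip states for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- tip_states[tree$tip.label]
  if (any(is.na(s)) )
    stop("missing tip states for: ",
         paste(tree$tip.label[is.na(s)], collapse = ", "), call. = FALSE)
  if (!all(s %in% c(0, 1)))
    stop("tip states must be coded 0/1", call. = FALSE)
  as.integer(s)
}

# post-order pruning pass; returns scaled partial likelihoods per node,
# per-node log scale factors, and the data log-likelihood
mk1_down <- function(tree, states, q, root_prior) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  D <- matrix(0, nn, 2)
  D[cbind(seq_len(ntip), states + 1L)] <- 1
  D[(ntip + 1):nn, ] <- 1
  logsc <- numeric(nn)
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    P <- mk1_transition(q, tree$edge.length[e])
    msg <- as.numeric(P %*% D[chi, ])
    D[par, ] <- D[par, ] * msg
    logsc[par] <- logsc[par] + logsc[chi]
    mx <- max(D[par, ])
    if (mx > 0 && is.finite(mx)) {
      D[par, ] <- D[par, ] / mx
      logsc[par] <- logsc[par] + log(mx)
    }
  }
  root <- ntip + 1L
  lik <- sum(root_prior * D[root, ])
  ll <- if (lik > 0) log(lik) + logsc[root] else -Inf
  list(D = D, logsc = logsc, logLik = ll)
}

#' Log-likelihood of binary tip states under the Mk1 model
#'
#' Computed by Felsenstein's pruning algorithm (post-order accumulation of
#' per-node partial likelihoods, numerically rescaled), combining the root
#' partials with the root state prior.
#'
#' @param tree a rooted `"phylo"` tree with branch lengths.
#' @param tip_states named vector of 0/1 states covering every tip.
#' @param q transition rate (>= 0).
#' @param root_prior probabilities of root states (0, 1); default uniform,
#'   the stationary distribution of the symmetric model.
#' @return log-likelihood (`-Inf` when the data are impossible, e.g.
#'   discordant tips with `q = 0`).
#' @export
mk1_loglik <- function(tree, tip_states, q, root_prior = c(0.5, 0.5)) {
  validate_phylogeny(tree)
  if (!has_branch_lengths(tree))
    stop("tree has no branch lengths", call. = FALSE)
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  if (length(root_prior) != 2 || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    stop("root_prior must be two probabilities summing to 1", call. = FALSE)
  states <- check_tip_states(tree, tip_states)
  mk1_down(tree, states, q, root_prior)$logLik
}

#' Maximum-likelihood transition rate of the Mk1 model
#'
#' One-dimensional bounded search on the log scale (tolerance 1e-8 on
#' `log q`).  When all tips share one state the optimum lies at the `q = 0`
#' boundary and the fit is flagged.
#'
#' @inheritParams mk1_loglik
#' @param interval search interval for `q`; default `c(1e-8, 1e3)`.
#' @return object of class `"mk1_model"`: list with `q`, `root_prior`,
#'   `logLik`, `boundary` (TRUE when the optimum sits at the search
#'   boundary).
#' @export
fit_q <- function(tree, tip_states, root_prior = c(0.5, 0.5),
                  interval = c(1e-8, 1e3)) {
  states <- check_tip_states(tree, tip_states)
  ll <- function(logq) mk1_loglik(tree, tip_states, exp(logq), root_prior)
  bounds <- log(interval)
  if (length(unique(states)) == 1L) {
    qhat <- 0
    out <- list(q = 0, root_prior = root_prior,
                logLik = mk1_loglik(tree, tip_states, 0, root_prior),
                boundary = TRUE)
  } else {
    opt <- optimize(ll, bounds, maximum = TRUE, tol = 1e-8)
    qhat <- exp(opt$maximum)
    boundary <- min(opt$maximum - bounds[1], bounds[2] - opt$maximum) < 1e-4
    out <- list(q = qhat, root_prior = root_prior, logLik = opt$objective,
                boundary = boundary)
  }
  class(out) <- "mk1_model"
  out
}

#' @export
print.mk1_model <- function(x, ...) {
  cat("Mk1 model: q =", signif(x$q, 4), " logLik =", signif(x$logLik, 6),
      if (x$boundary) "(boundary solution)" else "", "\n")
  invisible(x)
}

#' Marginal ancestral-state reconstruction under Mk1
#'
#' For every internal node, combines the partial likelihoods of the
#' subtree below the node with those of the rest of the tree (an up-down,
#' rerooting pass) to obtain the marginal likelihood of each state, then
#' normalizes to proportional likelihoods.  A node is called for a state
#' when the natural-log marginal likelihoods differ by more than 2 log
#' units (the conventional rule of thumb); otherwise the call is
#' `"ambiguous"`.
#'
#' @inheritParams mk1_loglik
#' @param q transition rate; if `NULL` (default) it is first estimated by
#'   [fit_q()].
#' @return object of class `"mk1_asr"`: data.frame `nodes` with columns
#'   `node` (ape node number), `PL0`, `PL1` (proportional likelihoods),
#'   `logdiff` (`log L0 - log L1`), `call` (`"0"`, `"1"`, `"ambiguous"`);
#'   plus `q`, `root_prior`, `logLik`, and the tree.
#' @export
asr_mk1 <- function(tree, tip_states, q = NULL, root_prior = c(0.5, 0.5)) {
  states <- check_tip_states(tree, tip_states)
  model <- if (is.null(q)) fit_q(tree, tip_states, root_prior)
           else list(q = q, root_prior = root_prior)
  q <- model$q
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  down <- mk1_down(tree, states, q, root_prior)
  D <- down$D; logscD <- down$logsc

  # per-edge messages: msg[e, s] = P(s -> .) %*% D[child]
  nedge <- nrow(tree$edge)
  msg <- matrix(0, nedge, 2)
  for (e in seq_len(nedge)) {
    P <- mk1_transition(q, tree$edge.length[e])
    msg[e, ] <- as.numeric(P %*% D[tree$edge[e, 2], ])
  }
  child_edges <- split(seq_len(nedge), tree$edge[, 1])

  U <- matrix(0, nn, 2); logscU <- numeric(nn)
  U[root, ] <- root_prior
  for (e in rev(ape::postorder(tree))) {       # root-to-tip order
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    sibs <- setdiff(child_edges[[as.character(par)]], e)
    tmp <- U[par, ]
    sc <- logscU[par]
    for (s in sibs) {
      tmp <- tmp * msg[s, ]
      sc <- sc + logscD[tree$edge[s, 2]]
    }
    P <- mk1_transition(q, tree$edge.length[e])
    U[chi, ] <- as.numeric(tmp %*% P)          # sum over parent state
    mx <- max(U[chi, ])
    if (mx > 0 && is.finite(mx)) {
      U[chi, ] <- U[chi, ] / mx
      sc <- sc + log(mx)
    }
    logscU[chi] <- sc
  }

  internal <- (ntip + 1L):nn
  logM <- matrix(-Inf, length(internal), 2)
  for (i in seq_along(internal)) {
    v <- internal[i]
    m <- D[v, ] * U[v, ]
    lsc <- logscD[v] + logscU[v]
    logM[i, ] <- ifelse(m > 0, log(m) + lsc, -Inf)
  }
  pl <- t(apply(logM, 1, function(lm) {
    if (all(!is.finite(lm))) return(c(NA, NA))
    w <- exp(lm - max(lm)); w / sum(w)
  }))
  logdiff <- logM[, 1] - logM[, 2]
  call <- ifelse(abs(logdiff) <= 2, "ambiguous", ifelse(logdiff > 2, "0", "1"))
  nodes <- data.frame(node = internal, PL0 = pl[, 1], PL1 = pl[, 2],
                      logdiff = logdiff, call = call,
                      stringsAsFactors = FALSE)
  out <- list(nodes = nodes, q = q, root_prior = root_prior,
              logLik = down$logLik, tree = tree,
              tip_states = setNames(states, tree$tip.label),
              marginal_loglik = logM)
  class(out) <- "mk1_asr"
  out
}

#' @export
print.mk1_asr <- function(x, digits = 3, ...) {
  cat("Mk1 marginal ancestral-state reconstruction\n")
  cat("q =", signif(x$q, 4), " logLik =", signif(x$logLik, 6), "\n")
  root <- ape::Ntip(x$tree) + 1L
  r <- x$nodes[x$nodes$node == root, ]
  cat("Root: PL(0) =", signif(r$PL0, digits), " PL(1) =",
      signif(r$PL1, digits), " call =", r$call, "\n")
  cat(sum(x$nodes$call == "ambiguous"), "of", nrow(x$nodes),
      "internal nodes ambiguous (2-log-unit rule)\n")
  invisible(x)
}

#' Parsimony count of character origins and losses
#'
#' Computes the minimum number of state changes for a binary character on
#' a rooted tree (Fitch parsimony; the Hartigan generalization is used at
#' polytomies) and decomposes the changes into gains (0 to 1) and losses
#' (1 to 0) under a most-parsimonious node assignment that keeps a node in
#' its parent's state whenever possible (delayed transformation).  The
#' root state is taken from the parsimony root set by default; ties are
#' reported and broken in favour of state 0, matching a marginal-ML root
#' call of the ancestral, unable-to-manipulate state.  Forcing a
#' `root_state` outside the parsimony root set adds one change.
#'
#' @inheritParams mk1_loglik
#' @param root_state optional forced root state (0 or 1).
#' @return list with `score` (minimum changes), `gains`, `losses`,
#'   `root_state`, `root_tie` (TRUE when both root states are equally
#'   parsimonious), and `states` (the node assignment used).
#' @export
count_origins <- function(tree, tip_states, root_state = NULL) {
  validate_phylogeny(tree)
  states <- check_tip_states(tree, tip_states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::postorder(tree)
  child_of <- split(tree$edge[, 2], tree$edge[, 1])
  # Hartigan up-pass: vote counts over children's preferred sets
  prefer <- vector("list", nn)
  for (i in seq_len(ntip)) prefer[[i]] <- states[i]
  score <- 0L
  internal_po <- unique(tree$edge[po, 1])      # children-first order
  for (v in internal_po) {
    kids <- child_of[[as.character(v)]]
    votes <- c(`0` = 0L, `1` = 0L)
    for (k in kids)
      votes[as.character(prefer[[k]])] <- votes[as.character(prefer[[k]])] + 1L
    mx <- max(votes)
    prefer[[v]] <- as.integer(names(votes)[votes == mx])
    score <- score + length(kids) - mx
  }
  root_set <- prefer[[root]]
  root_tie <- length(root_set) > 1
  if (is.null(root_state)) {
    root_state <- if (root_tie) 0L else root_set[1]
  } else {
    root_state <- as.integer(root_state)
    if (!root_state %in% c(0L, 1L)) stop("root_state must be 0 or 1",
                                         call. = FALSE)
  }
  # down-pass assignment: keep the parent's state when it is preferred
  assign <- integer(nn)
  assign[seq_len(ntip)] <- states
  assign[root] <- root_state
  for (e in rev(po)) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    if (chi <= ntip) next
    assign[chi] <- if (assign[par] %in% prefer[[chi]]) assign[par]
                   else prefer[[chi]][1]
  }
  gains <- 0L; losses <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    a <- assign[tree$edge[e, 1]]; b <- assign[tree$edge[e, 2]]
    if (a == 0L && b == 1L) gains <- gains + 1L
    if (a == 1L && b == 0L) losses <- losses + 1L
  }
  list(score = score, gains = gains, losses = losses,
       root_state = root_state, root_tie = root_tie,
       states = setNames(assign, c(tree$tip.label,
                                   paste0("node", (ntip + 1L):nn))))
}
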