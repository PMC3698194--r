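#' Read and validate a rooted phylogeny from Newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: unique tip labels, no negative branch
#' lengths, and a rooted topology.  Trees without branch lengths are
#' accepted (use [grafen_lengths()] to assign them) but flagged via the
#' return value of [has_branch_lengths()].
#'
#' @param file path to a Newick file. Exactly one of `file`/`text`.
#' @param text a Newick string.
#' @return an object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @seealso [phylo_covariance()], [grafen_lengths()]
#' @export
read_phylogeny <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  if (!is.null(text)) {
    check_newick_balance(text)
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  } else {
    if (!file.exists(file)) stop("tree file not found: ", file, call. = FALSE)
    check_newick_balance(paste(readLines(file, warn = FALSE), collapse = ""))
    tr <- tryCatch(ape::read.tree(file),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  }
  if (is.null(tr)) stop("Newick parse error: no tree found", call. = FALSE)
  validate_phylogeny(tr)
  tr
}

check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop("Newick parse error: unbalanced parentheses near position ",
         if (any(depth < 0)) which(depth < 0)[1] else length(depth),
         call. = FALSE)
  invisible(TRUE)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    child <- tree$edge[bad, 2]
    lab <- if (child <= ape::Ntip(tree)) tree$tip.label[child]
           else paste0("node ", child)
    stop("negative branch length (", tree$edge.length[bad],
         ") on the edge leading to ", lab, call. = FALSE)
  }
  invisible(tree)
}

#' Does a tree carry branch lengths?
#' @param tree a `"phylo"` object.
#' @return logical.
#' @export
has_branch_lengths <- function(tree) {
  !is.null(tree$edge.length) && all(is.finite(tree$edge.length))
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix of expected trait covariances under Brownian motion:
#' entry (i, j) is the summed branch length from the root to the most
#' recent common ancestor of tips i and j, and the diagonal holds
#' root-to-tip path lengths.  This is the matrix scaled by Pagel's lambda
#' in [lambda_transform()] and used as the error covariance in [pgls()].
#'
#' @param tree a rooted `"phylo"` tree with branch lengths.
#' @return a symmetric matrix with tip labels as dimnames.
#' @examples
#' phylo_covariance(read_phylogeny(text = "((A:1,B:1):1,C:2);"))
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  if (!has_branch_lengths(tree))
    stop("tree has no branch lengths; assign them first, e.g. with grafen_lengths()",
         call. = FALSE)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # depth of every node measured from the root
  depth <- numeric(ntip + nnode)
  ord <- rev(ape::postorder(tree))           # root-to-tip edge order
  for (e in ord) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    depth[chi] <- depth[par] + tree$edge.length[e]
  }
  # accumulate: each internal node contributes its parent-edge length to
  # all pairs of tips descending from it; equivalently V[i, j] = depth of
  # the MRCA.  Build tip descendant lists bottom-up, then fill.
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    if (is.null(desc[[par]])) desc[[par]] <- integer(0)
    # pairs split across previously-seen children of 'par' coalesce at 'par'
    a <- desc[[par]]; b <- desc[[chi]]
    if (length(a)) V[a, b] <- V[b, a] <- depth[par]
    desc[[par]] <- c(a, b)
  }
  diag(V) <- depth[seq_len(ntip)]
  V
}

#' Scale off-diagonal phylogenetic covariances by Pagel's lambda
#'
#' lambda = 1 returns the Brownian matrix unchanged; lambda = 0 removes all
#' shared history, leaving a diagonal matrix (phylogenetic independence).
#'
#' @param V covariance matrix from [phylo_covariance()].
#' @param lambda scalar in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Assign Grafen branch lengths
#'
#' Sets each internal node's height proportional to its number of
#' descendant tips minus one, normalizes the root height to 1 (then raises
#' heights to `power`), and derives branch lengths from height differences.
#' The result is ultrametric with depth 1 and serves as a neutral
#' branch-length assignment when true divergence times are unknown.
#' Computation is delegated to [ape::compute.brlen()].
#'
#' @param tree a rooted `"phylo"` topology (existing lengths are ignored).
#' @param power exponent applied to the normalized heights (rho in
#'   Grafen's method); default 1.
#' @return the tree with branch lengths, ultrametric with depth 1.
#' @examples
#' grafen_lengths(read_phylogeny(text = "(((A,B),C),D);"))$edge.length
#' @export
grafen_lengths <- function(tree, power = 1) {
  validate_phylogeny(tree)
  ape::compute.brlen(tree, power = power)
}

#' Root-to-tip depths
#' @param tree a `"phylo"` tree with branch lengths.
#' @return named numeric vector of tip depths.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Is a tree ultrametric (all tips equidistant from the root)?
#' @param tree a `"phylo"` tree with branch lengths.
#' @param tol absolute tolerance on depth differences.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol
}
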