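#' BIONJ tree from a distance matrix
#'
#' Thin validated wrapper around the BIONJ agglomeration (Gascuel 1997) as
#' implemented in \pkg{ape}: neighbor-joining selection with variance-weighted
#' branch-length reduction. Negative branch lengths are retained as computed;
#' downstream split comparisons use topology only.
#'
#' @param d Symmetric numeric matrix with zero diagonal (labelled), or a
#'   `dist` object.
#' @return An unrooted `phylo` tree.
#' @export
bionj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (any(is.na(d)) || any(!is.finite(d))) abort("distance matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (nrow(d) < 3) abort("need at least 3 taxa")
  ape::bionj(d)
}

#' Nontrivial splits of an unrooted tree
#'
#' Every internal edge of an unrooted tree bipartitions the tips; the
#' nontrivial bipartitions (both sides of size >= 2) are the tree's splits, a
#' fully resolved tree on `n` tips having exactly `n - 3` of them. Splits are
#' returned in canonical form: the side not containing the reference tip
#' (the lexicographically smallest label), sorted and joined with `"|"`.
#'
#' @param tree A `phylo` object (rooted trees are read as their unrooted
#'   topology).
#' @return Character vector of canonical splits.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tree_splits(tr)
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  n <- length(labels)
  ref <- sort(labels)[1]
  out <- character(0)
  for (clade in pp) {
    side <- labels[clade]
    if (ref %in% side) side <- setdiff(labels, side)
    k <- length(side)
    if (k >= 2 && k <= n - 2) out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Number of splits shared by two trees
#'
#' The count of identical nontrivial bipartitions; a topology-only similarity
#' (branch lengths ignored) bounded by `n - 3` for fully resolved trees.
#'
#' @param t1,t2 `phylo` trees on the same tip set.
#' @return Integer shared-split count.
#' @export
shared_splits <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees must share an identical tip set")
  }
  length(intersect(tree_splits(t1), tree_splits(t2)))
}

#' Expected invasion tree (caterpillar)
#'
#' The tree corresponding to a strict serial invasion route through the given
#' labels (origin first): a caterpillar/ladder topology with unit branch
#' lengths whose splits are exactly the prefixes of the order.
#'
#' @param labels Ordered character vector (length >= 4), e.g.
#'   `c("FL", paste0("pop", 1:10))`.
#' @return Unrooted `phylo` caterpillar.
#' @export
expected_invasion_tree <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 4) abort("need at least 4 labels for a caterpillar with a split")
  inner <- paste0("(", labels[n - 1], ":1,", labels[n], ":1)")
  if (n >= 5) {
    for (i in rev(seq(3, n - 2))) {
      inner <- paste0("(", labels[i], ":1,", inner, ":1)")
    }
  }
  txt <- paste0("(", labels[1], ":1,", labels[2], ":1,", inner, ":1);")
  ape::read.tree(text = txt)
}

#' Random unrooted binary trees
#'
#' Two null generators over labeled topologies. `"recursive-split"`
#' recursively assigns each label of the current set independently to one of
#' two sides (redrawing if a side comes up empty) — the splitting scheme of
#' the classical random-tree generators used for tree-shape nulls; it is not
#' uniform over labeled topologies. `"uniform-addition"` grows the tree by
#' stepwise insertion of each taxon on a uniformly chosen edge, which is
#' uniform over the `(2n-5)!!` labeled topologies. Branch lengths are set
#' to 1; only the topology is meaningful.
#'
#' @param labels Tip labels (length >= 4).
#' @param method `"recursive-split"` (default) or `"uniform-addition"`.
#' @return Unrooted binary `phylo` tree.
#' @export
random_tree <- function(labels, method = c("recursive-split", "uniform-addition")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 4) abort("need at least 4 labels")
  if (method == "recursive-split") {
    rec <- function(v) {
      k <- length(v)
      if (k == 1) return(v)
      if (k == 2) return(paste0("(", v[1], ",", v[2], ")"))
      repeat {
        side <- stats::runif(k) < 0.5
        if (any(side) && !all(side)) break
      }
      paste0("(", rec(v[side]), ",", rec(v[!side]), ")")
    }
    tr <- ape::read.tree(text = paste0(rec(labels), ";"))
    tr <- ape::unroot(tr)
  } else {
    # edges as rows (a, b); start from the 3-taxon star, insert each further
    # taxon on a uniformly chosen edge
    tr <- ape::read.tree(text = paste0("(", labels[1], ":1,", labels[2], ":1,",
                                       labels[3], ":1);"))
    for (i in seq(4, n)) {
      e <- sample.int(nrow(tr$edge), 1)
      tr <- ape::bind.tree(
        tr,
        ape::read.tree(text = paste0("(", labels[i], ":1);")),
        where = tr$edge[e, 2], position = 0.5
      )
      tr <- ape::unroot(tr)
      tr$edge.length <- rep(1, nrow(tr$edge))
    }
  }
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Null distribution of shared splits against a reference tree
#'
#' Draws `n_trees` random trees on the tip set of `reference` and counts the
#' splits each shares with it.
#'
#' @param reference A `phylo` tree.
#' @param n_trees Number of random trees.
#' @inheritParams random_tree
#' @return Integer vector of shared-split counts (length `n_trees`).
#' @export
random_shared_splits <- function(reference, n_trees,
                                 method = c("recursive-split", "uniform-addition")) {
  method <- match.arg(method)
  ref_splits <- tree_splits(reference)
  labels <- reference$tip.label
  vapply(seq_len(n_trees), function(i) {
    length(intersect(tree_splits(random_tree(labels, method)), ref_splits))
  }, integer(1))
}

#' Bootstrap majority-rule consensus tree over ID alleles
#'
#' Resamples the ID allele columns of a frequency matrix with replacement
#' (`B` replicates of the same allele count), recomputes the FL column as the
#' complement of the resampled ID frequencies (renormalizing rows so each
#' remains a probability vector when an allele is drawn multiple times),
#' rebuilds the Jost's D matrix and the BIONJ tree for every replicate, and
#' keeps the splits present in strictly more than `threshold` of the
#' successful replicates. Retained edges carry their support fraction as node
#' labels; everything else collapses into multifurcations.
#'
#' @param matrix A frequency matrix (>= 4 samples, >= 2 ID alleles).
#' @param B Number of bootstrap replicates.
#' @param threshold Strict majority threshold on split frequency.
#' @return A `phylo` consensus tree with support values in `node.label`
#'   and an attribute `split_support` (named numeric vector over retained
#'   splits).
#' @export
bootstrap_consensus <- function(matrix, B = 100, threshold = 0.5) {
  ids <- id_allele_cols(matrix)
  if (nrow(matrix) < 4) abort("need at least 4 samples for a consensus tree")
  if (length(ids) < 2) abort("need at least 2 ID alleles to bootstrap")
  counts <- list()
  ok <- 0
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    # frequency of an allele counts once per draw
    freq <- sapply(unique(take), function(a) {
      matrix[[a]] * sum(take == a)
    })
    freq <- base::matrix(freq, nrow = nrow(matrix),
                         dimnames = list(matrix$sample_id, unique(take)))
    tot <- rowSums(freq)
    fl <- pmax(1 - tot, 0)
    denom <- tot + fl
    if (any(denom <= 0)) next
    prob <- cbind(freq, FL = fl) / denom
    if (nrow(unique(round(prob, 12))) < 2) next  # degenerate: all samples identical
    d <- matrix(0, nrow(prob), nrow(prob),
                dimnames = list(rownames(prob), rownames(prob)))
    for (i in seq_len(nrow(prob) - 1)) {
      for (j in (i + 1):nrow(prob)) {
        d[i, j] <- d[j, i] <- jost_d_pair(prob[i, ], prob[j, ])
      }
    }
    tr <- bionj_tree(d)
    ok <- ok + 1
    for (s in tree_splits(tr)) counts[[s]] <- (counts[[s]] %||% 0) + 1
  }
  if (ok < B / 2) abort("too many degenerate bootstrap replicates")
  support <- vapply(counts, function(x) x / ok, double(1))
  keep <- support[support > threshold]
  tree <- consensus_from_splits(matrix$sample_id, names(keep), keep)
  attr(tree, "split_support") <- keep
  attr(tree, "n_replicates") <- ok
  tree
}

# Build a (multifurcating) tree from pairwise-compatible canonical splits.
# Splits with frequency > 0.5 are automatically pairwise compatible.
consensus_from_splits <- function(labels, splits, support = NULL) {
  labels <- as.character(labels)
  ref <- sort(labels)[1]
  clades <- lapply(splits, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  # represent as clades not containing the reference tip; nested or disjoint
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]
  sup <- if (is.null(support)) NULL else unname(support[ord])
  node_of <- function(members, depth) {
    # children: maximal clades strictly inside `members`
    inside <- which(vapply(clades, function(cl) {
      all(cl %in% members) && length(cl) < length(members)
    }, logical(1)))
    taken <- character(0)
    parts <- character(0)
    for (i in inside) {
      cl <- clades[[i]]
      if (length(intersect(cl, taken)) > 0) next  # nested inside a used child
      lab <- if (is.null(sup)) "" else sprintf("%.2f", sup[i])
      parts <- c(parts, paste0(node_of(cl, depth + 1), lab))
      taken <- c(taken, cl)
    }
    singles <- setdiff(members, taken)
    paste0("(", paste(c(singles, parts), collapse = ","), ")")
  }
  txt <- paste0(node_of(labels, 0), ";")
  ape::read.tree(text = txt)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds the samples on the
#' top `k` nonnegative-eigenvalue axes. Fewer axes are returned with a
#' warning when the matrix supports fewer positive eigenvalues.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of axes requested.
#' @return Tibble with `sample_id` and coordinate columns `MDS1`, `MDS2`, ...;
#'   eigenvalues in attribute `eig`.
#' @export
classical_mds <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, nrow(d) - 1), eig = TRUE))
  pos <- sum(fit$eig > 1e-12)
  if (pos < k) {
    warn(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                 pos, pos))
  }
  keep <- min(k, max(pos, 1), ncol(fit$points))
  pts <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(pts) <- paste0("MDS", seq_len(keep))
  out <- bind_cols(tibble(sample_id = rownames(d)), as_tibble(pts))
  attr(out, "eig") <- fit$eig
  out
}
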