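#' Pairwise distances between expression profiles
#'
#' Distances are computed on the log2 scale: either the Euclidean distance
#' between log2 profiles, or one minus their Pearson correlation.
#'
#' @param x A data frame whose first character column labels the items and
#'   whose remaining numeric columns are the profile values, or a plain
#'   numeric matrix with rownames. Rows are the items being compared.
#' @param metric `"euclidean_log2"` (default) or `"one_minus_pearson"`.
#' @param values `"linear"` (default; values are linear ratios, log2 is
#'   applied) or `"log2"` (already transformed).
#' @return A [stats::dist] object with item labels and a `metric`
#'   attribute.
#' @export
profile_dist <- function(x, metric = c("euclidean_log2", "one_minus_pearson"),
                         values = c("linear", "log2")) {
  metric <- match.arg(metric)
  values <- match.arg(values)
  if (is.data.frame(x)) {
    label_col <- names(x)[!vapply(x, is.numeric, logical(1))][1]
    if (is.na(label_col)) abort("no label column found")
    labels <- as.character(x[[label_col]])
    m <- as.matrix(x[vapply(x, is.numeric, logical(1))])
    rownames(m) <- labels
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  }
  if (nrow(m) < 2) abort("need at least 2 items")
  if (anyNA(m) || any(!is.finite(m))) {
    abort("profiles contain missing or non-finite values")
  }
  if (values == "linear") {
    if (any(m <= 0)) abort("linear ratios must be strictly positive")
    m <- log2(m)
  }
  if (metric == "euclidean_log2") {
    d <- stats::dist(m, method = "euclidean")
  } else {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      abort(paste0("constant profile(s) under Pearson: ",
                   paste(rownames(m)[sds == 0], collapse = ", ")))
    }
    d <- stats::as.dist(1 - stats::cor(t(m)))
  }
  attr(d, "metric") <- metric
  d
}

#' UPGMA agglomerative clustering
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly
#' merge the two closest clusters; the distance from the merged cluster to
#' any other is the size-weighted average of its members' distances (i.e.
#' the unweighted average over all member pairs). When several pairs tie at
#' the minimum distance, the pair whose clusters contain the smallest
#' original item indices merges first, making the linkage deterministic.
#'
#' @param d A [stats::dist] object or symmetric non-negative matrix with
#'   zero diagonal.
#' @return An object of class `c("upgma", "hclust")` with the usual
#'   `merge`, `height`, `order`, `labels` components, so
#'   [stats::cophenetic()], [stats::cutree()] and plotting all work.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12)) {
    abort("distance input must be symmetric")
  }
  if (any(m < 0) || any(diag(m) != 0)) {
    abort("distances must be non-negative with zero diagonal")
  }
  n <- nrow(m)
  if (n < 2) abort("need at least 2 items")
  labels <- rownames(m) %||% as.character(seq_len(n))

  # active clusters: id (negative = singleton leaf, positive = merge row),
  # size, min original index (tie-break key)
  id <- -seq_len(n)
  size <- rep(1L, n)
  min_idx <- seq_len(n)
  active <- rep(TRUE, n)
  dmat <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- dmat[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best <- min(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    # tie-break: lexicographically smallest (min original index) pair
    keys <- cbind(pmin(min_idx[act[cand[, 1]]], min_idx[act[cand[, 2]]]),
                  pmax(min_idx[act[cand[, 1]]], min_idx[act[cand[, 2]]]))
    pick <- lex_order(keys[, 1], keys[, 2])[1]
    i <- act[min(cand[pick, ])]
    j <- act[max(cand[pick, ])]

    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmat[i, j]

    # size-weighted average distance from the merged cluster to the rest
    others <- setdiff(act, c(i, j))
    new_d <- (size[i] * dmat[i, others] + size[j] * dmat[j, others]) /
      (size[i] + size[j])
    dmat[i, others] <- new_d
    dmat[others, i] <- new_d
    size[i] <- size[i] + size[j]
    min_idx[i] <- min(min_idx[i], min_idx[j])
    id[i] <- step
    active[j] <- FALSE
  }

  out <- list(merge = merge, height = height,
              order = upgma_order(merge, n),
              labels = labels, method = "upgma",
              dist.method = attr(d, "metric") %||% "euclidean",
              call = match.call())
  class(out) <- c("upgma", "hclust")
  out
}

# left-to-right leaf order: at every merge the child containing the smaller
# original index is placed left
upgma_order <- function(merge, n) {
  min_leaf <- function(k) if (k < 0) -k else node_min[k]
  node_min <- integer(nrow(merge))
  for (s in seq_len(nrow(merge))) {
    node_min[s] <- min(min_leaf(merge[s, 1]), min_leaf(merge[s, 2]))
  }
  expand <- function(k) {
    if (k < 0) return(-k)
    a <- merge[k, 1]
    b <- merge[k, 2]
    if (min_leaf(a) > min_leaf(b)) { tmp <- a; a <- b; b <- tmp }
    c(expand(a), expand(b))
  }
  expand(nrow(merge))
}

#' Leaf order of a linkage
#'
#' @param linkage An object from [upgma()] (or any `hclust`).
#' @return Character vector of leaf labels in deterministic left-to-right
#'   display order.
#' @export
leaf_order <- function(linkage) {
  linkage$labels[linkage$order]
}

#' Export a linkage as a Newick tree
#'
#' Uses the ultrametric convention: every merge node sits at half its merge
#' distance, leaves at height zero, and each branch length is the height
#' difference between parent and child.
#'
#' @param linkage An object from [upgma()] (or any `hclust`).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(linkage, digits = 10) {
  merge <- linkage$merge
  height <- linkage$height / 2
  labels <- linkage$labels
  node_h <- function(k) if (k < 0) 0 else height[k]
  render <- function(k, parent_h) {
    bl <- format(parent_h - node_h(k), digits = digits, trim = TRUE,
                 scientific = FALSE)
    if (k < 0) return(paste0(labels[-k], ":", bl))
    a <- merge[k, 1]
    b <- merge[k, 2]
    # same left/right rule as the displayed leaf order
    if (min_leaf_of(merge, a) > min_leaf_of(merge, b)) {
      tmp <- a; a <- b; b <- tmp
    }
    paste0("(", render(a, height[k]), ",", render(b, height[k]), "):", bl)
  }
  root <- nrow(merge)
  a <- merge[root, 1]
  b <- merge[root, 2]
  if (min_leaf_of(merge, a) > min_leaf_of(merge, b)) {
    tmp <- a; a <- b; b <- tmp
  }
  paste0("(", render(a, height[root]), ",",
         render(b, height[root]), ");")
}

min_leaf_of <- function(merge, k) {
  if (k < 0) return(-k)
  min(min_leaf_of(merge, merge[k, 1]), min_leaf_of(merge, merge[k, 2]))
}

#' @method tidy upgma
#' @export
tidy.upgma <- function(x, ...) {
  sizes <- integer(nrow(x$merge))
  csize <- function(k) if (k < 0) 1L else sizes[k]
  for (s in seq_len(nrow(x$merge))) {
    sizes[s] <- csize(x$merge[s, 1]) + csize(x$merge[s, 2])
  }
  tibble(step = seq_len(nrow(x$merge)),
         cluster_a = x$merge[, 1], cluster_b = x$merge[, 2],
         merge_distance = x$height, new_cluster_size = sizes)
}

#' @method glance upgma
#' @export
glance.upgma <- function(x, ...) {
  tibble(n_leaves = length(x$labels),
         n_merges = nrow(x$merge),
         max_merge_distance = max(x$height),
         heights_monotone = !is.unsorted(x$height))
}
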