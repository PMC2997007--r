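# Independent reference implementations used as oracles. These deliberately
# recompute results by the most literal route available (exhaustive loops,
# definition-level averages, matrix powers) and share no code with the
# package internals they check.

# UPGMA by definition: the distance between two clusters is the plain mean
# of all member-pair distances in the ORIGINAL matrix, recomputed at every
# step (O(n^3)); ties broken like the package (smallest original indices).
brute_upgma <- function(m) {
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- Inf
    bi <- bj <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- mean(m[clusters[[i]], clusters[[j]]])
        key_new <- c(min(clusters[[i]][1], clusters[[j]][1]),
                     max(clusters[[i]][1], clusters[[j]][1]))
        if (d < best - 1e-12) {
          best <- d; bi <- i; bj <- j; key_best <- key_new
        } else if (abs(d - best) <= 1e-12) {
          if (key_new[1] < key_best[1] ||
              (key_new[1] == key_best[1] && key_new[2] < key_best[2])) {
            bi <- i; bj <- j; key_best <- key_new
          }
        }
      }
    }
    merge[step, ] <- sort(c(ids[bi], ids[bj]))
    height[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[bi] <- step
    clusters[[bj]] <- NULL
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# cophenetic matrix straight from a merge/height pair
brute_cophenetic <- function(merge, height, n) {
  members <- function(k) {
    if (k < 0) return(-k)
    c(members(merge[k, 1]), members(merge[k, 2]))
  }
  cm <- matrix(0, n, n)
  for (s in seq_len(nrow(merge))) {
    a <- members(merge[s, 1])
    b <- members(merge[s, 2])
    cm[a, b] <- height[s]
    cm[b, a] <- height[s]
  }
  cm
}

# literal double-loop fold-change scan
brute_filter <- function(tbl, treatments, threshold, rule, direction) {
  keep <- logical(nrow(tbl))
  for (g in seq_len(nrow(tbl))) {
    passes <- logical(length(treatments))
    for (t in seq_along(treatments)) {
      r <- tbl[[treatments[t]]][g]
      up <- !is.na(r) && r >= threshold
      dn <- !is.na(r) && r <= 1 / threshold
      passes[t] <- switch(direction, up = up, down = dn, both = up || dn)
    }
    keep[g] <- if (rule == "any") any(passes) else all(passes)
  }
  tbl$gene_symbol[keep]
}

# shortest directed depths up to L by boolean adjacency-matrix powers
matrix_power_depths <- function(network, source, L) {
  nodes <- network$nodes
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(network$edges))) {
    A[network$edges$source[e], network$edges$target[e]] <- TRUE
  }
  depth <- setNames(rep(NA_integer_, n), nodes)
  reach <- A[source, ]
  for (d in seq_len(L)) {
    newly <- reach & is.na(depth)
    depth[newly] <- d
    reach <- as.vector(reach %*% A) > 0
  }
  depth[!is.na(depth)]
}

random_distance_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- letters[seq_len(n)]
  m
}

random_network <- function(n_nodes, n_edges) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  keep <- src != tgt
  as_signaling_network(tibble::tibble(
    source = src[keep],
    sign = sample(c("activate", "inhibit"), sum(keep), replace = TRUE),
    target = tgt[keep]))
}
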