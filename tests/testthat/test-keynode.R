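test_that("SIF parsing builds the signed multigraph", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("K\tactivate\tA", path)
  net <- load_network(path)
  expect_setequal(net$nodes, c("K", "A"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "activate")

  writeLines("K\tinhibit\tK", path)
  expect_warning(net <- load_network(path), "self-loop")
  expect_equal(net$nodes, "K")
  expect_equal(nrow(net$edges), 0)

  writeLines("K\tbinds\tA", path)
  expect_error(load_network(path), "unknown interaction 'binds' on line 1")
})

test_that("a written network re-parses to the same edge multiset", {
  set.seed(31)
  net <- random_network(40, 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(net$edges$source, net$edges$sign, net$edges$target,
                   sep = "\t"), path)
  # independent line-by-line parse
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  manual <- sort(vapply(fields, paste, character(1), collapse = "|"))
  reparsed <- load_network(path)
  got <- sort(paste(reparsed$edges$source, reparsed$edges$sign,
                    reparsed$edges$target, sep = "|"))
  expect_equal(got, manual)
})

test_that("reachability is truncated at the depth bound", {
  chain <- as_signaling_network(tibble::tibble(
    source = c("K", "x1", "x2", "x3", "x4"),
    sign = "activate",
    target = c("x1", "x2", "x3", "x4", "g")))
  r <- bounded_reach(chain, "K", 4)
  expect_false("g" %in% r$node)
  expect_equal(r$depth[r$node == "x4"], 4L)

  star <- as_signaling_network(tibble::tibble(
    source = "K", sign = "activate", target = c("a", "b", "c")))
  r <- bounded_reach(star, "K", 4)
  expect_equal(sort(r$node), c("a", "b", "c"))
  expect_equal(r$depth, rep(1L, 3))

  expect_error(bounded_reach(star, "nope", 4), "unknown source")
})

test_that("BFS depths match matrix-power and igraph oracles", {
  skip_if_not_installed("igraph")
  set.seed(32)
  for (rep in 1:20) {
    net <- random_network(sample(6:12, 1), sample(10:40, 1))
    L <- sample(1:4, 1)
    src <- sample(net$nodes, 1)
    got <- bounded_reach(net, src, L)
    want <- matrix_power_depths(net, src, L)
    expect_equal(sort(names(want)), sort(got$node))
    expect_equal(unname(want[got$node]), got$depth)
    # igraph cannot report a positive self-distance, so compare other nodes
    g <- igraph::graph_from_data_frame(
      net$edges[c("source", "target")], vertices = net$nodes)
    dist <- igraph::distances(g, v = src, mode = "out")[1, ]
    ig <- dist[names(dist) != src & is.finite(dist) & dist >= 1 & dist <= L]
    got_o <- got[got$node != src, ]
    expect_equal(sort(names(ig)), sort(got_o$node))
    expect_equal(unname(ig[got_o$node]), as.numeric(got_o$depth))
  }
})

test_that("path signs multiply like signs", {
  expect_equal(path_sign(c("activate", "activate")), "net_activate")
  expect_equal(path_sign(c("activate", "inhibit")), "net_inhibit")
  expect_equal(path_sign(c("inhibit", "inhibit")), "net_activate")
  expect_error(path_sign(character(0)), "at least one")
  set.seed(33)
  for (rep in 1:20) {
    signs <- sample(c("activate", "inhibit"), sample(1:8, 1), replace = TRUE)
    want <- if (prod(ifelse(signs == "inhibit", -1, 1)) > 0)
      "net_activate" else "net_inhibit"
    expect_equal(path_sign(signs), want)
  }
})

test_that("a forced two-gene query has a unique key node", {
  net <- as_signaling_network(tibble::tibble(
    source = "K", sign = c("activate", "inhibit"), target = c("a", "b")))
  res <- find_key_nodes(net, tibble::tibble(gene = c("a", "b"),
                                            direction = c("up", "down")))
  expect_equal(res$node, "K")
  expect_equal(res$coverage, 1)
  expect_equal(res$max_depth, 1)
  expect_equal(res$sign_consistency, 1)
  expect_equal(res$assumed_state, "active_up")
})

test_that("query genes do not cover themselves at depth zero", {
  net <- as_signaling_network(tibble::tibble(
    source = "a", sign = "activate", target = "b"))
  res <- find_key_nodes(net, c("a", "b"), require_full_coverage = FALSE)
  expect_equal(res$node, "a")
  expect_equal(res$coverage, 0.5)  # a reaches b but not itself
  expect_message(
    full <- find_key_nodes(net, c("a", "b")), "no node covers")
  expect_equal(nrow(full), 0)
})

test_that("results are invariant to edge order in the file", {
  set.seed(34)
  net <- simulate_network(network_config(n_nodes = 60, n_filler_edges = 40,
                                         seed = 5))
  edges <- net$network$edges
  shuffled <- as_signaling_network(edges[sample(nrow(edges)), ])
  r1 <- find_key_nodes(net$network, net$truth$query,
                       require_full_coverage = FALSE)
  r2 <- find_key_nodes(shuffled, net$truth$query,
                       require_full_coverage = FALSE)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("coverage never decreases with the depth bound", {
  set.seed(35)
  for (rep in 1:5) {
    net <- random_network(15, 50)
    query <- sample(net$nodes, 5)
    prev <- rep(0, length(net$nodes))
    for (L in 1:5) {
      res <- find_key_nodes(net, query, max_depth = L,
                            require_full_coverage = FALSE)
      cov <- setNames(res$coverage, res$node)[net$nodes]
      cov[is.na(cov)] <- 0
      expect_true(all(cov >= prev - 1e-12))
      prev <- cov
    }
  }
})

test_that("planted regulators are recovered at rank one", {
  for (s in 1:5) {
    nw <- simulate_network(network_config(seed = 100 + s))
    res <- find_key_nodes(nw$network, nw$truth$query,
                          require_full_coverage = FALSE)
    expect_equal(res$node[1], nw$truth$regulator)
    expect_equal(res$coverage[1], 1)
    # the planted chains make every covered gene sign-consistent
    expect_equal(res$sign_consistency[1], 1)
  }
})

test_that("sign consistency picks the better regulator state", {
  # K inhibits both genes; both observed down: consistent if K is active
  net <- as_signaling_network(tibble::tibble(
    source = "K", sign = "inhibit", target = c("a", "b")))
  res <- find_key_nodes(net, tibble::tibble(gene = c("a", "b"),
                                            direction = "down"))
  expect_equal(res$assumed_state, "active_up")
  expect_equal(res$sign_consistency, 1)
  # both observed up: only consistent if K itself is down/inactive
  res2 <- find_key_nodes(net, tibble::tibble(gene = c("a", "b"),
                                             direction = "up"))
  expect_equal(res2$assumed_state, "active_down")
  expect_equal(res2$sign_consistency, 1)
})

test_that("every figure network fixture has its named sole key node", {
  for (nm in grep("network", fixture_names(), value = TRUE)) {
    net <- phyto_fixture(nm)
    res <- find_key_nodes(net, attr(net, "query"), max_depth = 4)
    expect_equal(res$node, attr(net, "master"), info = nm)
  }
})
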