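#' Signed directed signaling networks
#'
#' A signaling network is a directed multigraph whose edges carry a
#' regulatory sign: `activate` or `inhibit`. Parallel edges with different
#' signs between the same pair of nodes are allowed; exact duplicate edges
#' are collapsed and self-loops are dropped with a warning.
#'
#' @param edges A data frame with columns `source`, `sign`, `target`
#'   (`sign` in `c("activate", "inhibit")`).
#' @return An object of class `signaling_network`: a list with `nodes`
#'   (character) and `edges` (tibble).
#' @export
as_signaling_network <- function(edges) {
  required <- c("source", "sign", "target")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    abort(paste0("edge table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- !edges$sign %in% c("activate", "inhibit")
  if (any(bad)) {
    abort(paste0("unknown interaction word(s): ",
                 paste(unique(edges$sign[bad]), collapse = ", ")))
  }
  nodes <- unique(c(edges$source, edges$target))
  loops <- edges$source == edges$target
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop(s): ",
                paste(head(unique(edges$source[loops]), 5), collapse = ", ")))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- distinct(as_tibble(edges)[required])
  structure(list(nodes = nodes[lex_order(nodes)], edges = edges),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("<signaling_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " signed edges (",
      sum(x$edges$sign == "activate"), " activate / ",
      sum(x$edges$sign == "inhibit"), " inhibit)\n", sep = "")
  invisible(x)
}

#' Load a signaling network from a SIF-like TSV file
#'
#' Three tab-separated columns per line: source node, interaction word
#' (`activate` or `inhibit`), target node. No header.
#'
#' @param path Path to the network file.
#' @return A [as_signaling_network()] object.
#' @export
load_network <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  incomplete <- which(parts[, 3] == "" | parts[, 2] == "")
  if (length(incomplete) > 0) {
    abort(paste0("malformed network line ", incomplete[1], ": '",
                 lines[incomplete[1]], "'"))
  }
  bad <- which(!parts[, 2] %in% c("activate", "inhibit"))
  if (length(bad) > 0) {
    abort(paste0("unknown interaction '", parts[bad[1], 2],
                 "' on line ", bad[1]))
  }
  as_signaling_network(tibble(source = parts[, 1], sign = parts[, 2],
                              target = parts[, 3]))
}

# adjacency lists keyed by source node: plain character vectors for speed
adjacency <- function(network) {
  list(target = split(network$edges$target, network$edges$source),
       activates = split(network$edges$sign == "activate",
                         network$edges$source))
}

#' Bounded-depth downstream reachability
#'
#' Breadth-first search along directed edges from a source node, truncated
#' at `max_depth` regulation steps. The depth reported for each reachable
#' node is the length of the shortest directed path from the source.
#'
#' @param network A [as_signaling_network()] object.
#' @param source Node identifier to start from.
#' @param max_depth Maximum number of regulation steps (default 4).
#' @return A tibble (`node`, `depth`) of nodes reachable in 1..`max_depth`
#'   steps (the source itself, at depth 0, is not listed).
#' @export
bounded_reach <- function(network, source, max_depth = 4) {
  res <- reach_signs(network, source, max_depth)
  res[c("node", "depth")]
}

# BFS recording, per node at its shortest depth, which net path signs
# (+1 activation / -1 net inhibition) are achievable along shortest paths
reach_signs <- function(network, source, max_depth) {
  if (!source %in% network$nodes) {
    abort(paste0("unknown source node '", source, "'"))
  }
  if (max_depth < 1) abort("max_depth must be >= 1")
  adj <- attr(network, "adjacency") %||% adjacency(network)
  depth <- new.env(parent = emptyenv())
  can_act <- new.env(parent = emptyenv())
  can_inh <- new.env(parent = emptyenv())
  # frontier holds (node, can_act, can_inh) at the current depth
  frontier_nodes <- source
  frontier_act <- TRUE   # empty path has positive sign
  frontier_inh <- FALSE
  d <- 0L
  while (length(frontier_nodes) > 0 && d < max_depth) {
    d <- d + 1L
    nxt <- new.env(parent = emptyenv())
    for (k in seq_along(frontier_nodes)) {
      tgts <- adj$target[[frontier_nodes[k]]]
      if (is.null(tgts)) next
      acts <- adj$activates[[frontier_nodes[k]]]
      a <- frontier_act[k]
      i <- frontier_inh[k]
      for (e in seq_along(tgts)) {
        tgt <- tgts[e]
        # sign product: an inhibiting edge flips achievable signs
        if (acts[e]) { na <- a; ni <- i } else { na <- i; ni <- a }
        known_d <- depth[[tgt]]
        if (!is.null(known_d) && known_d < d) next  # already settled shallower
        if (is.null(known_d)) depth[[tgt]] <- d
        can_act[[tgt]] <- isTRUE(can_act[[tgt]]) || na
        can_inh[[tgt]] <- isTRUE(can_inh[[tgt]]) || ni
        nxt[[tgt]] <- TRUE
      }
    }
    frontier_nodes <- ls(nxt)
    frontier_act <- vapply(frontier_nodes, function(nd) isTRUE(can_act[[nd]]),
                           logical(1))
    frontier_inh <- vapply(frontier_nodes, function(nd) isTRUE(can_inh[[nd]]),
                           logical(1))
  }
  nodes <- ls(depth)
  out <- tibble(
    node = nodes,
    depth = vapply(nodes, function(nd) depth[[nd]], integer(1),
                   USE.NAMES = FALSE),
    can_activate = vapply(nodes, function(nd) isTRUE(can_act[[nd]]),
                          logical(1), USE.NAMES = FALSE),
    can_inhibit = vapply(nodes, function(nd) isTRUE(can_inh[[nd]]),
                         logical(1), USE.NAMES = FALSE)
  )
  out[lex_order(out$depth, out$node), ]
}

#' Net sign of a regulation path
#'
#' The product rule of signed paths: an even number of inhibiting edges
#' yields net activation, an odd number net inhibition.
#'
#' @param signs Character vector of edge signs (`activate`/`inhibit`) along
#'   a path, in order.
#' @return `"net_activate"` or `"net_inhibit"`.
#' @export
path_sign <- function(signs) {
  bad <- !signs %in% c("activate", "inhibit")
  if (length(signs) == 0) abort("path must contain at least one edge")
  if (any(bad)) {
    abort(paste0("unknown sign(s): ", paste(unique(signs[bad]), collapse = ", ")))
  }
  if (sum(signs == "inhibit") %% 2 == 0) "net_activate" else "net_inhibit"
}

#' Key-node (master-regulator) search
#'
#' Scores every network node as a candidate upstream regulator of a set of
#' differentially expressed query genes: its *coverage* is the fraction of
#' mapped query genes reachable within `max_depth` directed steps (paths
#' must contain at least one edge, so a query gene does not cover itself).
#' Full-coverage nodes are the "common denominators" of the gene set.
#' Sign consistency annotates each candidate: under the better of the two
#' assumed regulator states (active/up or inactive/down), the fraction of
#' covered genes whose observed direction is predicted by the net sign of
#' at least one shortest path.
#'
#' @param network A [as_signaling_network()] object.
#' @param query Either a character vector of query gene nodes, or a data
#'   frame with columns `gene` and `direction` (`"up"`/`"down"`).
#' @param max_depth Maximum regulation depth (default 4).
#' @param require_full_coverage If `TRUE` (default) return only candidates
#'   covering the whole query set; an empty result (with a message) means
#'   no common denominator exists at this depth.
#' @return A tibble of class `keynode_tbl`, ranked by coverage (desc), max
#'   depth (asc), mean depth (asc), then node id: columns `node`,
#'   `coverage`, `n_covered`, `mean_depth`, `max_depth`,
#'   `sign_consistency`, `assumed_state`. Unmapped query genes are recorded
#'   in attribute `unmapped`.
#' @export
find_key_nodes <- function(network, query, max_depth = 4,
                           require_full_coverage = TRUE) {
  if (is.data.frame(query)) {
    genes <- as.character(query$gene)
    directions <- as.character(query$direction)
  } else {
    genes <- as.character(query)
    directions <- rep(NA_character_, length(genes))
  }
  if (anyDuplicated(genes)) abort("query genes must be unique")
  mapped <- genes %in% network$nodes
  unmapped <- genes[!mapped]
  if (length(unmapped) > 0) {
    inform(paste0(length(unmapped), " query gene(s) not in network: ",
                  paste(head(unmapped, 5), collapse = ", ")))
  }
  genes <- genes[mapped]
  directions <- directions[mapped]
  if (length(genes) == 0) abort("no query gene maps to the network")

  attr(network, "adjacency") <- adjacency(network)
  rows <- purrr::map(network$nodes, function(cand) {
    reach <- reach_signs(network, cand, max_depth)
    hit <- reach[match(genes, reach$node), ]
    covered <- !is.na(hit$depth)
    n_cov <- sum(covered)
    if (n_cov == 0) return(NULL)
    # predicted direction per assumed regulator state, per achievable
    # shortest-path net sign; a gene is consistent if any prediction
    # matches its observed direction
    has_dir <- covered & !is.na(directions)
    consistency <- c(active_up = NA_real_, active_down = NA_real_)
    if (any(has_dir)) {
      obs_up <- directions[has_dir] == "up"
      ca <- hit$can_activate[has_dir]
      ci <- hit$can_inhibit[has_dir]
      # regulator active/up: activation path -> up, inhibition path -> down
      consistency["active_up"] <- mean(ifelse(obs_up, ca, ci))
      consistency["active_down"] <- mean(ifelse(obs_up, ci, ca))
    }
    state <- if (anyNA(consistency)) NA_character_ else
      names(consistency)[which.max(consistency)]
    tibble(node = cand,
           coverage = n_cov / length(genes),
           n_covered = n_cov,
           mean_depth = mean(hit$depth[covered]),
           max_depth = max(hit$depth[covered]),
           sign_consistency = if (is.na(state)) NA_real_ else
             unname(consistency[state]),
           assumed_state = state)
  })
  res <- bind_rows(rows)
  if (nrow(res) > 0) {
    res <- res[lex_order(-res$coverage, res$max_depth, res$mean_depth,
                         res$node), ]
  }
  if (require_full_coverage) {
    res <- filter(res, .data$coverage == 1)
    if (nrow(res) == 0) {
      inform(paste0("no node covers the full query set within ",
                    max_depth, " steps"))
    }
  }
  attr(res, "unmapped") <- unmapped
  attr(res, "n_query") <- length(genes)
  attr(res, "max_depth") <- max_depth
  class(res) <- c("keynode_tbl", class(res))
  res
}

#' @method glance keynode_tbl
#' @export
glance.keynode_tbl <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_full_coverage = sum(x$coverage == 1),
         n_query = attr(x, "n_query"),
         n_unmapped = length(attr(x, "unmapped")),
         max_depth = attr(x, "max_depth"))
}
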