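#' Configure a synthetic focused-array experiment
#'
#' Builds the configuration for [simulate_experiment()]. Defaults emulate
#' the study design: a 228-gene focused immune array with 5 housekeeping
#' genes and 4 replicate spots per gene, a treatment panel of LPS alone
#' plus four compound co-treatments, the 0.5/2/4/12/48 h time grid, and
#' multiplicative log-normal spot noise.
#'
#' @param n_genes Total genes on the array (default 228, including the
#'   housekeeping genes).
#' @param n_housekeeping Number of housekeeping control genes (default 5;
#'   named after the five internal controls of the array:
#'   TUBA1A, B2M, ACTB, GAPDH, TFRC).
#' @param replicates Replicate spots per gene per chip (default 4).
#' @param treatments Chip treatment labels. By convention `"LPS"` chips
#'   hybridize LPS vs vehicle and every other label hybridizes
#'   compound+LPS vs LPS, so planted effects are the chip's own
#'   test:control ratio in either case.
#' @param times Time grid in hours.
#' @param effects Planted per-gene linear fold effects: a data frame with
#'   columns `gene_symbol`, `treatment`, `time_h`, `effect` (> 0).
#'   Unlisted combinations default to 1 (no change); housekeeping genes
#'   always have effect 1.
#' @param noise_sigma Standard deviation of the log-normal multiplicative
#'   spot noise, on the natural-log scale (default 0.1). Use 0 for a
#'   noise-free experiment.
#' @param base_scale Multiplier applied to all signal intensities.
#' @param abundance_range Range of per-gene baseline signal drawn
#'   log-uniformly, in intensity units.
#' @param bg_level Constant background intensity added to the foreground
#'   and reported in the background columns.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_genes = 228, n_housekeeping = 5,
                              replicates = 4,
                              treatments = c("LPS", "shikonin", "emodin",
                                             "cytopiloyne", "BF"),
                              times = c(0.5, 2, 4, 12, 48),
                              effects = NULL,
                              noise_sigma = 0.1,
                              base_scale = 1,
                              abundance_range = c(50, 5000),
                              bg_level = 100,
                              seed = 1) {
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (base_scale <= 0) abort("base_scale must be positive")
  if (n_housekeeping < 1 || n_housekeeping >= n_genes) {
    abort("need 1 <= n_housekeeping < n_genes")
  }
  if (replicates < 1) abort("replicates must be >= 1")
  if (!is.null(effects)) {
    req <- c("gene_symbol", "treatment", "time_h", "effect")
    if (!all(req %in% names(effects))) {
      abort(paste0("effects needs columns: ", paste(req, collapse = ", ")))
    }
    if (any(effects$effect <= 0)) abort("planted effects must be positive")
  }
  structure(list(n_genes = n_genes, n_housekeeping = n_housekeeping,
                 replicates = replicates, treatments = treatments,
                 times = times, effects = effects,
                 noise_sigma = noise_sigma, base_scale = base_scale,
                 abundance_range = abundance_range, bg_level = bg_level,
                 seed = seed),
            class = "experiment_config")
}

housekeeping_symbols <- function(n) {
  base <- c("TUBA1A", "B2M", "ACTB", "GAPDH", "TFRC")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("HK%02d", seq_len(n - length(base))))
}

#' Simulate a focused two-color array experiment
#'
#' Generates per-hybridization spot tables with planted fold effects and
#' log-normal multiplicative noise, together with the matching manifest,
#' array design, and the ground-truth effect table. Each chip's control
#' channel measures the per-gene baseline abundance; the test channel
#' measures the same expectation multiplied by the planted effect, with
#' independent noise per channel and spot. Housekeeping genes always have
#' effect 1, so their processed ratios have expectation 1 everywhere.
#'
#' @param config An [experiment_config()].
#' @return A list with elements `spots` (one spot table covering all
#'   hybridizations), `manifest`, `design`, and `truth` (the complete
#'   gene x treatment x time effect table, effect 1 where nothing was
#'   planted).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  with_seed(config$seed, {
    n_hk <- config$n_housekeeping
    hk <- housekeeping_symbols(n_hk)
    n_reg <- config$n_genes - n_hk
    genes <- sprintf("GENE%03d", seq_len(n_reg))
    all_genes <- c(hk, genes)
    design <- tibble(
      gene_symbol = all_genes,
      gene_id = seq_along(all_genes) + 100000L,
      category = c(rep("housekeeping", n_hk),
                   rep(setdiff(gene_categories(), "housekeeping"),
                       length.out = n_reg)),
      is_housekeeping = c(rep(TRUE, n_hk), rep(FALSE, n_reg))
    )
    conditions <- tidyr::expand_grid(treatment = config$treatments,
                                     time_h = config$times)
    manifest <- conditions %>%
      mutate(hybridization_id = sprintf("HYB%03d", row_number()),
             test_label = ifelse(.data$treatment == "LPS", "LPS",
                                 paste0(.data$treatment, "+LPS")),
             control_label = ifelse(.data$treatment == "LPS", "vehicle",
                                    "LPS")) %>%
      select("hybridization_id", "treatment", "time_h",
             "test_label", "control_label")

    truth <- tidyr::expand_grid(gene_symbol = all_genes, conditions) %>%
      mutate(effect = 1)
    if (!is.null(config$effects)) {
      eff <- config$effects
      if (any(eff$gene_symbol %in% hk & eff$effect != 1)) {
        abort("housekeeping genes cannot carry planted effects")
      }
      key_truth <- paste(truth$gene_symbol, truth$treatment, truth$time_h)
      key_eff <- paste(eff$gene_symbol, eff$treatment, eff$time_h)
      idx <- match(key_eff, key_truth)
      if (anyNA(idx)) abort("planted effect refers to unknown condition")
      truth$effect[idx] <- eff$effect
    }

    lo <- log(config$abundance_range[1])
    hi <- log(config$abundance_range[2])
    abundance <- setNames(exp(runif(length(all_genes), lo, hi)) *
                            config$base_scale, all_genes)

    spots <- tidyr::expand_grid(
      hybridization_id = manifest$hybridization_id,
      gene_symbol = all_genes,
      replicate = seq_len(config$replicates)
    ) %>%
      left_join(select(manifest, "hybridization_id", "treatment", "time_h"),
                by = "hybridization_id") %>%
      left_join(truth, by = c("gene_symbol", "treatment", "time_h"))
    k <- nrow(spots)
    noise <- function() exp(rnorm(k, 0, config$noise_sigma))
    base_sig <- abundance[spots$gene_symbol]
    spots <- spots %>%
      mutate(
        probe_id = paste0(.data$gene_symbol, "_", .data$replicate),
        ch_control_bg = config$bg_level,
        ch_test_bg = config$bg_level,
        ch_control_fg = config$bg_level + base_sig * noise(),
        ch_test_fg = config$bg_level + base_sig * .data$effect * noise(),
        flag = "ok"
      ) %>%
      select("hybridization_id", "probe_id", "gene_symbol", "replicate",
             "ch_control_fg", "ch_control_bg", "ch_test_fg", "ch_test_bg",
             "flag")
    list(spots = spots, manifest = manifest, design = design,
         truth = select(truth, "gene_symbol", "treatment", "time_h",
                        "effect"))
  })
}

#' Configure a synthetic signaling network with a planted regulator
#'
#' @param n_nodes Total node count (default 200).
#' @param regulator Identifier of the planted master regulator.
#' @param query_depths Named integer vector: query gene node ids and the
#'   exact depth (1..`max_depth`) at which the regulator is wired to each,
#'   via fresh intermediate nodes.
#' @param max_depth Depth bound the wiring must respect (default 4).
#' @param n_distractors Number of distractor regulators, each wired
#'   directly to a strict subset of the query genes.
#' @param distractor_max_coverage Largest number of query genes a
#'   distractor may reach (default 7).
#' @param p_inhibit Probability that any generated edge is inhibiting.
#' @param n_filler_edges Random edges added among the remaining (filler)
#'   nodes; filler edges never target the planted scaffold or the query
#'   genes, so distractors are the only partial coverers by construction.
#' @param seed Integer seed.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_nodes = 200,
                           regulator = "MASTER",
                           query_depths = setNames(
                             rep(1:4, length.out = 10),
                             sprintf("QGENE%02d", 1:10)),
                           max_depth = 4,
                           n_distractors = 5,
                           distractor_max_coverage = 7,
                           p_inhibit = 0.3,
                           n_filler_edges = 150,
                           seed = 1) {
  if (any(query_depths > max_depth)) {
    abort("query wiring depths must not exceed max_depth")
  }
  if (any(query_depths < 1)) abort("wiring depths must be >= 1")
  if (is.null(names(query_depths))) abort("query_depths must be named")
  if (distractor_max_coverage >= length(query_depths)) {
    abort("distractor coverage cap must be below the query size")
  }
  structure(list(n_nodes = n_nodes, regulator = regulator,
                 query_depths = query_depths, max_depth = max_depth,
                 n_distractors = n_distractors,
                 distractor_max_coverage = distractor_max_coverage,
                 p_inhibit = p_inhibit, n_filler_edges = n_filler_edges,
                 seed = seed),
            class = "network_config")
}

#' Simulate a signaling network with a planted master regulator
#'
#' The planted regulator is wired to every query gene at its configured
#' depth through chains of fresh intermediate nodes; distractor nodes get
#' direct edges to strict subsets of the query genes; remaining filler
#' nodes receive random edges among themselves. Edge signs are Bernoulli
#' with the configured inhibition probability. Every query gene's observed
#' direction is the direction its planted chain predicts when the
#' regulator is active.
#'
#' @param config A [network_config()].
#' @return A list with `network` (a [as_signaling_network()] object) and
#'   `truth` (regulator id, query table with `gene`, `depth`, `direction`,
#'   and the distractor assignments).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, {
    qg <- names(config$query_depths)
    depths <- unname(config$query_depths)
    draw_sign <- function(n) {
      ifelse(runif(n) < config$p_inhibit, "inhibit", "activate")
    }
    edges <- list()
    direction <- character(length(qg))
    for (i in seq_along(qg)) {
      chain <- c(config$regulator,
                 if (depths[i] > 1)
                   sprintf("INT_%s_%d", qg[i], seq_len(depths[i] - 1)),
                 qg[i])
      signs <- draw_sign(length(chain) - 1)
      edges[[length(edges) + 1]] <- tibble(
        source = chain[-length(chain)], sign = signs, target = chain[-1])
      direction[i] <- if (path_sign(signs) == "net_activate") "up" else "down"
    }
    distractors <- sprintf("DISTR%02d", seq_len(config$n_distractors))
    distr_truth <- purrr::map_dfr(distractors, function(d) {
      k <- sample(config$distractor_max_coverage, 1)
      targets <- sample(qg, k)
      edges[[length(edges) + 1]] <<- tibble(
        source = d, sign = draw_sign(k), target = targets)
      tibble(distractor = d, n_targets = k)
    })
    planted_edges <- bind_rows(edges)
    named <- unique(c(config$regulator, qg, distractors,
                      planted_edges$source, planted_edges$target))
    n_filler <- config$n_nodes - length(named)
    if (n_filler < 2) abort("n_nodes too small for the planted structure")
    filler <- sprintf("NODE%03d", seq_len(n_filler))
    src <- sample(filler, config$n_filler_edges, replace = TRUE)
    tgt <- sample(filler, config$n_filler_edges, replace = TRUE)
    keep <- src != tgt
    filler_edges <- tibble(source = src[keep],
                           sign = draw_sign(sum(keep)),
                           target = tgt[keep])
    # isolated filler nodes still need to exist in the graph
    lonely <- setdiff(filler, c(filler_edges$source, filler_edges$target))
    anchor_edges <- if (length(lonely) > 0) {
      tibble(source = lonely, sign = draw_sign(length(lonely)),
             target = sample(filler[!filler %in% lonely],
                             length(lonely), replace = TRUE))
    }
    network <- as_signaling_network(
      bind_rows(planted_edges, filler_edges, anchor_edges))
    list(network = network,
         truth = list(regulator = config$regulator,
                      query = tibble(gene = qg, depth = depths,
                                     direction = direction),
                      distractors = distr_truth))
  })
}

#' Noise-free synthetic profiles embodying each regulation mode
#'
#' Draws log2 anchor values inside the defining region of each kinetic
#' regulation mode (with a safety margin away from the `theta` boundary),
#' for testing and calibrating the mode classifier.
#'
#' @param n_per_mode Profiles per mode.
#' @param theta Response threshold on the log2 scale.
#' @param times Time grid; must contain the 0.5, 2 and 4 h anchors.
#' @param margin Fraction of `theta` kept clear of the decision boundary.
#' @param seed Integer seed.
#' @return A `phyto_profiles` tibble with a `true_mode` column.
#' @export
make_mode_profiles <- function(n_per_mode = 10, theta = log2(1.5),
                               times = c(0.5, 2, 4, 12), margin = 0.2,
                               seed = 1) {
  stopifnot(all(c(0.5, 2, 4) %in% times))
  with_seed(seed, {
    lo_in <- -(1 - margin) * theta   # inside the no-response band
    hi_in <- (1 - margin) * theta
    beyond <- function(n) theta * (1 + margin + runif(n))  # past threshold
    inside <- function(n) runif(n, lo_in, hi_in)
    anchor_idx <- match(c(0.5, 2, 4), times)
    one_mode <- function(mode, i) {
      vals <- inside(length(times))  # non-anchor times stay in the band
      vals[anchor_idx] <- switch(mode,
        EARLY_DOWN_THEN_UP = c(-beyond(1), inside(1), beyond(1)),
        DELAYED_DOWN_THEN_UP = c(inside(1), -beyond(1), beyond(1)),
        EARLY_NONE_THEN_UP = c(inside(1), inside(1), beyond(1)),
        OTHER = inside(3))
      tibble(gene_symbol = sprintf("%s_%02d", mode, i),
             treatment = "synthetic", time_h = times,
             log2_ratio = vals, true_mode = mode)
    }
    profiles <- purrr::map_dfr(regulation_modes(), function(m) {
      purrr::map_dfr(seq_len(n_per_mode), function(i) one_mode(m, i))
    })
    profiles <- arrange(profiles, .data$gene_symbol, .data$time_h)
    class(profiles) <- c("phyto_profiles", class(profiles))
    profiles
  })
}

#' Decoy genes for filter specificity checks
#'
#' Generates genes whose ratios all lie strictly inside the non-significant
#' band (1/threshold, threshold), so a correct fold-change filter must
#' reject every one of them.
#'
#' @param n Number of decoy genes.
#' @param treatments Treatment column names to generate.
#' @param threshold The fold threshold the decoys must evade (default 3).
#' @param seed Integer seed.
#' @return A wide tibble shaped like the published ratio tables.
#' @export
simulate_decoy_genes <- function(n = 50,
                                 treatments = c("shikonin", "emodin",
                                                "cytopiloyne", "BF"),
                                 threshold = 3, seed = 1) {
  with_seed(seed, {
    # stay 5% clear of the boundary so printed rounding cannot flip a call
    lo <- log2(1 / threshold) * 0.95
    hi <- log2(threshold) * 0.95
    vals <- matrix(2^runif(n * length(treatments), lo, hi), nrow = n)
    colnames(vals) <- treatments
    bind_cols(
      tibble(gene_symbol = sprintf("DECOY%03d", seq_len(n)),
             gene_id = 900000L + seq_len(n),
             category = rep(setdiff(gene_categories(), "housekeeping"),
                            length.out = n)),
      as_tibble(vals))
  })
}
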