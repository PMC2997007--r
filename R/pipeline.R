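pipeline_defaults <- function() {
  list(
    spot_tables = NULL,     # directory or vector of spot-table TSVs
    manifest = NULL,
    design = NULL,
    network = NULL,         # optional SIF-like TSV
    out_dir = NULL,
    fold_threshold = 3,
    theta = log2(1.5),
    metric = "euclidean_log2",
    max_depth = 4,
    aggregate = "median",
    reference_gene = NULL,  # default: ACTB if present, else first housekeeping
    ratio_semantics = "lps_ref",  # or "vehicle_ref"
    reference_treatment = "cytopiloyne",
    filter_treatments = NULL,     # default: all non-LPS treatments
    filter_time_h = NULL,         # default: every time point
    filter_direction = "both",
    keynode_time_h = NULL,        # default: first filter time with hits
    lps_treatment = "LPS",
    seed = 1
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) abort("config must set out_dir")
  if (cfg$fold_threshold <= 1) abort("fold_threshold must be > 1")
  if (cfg$theta <= 0) abort("theta must be > 0")
  if (cfg$max_depth < 1) abort("max_depth must be >= 1")
  if (!cfg$ratio_semantics %in% c("lps_ref", "vehicle_ref")) {
    abort("ratio_semantics must be 'lps_ref' or 'vehicle_ref'")
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end: ingest spot tables, process them into a
#' normalized treatment:LPS ratio matrix, apply the fold-change filter,
#' classify kinetic regulation modes and score concordance against the
#' reference treatment, cluster the treatments by UPGMA, and (when a
#' signaling network is supplied) run the key-node search on the filtered
#' genes. All outputs are TSV (plus a Newick dendrogram and a run log with
#' parameter echo and input checksums) written to `out_dir` only after
#' every stage has succeeded, so a failing run leaves no partial outputs.
#' Re-running with identical inputs and config reproduces identical files.
#'
#' @param config A named list or path to a YAML file. Recognised keys (all
#'   others are rejected): `spot_tables` (directory or file paths),
#'   `manifest`, `design`, `network`, `out_dir`, `fold_threshold`, `theta`,
#'   `metric`, `max_depth`, `aggregate`, `reference_gene`,
#'   `ratio_semantics` (`"lps_ref"` when compound chips hybridize against
#'   LPS, `"vehicle_ref"` when all chips hybridize against vehicle and the
#'   treatment:LPS ratio is formed as a ratio of ratios),
#'   `reference_treatment`, `filter_treatments`, `filter_time_h`,
#'   `filter_direction`, `keynode_time_h`, `lps_treatment`, `seed`.
#' @return Invisibly, a named list of the computed result objects.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)

  inputs <- stage("ingest", {
    paths <- cfg$spot_tables
    if (is.null(paths) || is.null(cfg$manifest) || is.null(cfg$design)) {
      abort("spot_tables, manifest and design are required")
    }
    if (length(paths) == 1 && dir.exists(paths)) {
      paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
    }
    for (p in c(paths, cfg$manifest, cfg$design, cfg$network)) {
      if (!file.exists(p)) abort(paste0("input not found: ", p))
    }
    list(
      spots = purrr::map_dfr(paths, read_spot_table),
      manifest = read_manifest(cfg$manifest),
      design = read_array_design(cfg$design),
      network = if (!is.null(cfg$network)) load_network(cfg$network),
      checksums = tools::md5sum(c(paths, cfg$manifest, cfg$design,
                                  cfg$network))
    )
  })

  ratios <- stage("process", {
    reference <- cfg$reference_gene
    if (is.null(reference)) {
      hk <- inputs$design$gene_symbol[inputs$design$is_housekeeping]
      reference <- if ("ACTB" %in% hk) "ACTB" else hk[1]
    }
    raw <- process_experiment(inputs$spots, inputs$manifest, inputs$design,
                              aggregate = cfg$aggregate)
    normalize_to_reference(raw, reference, inputs$design)
  })

  vs_lps <- stage("process", {
    if (cfg$ratio_semantics == "vehicle_ref") {
      treatment_vs_lps(ratios, cfg$lps_treatment)
    } else {
      filter(ratios, .data$treatment != cfg$lps_treatment)
    }
  })

  hits <- stage("filter", {
    treatments <- cfg$filter_treatments %||%
      setdiff(unique(vs_lps$treatment), cfg$lps_treatment)
    times <- cfg$filter_time_h %||% sort(unique(vs_lps$time_h))
    purrr::map_dfr(times, function(t) {
      ratio_wide(vs_lps, time_h = t) %>%
        left_join(select(inputs$design, "gene_symbol", "gene_id",
                         "category"), by = "gene_symbol") %>%
        filter_fold_change(treatments, threshold = cfg$fold_threshold,
                           direction = cfg$filter_direction) %>%
        mutate(time_h = t)
    })
  })

  modes <- stage("modes", {
    profiles <- build_profiles(vs_lps)
    classify_modes(profiles, theta = cfg$theta)
  })

  baseline <- stage("modes", {
    if (cfg$ratio_semantics == "vehicle_ref" &&
        cfg$lps_treatment %in% ratios$treatment) {
      lps_prof <- build_profiles(ratios, treatments = cfg$lps_treatment)
      classify_baseline(lps_prof, theta = cfg$theta)
    }
  })

  conc <- stage("concordance", {
    if (cfg$reference_treatment %in% modes$treatment) {
      suppressWarnings(concordance_table(modes, cfg$reference_treatment))
    }
  })

  linkage <- stage("cluster", {
    wide <- vs_lps %>%
      mutate(condition = paste0(.data$gene_symbol, "@", .data$time_h)) %>%
      select("treatment", "condition", "ratio") %>%
      tidyr::pivot_wider(names_from = "condition", values_from = "ratio") %>%
      tidyr::drop_na()
    upgma(profile_dist(wide, metric = cfg$metric))
  })

  keynodes <- stage("keynode", {
    if (!is.null(inputs$network) && nrow(hits) > 0) {
      t <- cfg$keynode_time_h %||% hits$time_h[1]
      query <- hits %>%
        filter(.data$time_h == t, .data$direction %in% c("up", "down")) %>%
        distinct(.data$gene_symbol, .data$direction) %>%
        rename(gene = "gene_symbol")
      if (nrow(query) > 0) {
        find_key_nodes(inputs$network, query, max_depth = cfg$max_depth)
      }
    }
  })

  stage("write", {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    write_ratio_matrix(vs_lps, out("ratio_matrix.tsv"))
    readr::write_tsv(hits, out("hits.tsv"))
    readr::write_tsv(modes, out("modes.tsv"))
    if (!is.null(baseline)) readr::write_tsv(baseline, out("baseline.tsv"))
    if (!is.null(conc)) readr::write_tsv(conc, out("concordance.tsv"))
    readr::write_tsv(tidy(linkage), out("linkage.tsv"))
    writeLines(to_newick(linkage), out("dendrogram.nwk"))
    if (!is.null(keynodes)) {
      readr::write_tsv(keynodes, out("keynodes.tsv"))
      writeLines(c(
        paste0("key-node search at max depth ", cfg$max_depth),
        paste0("query size: ", attr(keynodes, "n_query"),
               "; unmapped: ", length(attr(keynodes, "unmapped"))),
        paste0("full-coverage nodes: ",
               paste(keynodes$node[keynodes$coverage == 1],
                     collapse = ", "))
      ), out("keynodes.txt"))
    }
    writeLines(c(
      "phytoarray pipeline run",
      paste0("parameters: ", paste(
        vapply(setdiff(names(cfg), c("spot_tables", "out_dir")), function(k) {
          paste0(k, "=", paste(format(cfg[[k]]), collapse = ","))
        }, character(1)), collapse = " ")),
      "input checksums:",
      paste0("  ", names(inputs$checksums), " ", inputs$checksums),
      paste0("genes x conditions: ", length(unique(vs_lps$gene_symbol)),
             " x ", nrow(distinct(vs_lps, .data$treatment, .data$time_h))),
      paste0("fold-change hits: ", nrow(hits))
    ), out("run_log.txt"))
  })

  invisible(list(ratios = vs_lps, hits = hits, modes = modes,
                 baseline = baseline, concordance = conc,
                 linkage = linkage, keynodes = keynodes))
}
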