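fixture_files <- c(
  table1 = "table1_down_shikonin_emodin_0.5h.tsv",
  table2 = "table2_up_cytopiloyne_bf_4h.tsv",
  table3 = "table3_down_cytopiloyne_bf_12h.tsv",
  fig5b_network = "network_fig5b_erk12_synthetic.tsv",
  fig6a_network = "network_fig6a_rad23a_synthetic.tsv",
  fig6b_network = "network_fig6b_e6ap_synthetic.tsv",
  fig6c_network = "network_fig6c_e6ap_synthetic.tsv",
  fig7_network = "network_fig7_lck_synthetic.tsv"
)

table_meta <- list(
  table1 = list(direction = "down", treatments = c("shikonin", "emodin"),
                time_h = 0.5),
  table2 = list(direction = "up", treatments = c("cytopiloyne", "BF"),
                time_h = 4),
  table3 = list(direction = "down", treatments = c("cytopiloyne", "BF"),
                time_h = 12)
)

# regulated gene sets and expected master regulator for each network
# fixture; the network topologies are synthetic reconstructions, so these
# support qualitative (topology-level) checks only
network_meta <- list(
  fig5b_network = list(
    master = "ERK1/2", direction = "up",
    genes = c("CSF1", "SHC1", "IL5", "TNFSF14", "CD14", "ITGAX", "CXCR4",
              "MADCAM1", "CCR1")),
  fig6a_network = list(
    master = "Rad23A", direction = "down",
    genes = c("TNF", "IL1B", "CCL4", "CCL8", "PTGS2", "IL2RA", "SELP",
              "STAT1", "NFATC3", "IL4")),
  fig6b_network = list(
    master = "E6-AP", direction = "down",
    genes = c("PTGS2", "IL2RA", "SELP", "LILRB4", "ETS1", "TAP2", "CCR2",
              "NFATC3", "IL4", "STAT1")),
  fig6c_network = list(
    master = "E6-AP", direction = "down",
    genes = c("IL4", "IRF1", "GATA3", "NFATC3", "PTGS2", "CCR2", "CCR3",
              "CXCR4", "CLEC1A", "BCL2")),
  fig7_network = list(
    master = "Lck", direction = "down",
    genes = c("CCL2", "SLAMF1", "ANXA3", "ITK", "CD80", "IL8RB", "IGSF6",
              "LIFR", "IL7R", "MPO"))
)

#' Packaged fixtures of the published tables and figure networks
#'
#' `phyto_fixture()` returns one packaged payload: the three published
#' treatment:LPS ratio tables (transcribed verbatim, as printed to two
#' decimals), or one of the figure signaling networks. The ratio tables
#' carry attributes `direction`, `treatments` and `time_h` describing the
#' fold rule each table was built with. The figure networks are *synthetic
#' reconstructions* — the published figures convey their topology
#' graphically and only the qualitative claim (which node is the sole
#' full-coverage master regulator over which regulated gene set) is
#' preserved — so they support topology-level tests, never numeric claims.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`,
#'   `"fig5b_network"`, `"fig6a_network"`, `"fig6b_network"`,
#'   `"fig6c_network"`, `"fig7_network"`.
#' @return A wide ratio tibble for table fixtures; a
#'   [as_signaling_network()] object for network fixtures, with attributes
#'   `query` (tibble of `gene`, `direction`) and `master`.
#' @export
phyto_fixture <- function(name) {
  if (!name %in% names(fixture_files)) {
    abort(paste0("unknown fixture '", name, "'; available: ",
                 paste(names(fixture_files), collapse = ", ")))
  }
  path <- system.file("extdata", fixture_files[[name]],
                      package = "phytoarray", mustWork = TRUE)
  if (startsWith(name, "table")) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    meta <- table_meta[[name]]
    attr(tbl, "direction") <- meta$direction
    attr(tbl, "treatments") <- meta$treatments
    attr(tbl, "time_h") <- meta$time_h
    tbl
  } else {
    net <- load_network(path)
    meta <- network_meta[[name]]
    attr(net, "query") <- tibble(gene = meta$genes,
                                 direction = meta$direction)
    attr(net, "master") <- meta$master
    net
  }
}

#' @rdname phyto_fixture
#' @return `fixture_names()`: the available fixture names.
#' @export
fixture_names <- function() names(fixture_files)

#' Combined long ratio table of the three published tables
#'
#' Stacks the three table fixtures into one long treatment:LPS ratio table
#' (each table contributes its own time point), suitable for clustering the
#' four treatments.
#'
#' @return A long tibble (`gene_symbol`, `gene_id`, `category`,
#'   `treatment`, `time_h`, `ratio`).
#' @export
combined_tables <- function() {
  purrr::map_dfr(c("table1", "table2", "table3"), function(nm) {
    tbl <- phyto_fixture(nm)
    tbl %>%
      mutate(time_h = attr(tbl, "time_h"), table = nm) %>%
      tidyr::pivot_longer(c("shikonin", "emodin", "cytopiloyne", "BF"),
                          names_to = "treatment", values_to = "ratio")
  })
}
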