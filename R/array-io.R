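#' Read an array design table
#'
#' The design lists every probed gene, its Entrez identifier, its functional
#' category, and whether it is a housekeeping (internal control) gene usable
#' as a normalization reference.
#'
#' @param path Path to a TSV file with columns `gene_symbol`, `gene_id`,
#'   `category`, `is_housekeeping`.
#' @return A tibble with those columns; `category` is a factor with levels
#'   `cytokines`, `chemotaxis_migration`, `inflammatory_response`, `other`,
#'   `housekeeping`.
#' @export
read_array_design <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE)
  validate_array_design(design)
}

#' @rdname read_array_design
#' @param design A data frame to validate/coerce in place of a file.
#' @export
validate_array_design <- function(design) {
  required <- c("gene_symbol", "gene_id", "category", "is_housekeeping")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    abort(paste0("array design is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$gene_symbol)) {
    dup <- unique(design$gene_symbol[duplicated(design$gene_symbol)])
    abort(paste0("duplicated gene symbols in array design: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  design <- as_tibble(design)
  design$category <- factor(design$category, levels = gene_categories())
  if (anyNA(design$category)) {
    abort("array design contains categories outside the documented set")
  }
  design$is_housekeeping <- as.logical(design$is_housekeeping)
  design
}

#' @rdname read_array_design
#' @export
gene_categories <- function() {
  c("cytokines", "chemotaxis_migration", "inflammatory_response",
    "other", "housekeeping")
}

#' Read a hybridization manifest
#'
#' One row per two-color hybridization: which treatment and time point the
#' chip interrogates, and what each dye channel contains (`test_label` is the
#' Cy5/test sample, `control_label` the Cy3/control sample).
#'
#' @param path TSV with columns `hybridization_id`, `treatment`, `time_h`,
#'   `test_label`, `control_label`.
#' @return A tibble; errors if any (treatment, time) pair occurs twice.
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_tsv(path, show_col_types = FALSE)
  validate_manifest(manifest)
}

#' @rdname read_manifest
#' @param manifest A data frame to validate in place of a file.
#' @export
validate_manifest <- function(manifest) {
  required <- c("hybridization_id", "treatment", "time_h",
                "test_label", "control_label")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  key <- paste(manifest$treatment, manifest$time_h)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (treatment, time) pairs in manifest: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (any(!is.finite(manifest$time_h) | manifest$time_h <= 0)) {
    abort("manifest time_h must be finite and positive")
  }
  as_tibble(manifest)
}

#' Read a per-hybridization spot table
#'
#' Spot-level two-channel intensities as exported from image quantification:
#' foreground and background for the control (Cy3) and test (Cy5) channel of
#' every replicate spot.
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`, `replicate`,
#'   `ch_control_fg`, `ch_control_bg`, `ch_test_fg`, `ch_test_bg`, `flag`.
#' @param hybridization_id Identifier attached to every row; defaults to the
#'   file name without extension.
#' @return A tibble with a `hybridization_id` column prepended.
#' @export
read_spot_table <- function(path, hybridization_id = NULL) {
  spots <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(hybridization_id)) {
    spots$hybridization_id <- hybridization_id
  } else if (!"hybridization_id" %in% names(spots)) {
    # a file may carry chips for several hybridizations in one table;
    # otherwise the file name identifies the chip
    spots$hybridization_id <- tools::file_path_sans_ext(basename(path))
  }
  validate_spot_table(spots)
}

#' @rdname read_spot_table
#' @param spots A data frame to validate in place of a file.
#' @export
validate_spot_table <- function(spots) {
  required <- c("hybridization_id", "probe_id", "gene_symbol", "replicate",
                "ch_control_fg", "ch_control_bg", "ch_test_fg", "ch_test_bg",
                "flag")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    abort(paste0("spot table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(spots$flag %in% c("ok", "bad"))) {
    abort("spot table flag must be 'ok' or 'bad'")
  }
  key <- paste(spots$hybridization_id, spots$gene_symbol, spots$replicate)
  if (anyDuplicated(key)) {
    abort("each (hybridization, gene, replicate) may appear at most once")
  }
  intensity_cols <- c("ch_control_fg", "ch_control_bg",
                      "ch_test_fg", "ch_test_bg")
  for (col in intensity_cols) {
    x <- spots[[col]]
    bad <- !is.finite(x) | x < 0
    if (any(bad)) {
      abort(paste0("non-finite or negative intensity in ", col,
                   " for probe(s): ",
                   paste(head(spots$probe_id[bad], 5), collapse = ", ")))
    }
  }
  as_tibble(spots)[union(required, names(spots))]
}

#' Write / read a ratio matrix as TSV
#'
#' The long (gene, treatment, time, ratio) table is laid out wide with one
#' column per condition, named `treatment@time` (e.g. `cytopiloyne@4`).
#'
#' @param ratios Long ratio table with columns `gene_symbol`, `treatment`,
#'   `time_h`, `ratio`.
#' @param path Output (input) file path.
#' @return `write_ratio_matrix()` returns `path` invisibly;
#'   `read_ratio_matrix()` returns the long tibble.
#' @export
write_ratio_matrix <- function(ratios, path) {
  wide <- ratios %>%
    mutate(condition = paste0(.data$treatment, "@", .data$time_h)) %>%
    select("gene_symbol", "condition", "ratio") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "ratio")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_ratio_matrix
#' @export
read_ratio_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene_symbol",
                              names_to = "condition", values_to = "ratio")
  parts <- stringr::str_split_fixed(long$condition, "@", 2)
  long %>%
    mutate(treatment = parts[, 1], time_h = as.numeric(parts[, 2])) %>%
    select("gene_symbol", "treatment", "time_h", "ratio")
}
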