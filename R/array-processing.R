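#' Background-correct two-channel spot intensities
#'
#' Subtracts the local background estimate from the foreground of each
#' channel and floors the result at a small positive value so that
#' downstream ratios stay finite and positive.
#'
#' @param spots A spot table (see [read_spot_table()]).
#' @param floor Minimum corrected intensity, in the same intensity units as
#'   the input (default 1).
#' @return The input tibble with two added columns, `control_intensity` and
#'   `test_intensity`, each equal to `max(fg - bg, floor)`.
#' @export
background_correct <- function(spots, floor = 1) {
  for (ch in c("control", "test")) {
    fg <- spots[[paste0("ch_", ch, "_fg")]]
    bg <- spots[[paste0("ch_", ch, "_bg")]]
    bad <- !is.finite(fg) | fg < 0 | !is.finite(bg) | bg < 0
    if (any(bad)) {
      abort(paste0("invalid ", ch, "-channel intensity for probe(s): ",
                   paste(head(spots$probe_id[bad], 5), collapse = ", ")))
    }
    spots[[paste0(ch, "_intensity")]] <- pmax(fg - bg, floor)
  }
  spots
}

#' Aggregate replicate spot ratios into one gene-level ratio
#'
#' Each gene is printed as several replicate spots per chip; the gene-level
#' expression ratio is the median (default) or mean of the per-spot
#' test:control ratios that survive quality flagging.
#'
#' @param ratios Numeric vector of per-spot ratios (flagged spots already
#'   removed).
#' @param method `"median"` (default) or `"mean"`.
#' @return A single positive ratio, or `NA_real_` when no usable replicate
#'   remains (the gene is then treated as missing for that hybridization).
#' @export
aggregate_replicates <- function(ratios, method = c("median", "mean")) {
  method <- match.arg(method)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0) {
    return(NA_real_)
  }
  if (method == "median") median(ratios) else mean(ratios)
}

#' Process raw spot tables into a gene-by-condition ratio matrix
#'
#' Runs the full per-chip chain: background correction, per-spot
#' test:control ratio, exclusion of flagged spots, and replicate
#' aggregation, then joins the hybridization manifest to label each chip
#' with its treatment and time point. Genes whose replicates are all
#' flagged on a chip are reported missing (with a message) and dropped.
#'
#' @param spots Spot table covering one or more hybridizations.
#' @param manifest Hybridization manifest (see [read_manifest()]).
#' @param design Array design (see [read_array_design()]); used to restrict
#'   to designed genes when supplied.
#' @param aggregate Replicate aggregation method, `"median"` or `"mean"`.
#' @param floor Background-correction floor passed to
#'   [background_correct()].
#' @return A long tibble (`gene_symbol`, `treatment`, `time_h`, `ratio`)
#'   of linear test:control expression ratios, one row per gene and
#'   condition.
#' @export
process_experiment <- function(spots, manifest, design = NULL,
                               aggregate = c("median", "mean"), floor = 1) {
  aggregate <- match.arg(aggregate)
  spots <- validate_spot_table(spots)
  manifest <- validate_manifest(manifest)
  if (!is.null(design)) {
    design <- validate_array_design(design)
    spots <- semi_join(spots, design, by = "gene_symbol")
  }
  corrected <- background_correct(spots, floor = floor)
  per_gene <- corrected %>%
    filter(.data$flag == "ok") %>%
    mutate(spot_ratio = .data$test_intensity / .data$control_intensity) %>%
    group_by(.data$hybridization_id, .data$gene_symbol) %>%
    summarise(ratio = aggregate_replicates(.data$spot_ratio, aggregate),
              .groups = "drop")

  n_expected <- length(unique(spots$gene_symbol)) * nrow(manifest)
  n_missing <- n_expected - nrow(per_gene)
  if (n_missing > 0) {
    inform(paste0(n_missing, " gene/hybridization pair(s) had no usable ",
                  "replicate and are reported missing"))
  }
  per_gene %>%
    left_join(select(manifest, "hybridization_id", "treatment", "time_h"),
              by = "hybridization_id") %>%
    select("gene_symbol", "treatment", "time_h", "ratio") %>%
    arrange(.data$treatment, .data$time_h, .data$gene_symbol)
}

#' Normalize a ratio matrix to a housekeeping reference gene
#'
#' Divides every gene's ratio in each condition by the reference gene's
#' ratio in the same condition, so that chip-level dye or loading bias
#' cancels. After normalization the reference gene's own row is exactly 1
#' in every condition; applying the normalization twice is a no-op.
#'
#' @param ratios Long ratio table (`gene_symbol`, `treatment`, `time_h`,
#'   `ratio`).
#' @param reference_gene Symbol of the reference gene (conventionally
#'   beta-actin; any housekeeping gene on the design works).
#' @param design Optional array design; when given, the reference must be
#'   flagged `is_housekeeping`.
#' @return The ratio table with normalized `ratio`, carrying the reference
#'   gene in attribute `reference_gene`.
#' @export
normalize_to_reference <- function(ratios, reference_gene, design = NULL) {
  if (!is.null(design)) {
    design <- validate_array_design(design)
    hk <- design$gene_symbol[design$is_housekeeping]
    if (!reference_gene %in% hk) {
      abort(paste0("reference gene '", reference_gene,
                   "' is not housekeeping-flagged in the design"))
    }
  }
  ref <- ratios %>%
    filter(.data$gene_symbol == reference_gene) %>%
    select("treatment", "time_h", ref_ratio = "ratio")
  conditions <- distinct(ratios, .data$treatment, .data$time_h)
  check <- left_join(conditions, ref, by = c("treatment", "time_h"))
  bad <- is.na(check$ref_ratio) | check$ref_ratio <= 0 |
    !is.finite(check$ref_ratio)
  if (any(bad)) {
    abort(paste0(
      "reference gene '", reference_gene,
      "' is missing or non-positive in condition(s): ",
      paste(paste0(check$treatment[bad], "@", check$time_h[bad]),
            collapse = ", ")))
  }
  out <- ratios %>%
    left_join(ref, by = c("treatment", "time_h")) %>%
    mutate(ratio = .data$ratio / .data$ref_ratio) %>%
    select(-"ref_ratio")
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Convert vehicle-referenced ratios to treatment:LPS ratios
#'
#' On chip designs where every sample (LPS alone and each compound + LPS)
#' is hybridized against vehicle, the compound effect relative to LPS is
#' the ratio of ratios: (compound+LPS : vehicle) / (LPS : vehicle) at the
#' same gene and time point. `ratio_of_ratios()` is the scalar/vector
#' primitive; `treatment_vs_lps()` applies it across a long ratio table.
#'
#' @param test_vs_vehicle,lps_vs_vehicle Positive linear ratios for the
#'   same gene and time point.
#' @return `ratio_of_ratios()`: the element-wise quotient.
#' @export
ratio_of_ratios <- function(test_vs_vehicle, lps_vs_vehicle) {
  if (any(!is.finite(test_vs_vehicle) | test_vs_vehicle <= 0) ||
      any(!is.finite(lps_vs_vehicle) | lps_vs_vehicle <= 0)) {
    abort("ratios must be finite and strictly positive")
  }
  test_vs_vehicle / lps_vs_vehicle
}

#' @rdname ratio_of_ratios
#' @param ratios Long vehicle-referenced ratio table containing the
#'   `lps_treatment` rows and one or more compound treatments.
#' @param lps_treatment Treatment label of the LPS-only chips.
#' @return `treatment_vs_lps()`: a long ratio table of compound treatments
#'   re-expressed against LPS (the LPS rows themselves are dropped).
#' @export
treatment_vs_lps <- function(ratios, lps_treatment = "LPS") {
  lps <- ratios %>%
    filter(.data$treatment == lps_treatment) %>%
    select("gene_symbol", "time_h", lps_ratio = "ratio")
  if (nrow(lps) == 0) {
    abort(paste0("no rows with treatment '", lps_treatment, "'"))
  }
  ratios %>%
    filter(.data$treatment != lps_treatment) %>%
    left_join(lps, by = c("gene_symbol", "time_h")) %>%
    filter(!is.na(.data$lps_ratio)) %>%
    mutate(ratio = ratio_of_ratios(.data$ratio, .data$lps_ratio)) %>%
    select(-"lps_ratio")
}

#' Filter genes by fold change
#'
#' The differential rule of the analysis: a gene is a hit when its linear
#' ratio is at least `threshold`-fold up (`ratio >= threshold`) or down
#' (`ratio <= 1/threshold`), comparisons inclusive, in any (default) or all
#' of the selected treatments.
#'
#' @param tbl Wide ratio table: one row per gene with one numeric column per
#'   treatment, plus any identifying columns (`gene_symbol`, `gene_id`,
#'   `category`, ...). Use [tidyr::pivot_wider()] (or
#'   [ratio_wide()]) to reshape a long matrix first.
#' @param treatments Character vector of treatment columns the rule is
#'   evaluated on. Must be non-empty.
#' @param threshold Fold threshold T > 1 (default 3).
#' @param rule `"any"` (default): a gene is kept if any selected treatment
#'   passes; `"all"`: every selected treatment must pass.
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return The qualifying rows, sorted by `category` then `gene_id` (when
#'   present), with added columns `direction` (`up`, `down`, or `both` if
#'   different triggering treatments disagree) and `triggering` (comma-
#'   separated treatments that satisfied the rule).
#' @export
filter_fold_change <- function(tbl, treatments, threshold = 3,
                               rule = c("any", "all"),
                               direction = c("both", "up", "down")) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  if (length(treatments) == 0) {
    abort("at least one treatment must be selected")
  }
  missing <- setdiff(treatments, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("treatment column(s) not in table: ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(threshold) || threshold <= 1) {
    abort("threshold must be a number greater than 1")
  }

  vals <- as.matrix(tbl[treatments])
  up <- vals >= threshold
  dn <- vals <= 1 / threshold
  hit <- switch(direction, up = up, down = dn, both = up | dn)
  keep <- if (rule == "any") rowSums(hit, na.rm = TRUE) > 0 else
    rowSums(hit, na.rm = TRUE) == length(treatments)

  out <- tbl[keep, , drop = FALSE]
  hit_k <- hit[keep, , drop = FALSE]
  up_k <- up[keep, , drop = FALSE] & hit_k
  dn_k <- dn[keep, , drop = FALSE] & hit_k
  out$direction <- case_when(
    rowSums(up_k, na.rm = TRUE) > 0 & rowSums(dn_k, na.rm = TRUE) > 0 ~
      "both",
    rowSums(up_k, na.rm = TRUE) > 0 ~ "up",
    TRUE ~ "down"
  )
  out$triggering <- apply(hit_k, 1, function(h) {
    paste(treatments[which(h)], collapse = ",")
  })
  if ("category" %in% names(out)) {
    out$category <- factor(out$category, levels = gene_categories())
    out <- out[lex_order(as.integer(out$category),
                         if ("gene_id" %in% names(out)) out$gene_id else
                           out$gene_symbol), , drop = FALSE]
  } else if ("gene_id" %in% names(out)) {
    out <- out[lex_order(out$gene_id), , drop = FALSE]
  }
  as_tibble(out)
}

#' Reshape a long ratio table to one wide row per gene
#'
#' @param ratios Long ratio table (`gene_symbol`, `treatment`, `time_h`,
#'   `ratio`).
#' @param time_h Optional single time point to select before widening.
#' @return A wide tibble with one ratio column per treatment.
#' @export
ratio_wide <- function(ratios, time_h = NULL) {
  if (!is.null(time_h)) {
    t <- time_h
    ratios <- filter(ratios, .data$time_h == t)
  }
  if (length(unique(ratios$time_h)) > 1) {
    abort("ratios span several time points; pass time_h to select one")
  }
  ratios %>%
    select("gene_symbol", "treatment", "ratio") %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "ratio")
}
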