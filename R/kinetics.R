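#' Build per-gene log2 time profiles
#'
#' Turns a long linear ratio table into per-gene, per-treatment time
#' profiles on the log2 scale, the scale on which kinetic regulation modes
#' are defined. Genes with a missing ratio at any time point of a treatment
#' are dropped for that treatment.
#'
#' @param ratios Long ratio table (`gene_symbol`, `treatment`, `time_h`,
#'   `ratio`), typically treatment:LPS ratios.
#' @param treatments Optional subset of treatments to keep.
#' @return A tibble (`gene_symbol`, `treatment`, `time_h`, `log2_ratio`)
#'   of class `phyto_profiles`, ordered by time within gene.
#' @export
build_profiles <- function(ratios, treatments = NULL) {
  if (!is.null(treatments)) {
    ratios <- filter(ratios, .data$treatment %in% treatments)
  }
  n_times <- ratios %>%
    group_by(.data$treatment) %>%
    summarise(k = length(unique(.data$time_h)), .groups = "drop")
  if (any(n_times$k < 2)) {
    abort(paste0("need at least 2 time points per treatment; offending: ",
                 paste(n_times$treatment[n_times$k < 2], collapse = ", ")))
  }
  profiles <- ratios %>%
    group_by(.data$gene_symbol, .data$treatment) %>%
    filter(!anyNA(.data$ratio)) %>%
    ungroup() %>%
    mutate(log2_ratio = log2(.data$ratio)) %>%
    select("gene_symbol", "treatment", "time_h", "log2_ratio") %>%
    arrange(.data$treatment, .data$gene_symbol, .data$time_h)
  class(profiles) <- c("phyto_profiles", class(profiles))
  profiles
}

#' Kinetic regulation modes
#'
#' The four kinetic classes of a treatment:LPS expression profile:
#' early down-regulation followed by up-regulation, early non-response
#' followed by up-regulation, delayed down-regulation followed by
#' up-regulation, and a residual class.
#'
#' @return Character vector of the four mode labels, in precedence order.
#' @export
regulation_modes <- function() {
  c("EARLY_DOWN_THEN_UP", "DELAYED_DOWN_THEN_UP",
    "EARLY_NONE_THEN_UP", "OTHER")
}

# direction call at one time point: -1 down, +1 up, 0 none
call_direction <- function(log2_ratio, theta) {
  ifelse(log2_ratio <= -theta, -1L, ifelse(log2_ratio >= theta, 1L, 0L))
}

#' Classify time profiles into kinetic regulation modes
#'
#' A gene's direction at a time point is *down* when its log2 treatment:LPS
#' ratio is at or below `-theta`, *up* at or above `+theta`, and *none*
#' otherwise. Modes are assigned by precedence at three anchor times:
#' early down followed by up at the up-anchor; otherwise delayed down (not
#' down early, down at the delayed anchor, up later); otherwise early
#' non-response followed by up; every remaining profile is `OTHER`.
#'
#' @param profiles Profiles from [build_profiles()], containing the three
#'   anchor times for every gene.
#' @param theta Response threshold on the log2 scale (> 0). Default
#'   `log2(1.5)`, i.e. a 1.5-fold excursion.
#' @param early_t,delayed_t,up_t Anchor times in hours (defaults 0.5, 2, 4).
#' @return A tibble (`gene_symbol`, `treatment`, `mode`) with exactly one
#'   mode per gene and treatment.
#' @export
classify_modes <- function(profiles, theta = log2(1.5),
                           early_t = 0.5, delayed_t = 2, up_t = 4) {
  if (!is.numeric(theta) || theta <= 0) abort("theta must be positive")
  anchors <- c(early = early_t, delayed = delayed_t, up = up_t)
  anchor_tbl <- profiles %>%
    filter(.data$time_h %in% anchors) %>%
    mutate(anchor = names(anchors)[match(.data$time_h, anchors)]) %>%
    select("gene_symbol", "treatment", "anchor", "log2_ratio") %>%
    tidyr::pivot_wider(names_from = "anchor", values_from = "log2_ratio")
  for (a in names(anchors)) {
    if (!a %in% names(anchor_tbl) || anyNA(anchor_tbl[[a]])) {
      bad <- if (a %in% names(anchor_tbl)) {
        anchor_tbl$gene_symbol[is.na(anchor_tbl[[a]])]
      } else unique(anchor_tbl$gene_symbol)
      abort(paste0("missing anchor time (", anchors[[a]], " h) for gene(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  d_early <- call_direction(anchor_tbl$early, theta)
  d_delayed <- call_direction(anchor_tbl$delayed, theta)
  d_up <- call_direction(anchor_tbl$up, theta)
  mode <- case_when(
    d_early == -1L & d_up == 1L ~ "EARLY_DOWN_THEN_UP",
    d_early != -1L & d_delayed == -1L & d_up == 1L ~ "DELAYED_DOWN_THEN_UP",
    d_early == 0L & d_up == 1L ~ "EARLY_NONE_THEN_UP",
    TRUE ~ "OTHER"
  )
  tibble(gene_symbol = anchor_tbl$gene_symbol,
         treatment = anchor_tbl$treatment,
         mode = factor(mode, levels = regulation_modes()))
}

#' Classify the LPS-only baseline direction of each gene
#'
#' Genes are tagged *up* or *down* from their LPS-vs-vehicle profile: by the
#' first time point when its log2 ratio clears the threshold, otherwise by
#' the sign of the largest-magnitude excursion anywhere in the profile
#' (ties, including an all-zero profile, resolve to *up*).
#'
#' @param lps_profiles Profiles (from [build_profiles()]) of the LPS-only
#'   treatment referenced against vehicle.
#' @inheritParams classify_modes
#' @return A tibble (`gene_symbol`, `baseline`) with `baseline` in
#'   `c("up", "down")`.
#' @export
classify_baseline <- function(lps_profiles, theta = log2(1.5)) {
  if (nrow(lps_profiles) == 0) abort("empty profile set")
  lps_profiles %>%
    group_by(.data$gene_symbol) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(baseline = {
      x <- .data$log2_ratio
      f <- x[1]
      if (f >= theta) "up"
      else if (f <= -theta) "down"
      else if (x[which.max(abs(x))] < 0) "down" else "up"
    }, .groups = "drop")
}

#' Mode concordance between two treatments
#'
#' For the genes a reference treatment places in a given regulation mode,
#' the concordance of another treatment is the percentage of those genes
#' that the other treatment places in the same mode. Percentages are
#' rounded half-up to one decimal (17/23 prints as 73.9).
#'
#' @param modes_ref,modes_other Mode assignments (tibbles with
#'   `gene_symbol` and `mode`, as from [classify_modes()]) for the
#'   reference and comparison treatment.
#' @param group The regulation mode defining the reference gene group.
#' @return A one-row tibble: `mode_group`, `n_group`, `n_same`,
#'   `percent_same` (NA, with a warning, when the group is empty).
#' @export
concordance <- function(modes_ref, modes_other, group) {
  group <- match.arg(as.character(group), regulation_modes())
  ref_genes <- modes_ref$gene_symbol[modes_ref$mode == group]
  missing <- setdiff(ref_genes, modes_other$gene_symbol)
  if (length(missing) > 0) {
    abort(paste0("comparison treatment lacks mode calls for: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n_group <- length(ref_genes)
  other_mode <- modes_other$mode[match(ref_genes, modes_other$gene_symbol)]
  n_same <- sum(other_mode == group)
  if (n_group == 0) {
    warn(paste0("empty reference group ", group, "; percent undefined"))
    pct <- NA_real_
  } else {
    pct <- round_half_up(100 * n_same / n_group, 1)
  }
  tibble(mode_group = group, n_group = n_group, n_same = n_same,
         percent_same = pct)
}

#' All-mode, all-treatment concordance table
#'
#' @param modes Mode assignments for several treatments (columns
#'   `gene_symbol`, `treatment`, `mode`).
#' @param reference Treatment whose mode grouping defines the gene groups.
#' @param groups Modes to tabulate (default: all except `OTHER`).
#' @return A tibble with one row per (other treatment, mode group).
#' @export
concordance_table <- function(modes, reference,
                              groups = setdiff(regulation_modes(), "OTHER")) {
  if (!reference %in% modes$treatment) {
    abort(paste0("reference treatment '", reference, "' not present"))
  }
  modes_ref <- filter(modes, .data$treatment == reference)
  others <- setdiff(unique(modes$treatment), reference)
  purrr::map_dfr(others, function(tr) {
    modes_other <- filter(modes, .data$treatment == tr)
    purrr::map_dfr(groups, function(g) {
      mutate(concordance(modes_ref, modes_other, g),
             reference_treatment = reference, other_treatment = tr,
             .before = 1)
    })
  })
}
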