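make_spots <- function(fg_c, bg_c, fg_t, bg_t, flag = "ok") {
  n <- length(fg_c)
  tibble::tibble(
    hybridization_id = "H1",
    probe_id = sprintf("p%d", seq_len(n)),
    gene_symbol = sprintf("g%d", seq_len(n)),
    replicate = 1L,
    ch_control_fg = fg_c, ch_control_bg = bg_c,
    ch_test_fg = fg_t, ch_test_bg = bg_t,
    flag = flag)
}

test_that("background correction subtracts and floors each channel", {
  s <- make_spots(c(500, 50), c(100, 100), c(300, 10), c(50, 40))
  out <- background_correct(s)
  expect_equal(out$control_intensity, c(400, 1))
  expect_equal(out$test_intensity, c(250, 1))

  set.seed(41)
  fg <- runif(1000, 0, 1e4); bg <- runif(1000, 0, 5e3)
  fg2 <- runif(1000, 0, 1e4); bg2 <- runif(1000, 0, 5e3)
  out <- background_correct(make_spots(fg, bg, fg2, bg2))
  expect_equal(out$control_intensity, pmax(fg - bg, 1))
  expect_equal(out$test_intensity, pmax(fg2 - bg2, 1))
})

test_that("invalid intensities are rejected with the probe named", {
  s <- make_spots(c(500, -3), c(100, 10), c(300, 10), c(50, 5))
  expect_error(background_correct(s), "control.*p2")
  expect_error(validate_spot_table(
    make_spots(c(500, NaN), c(100, 10), c(300, 10), c(50, 5))), "p2")
})

test_that("replicate aggregation uses the median by default", {
  expect_equal(aggregate_replicates(c(1, 1, 1, 1)), 1)
  expect_equal(aggregate_replicates(c(0.30, 0.32, 0.34, 0.40)), 0.33)
  expect_equal(aggregate_replicates(2.0), 2.0)
  expect_equal(aggregate_replicates(c(1, 2, 3, 10), method = "mean"), 4)
  expect_true(is.na(aggregate_replicates(numeric(0))))
})

test_that("flagged spots are excluded and fully flagged genes go missing", {
  s <- dplyr::bind_rows(
    make_spots(rep(200, 4), rep(0, 4), c(400, 420, 380, 4000), rep(0, 4)),
    make_spots(rep(200, 2), rep(0, 2), rep(1000, 2), rep(0, 2), flag = "bad"))
  s$gene_symbol <- rep(c("gA", "gB"), c(4, 2))
  s$replicate <- c(1:4, 1:2)
  s$probe_id <- paste0(s$gene_symbol, "_", s$replicate)
  s$flag[4] <- "bad"  # the outlier replicate of gA
  manifest <- tibble::tibble(hybridization_id = "H1", treatment = "LPS",
                             time_h = 0.5, test_label = "LPS",
                             control_label = "vehicle")
  expect_message(r <- process_experiment(s, manifest), "missing")
  expect_equal(nrow(r), 1)
  expect_equal(r$ratio, 2.0)  # median of 400,420,380 over 200
})

test_that("normalization makes the reference row exactly 1 and is idempotent", {
  set.seed(11)
  grid <- tidyr::expand_grid(
    gene_symbol = c("REF", sprintf("g%02d", 1:19)),
    treatment = c("a", "b", "c"), time_h = c(0.5, 2))
  ratios <- dplyr::mutate(grid, ratio = runif(dplyr::n(), 0.2, 5))
  norm <- normalize_to_reference(ratios, "REF")
  ref_rows <- norm$ratio[norm$gene_symbol == "REF"]
  expect_identical(ref_rows, rep(1, 6))

  # direct recomputation oracle
  for (i in sample(nrow(norm), 20)) {
    r0 <- ratios$ratio[i]
    ref <- ratios$ratio[ratios$gene_symbol == "REF" &
                          ratios$treatment == norm$treatment[i] &
                          ratios$time_h == norm$time_h[i]]
    expect_equal(norm$ratio[i], r0 / ref)
  }
  twice <- normalize_to_reference(norm, "REF")
  expect_equal(twice$ratio, norm$ratio)
})

test_that("a missing or non-positive reference names the offending conditions", {
  ratios <- tidyr::expand_grid(gene_symbol = c("REF", "g1"),
                               treatment = "a", time_h = c(0.5, 2)) |>
    dplyr::mutate(ratio = c(1, 0, 2, 2))  # REF zero at 2 h
  expect_error(normalize_to_reference(ratios, "REF"), "a@2")
  expect_error(normalize_to_reference(ratios, "nope"), "nope")
})

test_that("housekeeping flag is enforced when a design is supplied", {
  design <- tibble::tibble(gene_symbol = c("REF", "g1"),
                           gene_id = 1:2,
                           category = c("housekeeping", "other"),
                           is_housekeeping = c(TRUE, FALSE))
  ratios <- tibble::tibble(gene_symbol = c("REF", "g1"), treatment = "a",
                           time_h = 0.5, ratio = c(2, 4))
  norm <- normalize_to_reference(ratios, "REF", design)
  expect_equal(norm$ratio, c(1, 2))
  expect_error(normalize_to_reference(ratios, "g1", design),
               "not housekeeping")
})

test_that("ratio of ratios forms the treatment:LPS ratio", {
  expect_equal(ratio_of_ratios(0.5, 1.0), 0.5)
  expect_equal(ratio_of_ratios(0.96, 3.0), 0.32)
  x <- runif(50, 0.01, 10)
  expect_equal(ratio_of_ratios(x, x), rep(1, 50))
  expect_error(ratio_of_ratios(-1, 2), "positive")

  vehicle_ref <- tidyr::expand_grid(gene_symbol = c("g1", "g2"),
                                    treatment = c("LPS", "emodin"),
                                    time_h = c(0.5, 4)) |>
    dplyr::mutate(ratio = c(2, 2, 1, 3, 4, 1, 2, 6))
  out <- treatment_vs_lps(vehicle_ref)
  expect_setequal(unique(out$treatment), "emodin")
  direct <- vehicle_ref |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "ratio")
  expect_equal(
    out$ratio[match(paste(direct$gene_symbol, direct$time_h),
                    paste(out$gene_symbol, out$time_h))],
    direct$emodin / direct$LPS)
})

test_that("fold filter applies inclusive thresholds in both directions", {
  tbl <- tibble::tibble(gene_symbol = c("at3", "at1", "athird", "near"),
                        gene_id = 1:4,
                        category = rep("other", 4),
                        trt = c(3.0, 1.0, 1 / 3, 2.99))
  hits <- filter_fold_change(tbl, "trt")
  expect_setequal(hits$gene_symbol, c("at3", "athird"))
  expect_equal(hits$direction[hits$gene_symbol == "at3"], "up")
  expect_equal(hits$direction[hits$gene_symbol == "athird"], "down")
  expect_error(filter_fold_change(tbl, character(0)), "at least one")
  expect_error(filter_fold_change(tbl, "trt", threshold = 1), "greater than 1")
})

test_that("published hit rows are retained with the printed direction", {
  t1 <- phyto_fixture("table1")
  h <- filter_fold_change(t1, c("shikonin", "emodin"), direction = "down")
  expect_true("NFATC3" %in% h$gene_symbol)
  expect_equal(t1$emodin[t1$gene_symbol == "NFATC3"], 0.06)

  t2 <- phyto_fixture("table2")
  h2 <- filter_fold_change(t2, c("cytopiloyne", "BF"), direction = "up")
  expect_true("MAP2K4" %in% h2$gene_symbol)
  expect_equal(t2$BF[t2$gene_symbol == "MAP2K4"], 3.56)
  expect_equal(h2$direction[h2$gene_symbol == "MAP2K4"], "up")
})

test_that("fold filter matches a brute-force scan on random matrices", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    k <- sample(2:4, 1)
    treatments <- paste0("t", seq_len(k))
    tbl <- tibble::as_tibble(setNames(
      as.data.frame(matrix(2^runif(n * k, -3, 3), n, k)), treatments))
    tbl$gene_symbol <- sprintf("g%02d", seq_len(n))
    rule <- sample(c("any", "all"), 1)
    direction <- sample(c("both", "up", "down"), 1)
    got <- filter_fold_change(tbl, treatments, 3, rule, direction)
    want <- brute_filter(tbl, treatments, 3, rule, direction)
    expect_setequal(got$gene_symbol, want)
  }
})

test_that("hit tables are sorted by category then gene id", {
  tbl <- tibble::tibble(
    gene_symbol = c("z", "a", "m"),
    gene_id = c(10L, 99L, 5L),
    category = c("other", "cytokines", "cytokines"),
    trt = c(4, 5, 6))
  h <- filter_fold_change(tbl, "trt")
  expect_equal(h$gene_symbol, c("m", "a", "z"))
})

test_that("ratio matrix TSV round-trips through treatment@time columns", {
  ratios <- tidyr::expand_grid(gene_symbol = c("g1", "g2"),
                               treatment = c("emodin", "shikonin"),
                               time_h = c(0.5, 12)) |>
    dplyr::mutate(ratio = seq(0.1, 0.8, 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_matrix(ratios, path)
  back <- read_ratio_matrix(path)
  expect_equal(dplyr::arrange(back, gene_symbol, treatment, time_h),
               dplyr::arrange(ratios, gene_symbol, treatment, time_h))
})
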