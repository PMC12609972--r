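make_scan <- function(fg1, bg1, fg2, bg2, flag = "OK",
                      dye_orientation = "standard") {
  n <- length(fg1)
  tibble(
    array_id = "array01", dye_orientation = dye_orientation,
    spot_id = sprintf("S%02d", seq_len(n)),
    gene = sprintf("G%02d", seq_len(n)),
    fg1 = fg1, bg1 = bg1, fg2 = fg2, bg2 = bg2,
    flag = rep_len(flag, n)
  )
}

test_that("background correction subtracts per channel and flags nonpositives", {
  scan <- make_scan(fg1 = c(100, 30), bg1 = c(40, 10),
                    fg2 = c(80, 30), bg2 = c(20, 50))
  out <- correct_background(scan)
  expect_equal(out$s1, c(60, 20))
  expect_equal(out$s2[1], 60)
  expect_equal(out$flag, c("OK", "BAD"))
  expect_equal(out$reason, c(NA, "nonpositive"))

  nobg <- correct_background(make_scan(fg1 = 10, bg1 = 0, fg2 = 20, bg2 = 0))
  expect_equal(nobg$s1, 10)
  expect_equal(nobg$flag, "OK")
})

test_that("spot filtering removes flagged and low-SNR spots with counts", {
  scan <- make_scan(fg1 = rep(1000, 10), bg1 = rep(10, 10),
                    fg2 = rep(1000, 10), bg2 = rep(10, 10))
  scan$flag[3] <- "BAD"
  out <- filter_spots(correct_background(scan))
  expect_equal(nrow(out), 9)
  rep_info <- attr(out, "filter_report")
  expect_equal(rep_info$by_reason$n[rep_info$by_reason$reason == "flagged"], 1L)

  # SNR straddling the 1.5 threshold: retained set equals brute-force reselection
  set.seed(1)
  fg <- runif(50, 50, 300)
  bg <- runif(50, 40, 160)
  scan2 <- make_scan(fg1 = fg, bg1 = bg, fg2 = rev(fg), bg2 = rev(bg))
  corrected <- correct_background(scan2)
  kept <- filter_spots(corrected, min_snr = 1.5)
  snr <- pmin(fg / pmax(bg, 1), rev(fg) / pmax(rev(bg), 1))
  ok <- corrected$flag == "OK" & snr >= 1.5
  expect_setequal(kept$spot_id, corrected$spot_id[ok])
})

test_that("MA coordinates follow the log-ratio arithmetic", {
  scan <- correct_background(make_scan(
    fg1 = c(100, 100, 200), bg1 = c(0, 0, 0),
    fg2 = c(100, 400, 50), bg2 = c(0, 0, 0)
  ))
  r <- compute_ratios(scan)
  expect_equal(r$M, c(0, 2, -2))
  expect_equal(r$A[3], (log2(200) + log2(50)) / 2)
})

test_that("dye-swap arrays yield the treated-minus-control orientation", {
  cfg_std <- quiet_config(prop_de = 0.3, seed = 21)
  sim <- simulate_experiment(cfg_std)
  scan <- sim$scans
  # physically swap channels and mark the orientation: M must be unchanged
  swapped <- scan %>%
    mutate(tmp1 = fg1, tmpb1 = bg1, fg1 = fg2, bg1 = bg2,
           fg2 = tmp1, bg2 = tmpb1, dye_orientation = "swapped") %>%
    select(-tmp1, -tmpb1)
  m_std <- compute_ratios(filter_spots(correct_background(scan)))
  m_swp <- compute_ratios(filter_spots(correct_background(swapped)))
  expect_equal(m_swp$M, m_std$M, tolerance = 1e-12)
})

test_that("LOWESS normalization removes a constant offset and keeps zero at zero", {
  set.seed(2)
  rec <- tibble(
    array_id = "a1", spot_id = sprintf("S%03d", 1:200),
    gene = sprintf("G%03d", 1:200),
    A = runif(200, 6, 14), M = 0
  )
  out <- lowess_normalize(rec)
  expect_equal(out$M, rep(0, 200))

  rec$M <- 0.8
  out2 <- lowess_normalize(rec)
  expect_true(max(abs(out2$M)) < 1e-6)

  rec$A <- 7
  expect_error(lowess_normalize(rec), "constant")
})

test_that("LOWESS recovers a planted cubic dye bias away from the A extremes", {
  cfg <- sim_config(n_genes = 2000, n_arrays = 1, background_level = 0,
                    noise_sd_at_low_A = 1e-9, noise_sd_at_high_A = 1e-9, seed = 3)
  sim <- simulate_experiment(cfg)
  norm <- lowess_normalize(compute_ratios(filter_spots(correct_background(sim$scans))))
  merged <- inner_join(norm, sim$truth, by = "gene")
  qr <- quantile(merged$A, c(0.02, 0.98))
  inner <- filter(merged, A >= qr[1], A <= qr[2])
  expect_lt(max(abs(inner$M - inner$true_log2fc)), 0.05)
})

test_that("few-record normalization falls back to median-centering with warning", {
  rec <- tibble(array_id = "a1", spot_id = sprintf("S%02d", 1:10),
                gene = sprintf("G%02d", 1:10),
                A = seq(6, 14, length.out = 10), M = rnorm(10) + 3)
  expect_warning(out <- lowess_normalize(rec), "median-centering")
  expect_equal(median(out$M), 0)
})

test_that("replicate averaging is the two-stage mean", {
  rec <- tibble(
    array_id = c("a1", "a1", "a2"),
    spot_id = c("S1", "S2", "S1"),
    gene = "G1",
    A = c(10, 10, 10),
    M = c(1, 3, 2)
  )
  out <- average_replicates(rec)
  expect_equal(out$R, mean(c(mean(c(1, 3)), 2)))
  expect_equal(out$n_spots, 3L)
  expect_equal(out$n_arrays, 2L)

  one <- average_replicates(rec[rec$array_id == "a1", ])
  expect_equal(one$R, 2)

  # random instance against a brute-force two-stage mean
  set.seed(4)
  big <- tibble(
    array_id = sample(c("a1", "a2", "a3"), 300, replace = TRUE),
    spot_id = sprintf("S%03d", 1:300),
    gene = sample(sprintf("G%02d", 1:40), 300, replace = TRUE),
    A = runif(300, 6, 14), M = rnorm(300)
  )
  out2 <- average_replicates(big)
  brute <- big %>%
    group_by(gene, array_id) %>% summarise(M = mean(M), .groups = "drop") %>%
    group_by(gene) %>% summarise(R = mean(M), .groups = "drop")
  joined <- inner_join(out2, brute, by = "gene")
  expect_equal(joined$R.x, joined$R.y)

  # min_arrays drops genes observed in too few arrays
  out3 <- average_replicates(big, min_arrays = 3)
  counts <- big %>% distinct(gene, array_id) %>% count(gene)
  expect_setequal(out3$gene, counts$gene[counts$n >= 3])
})

test_that("spot-order shuffling changes no numeric output", {
  cfg <- sim_config(n_genes = 100, n_arrays = 2, seed = 15)
  sim <- simulate_experiment(cfg)
  g1 <- preprocess_experiment(sim$scans)
  set.seed(1)
  shuffled <- sim$scans[sample(nrow(sim$scans)), ]
  g2 <- preprocess_experiment(shuffled)
  j <- inner_join(g1, g2, by = "gene", suffix = c("_a", "_b"))
  expect_equal(j$R_a, j$R_b, tolerance = 1e-12)
})

test_that("QC report computes correlations and verdicts", {
  cfg <- sim_config(n_genes = 500, n_arrays = 2, seed = 8)
  sim <- simulate_experiment(cfg)
  gl <- preprocess_experiment(sim$scans)
  spots <- attr(gl, "spot_records")
  qc <- qc_report(spots, attr(gl, "filter_reports"))
  expect_true(all(qc$correlations$r >= -1 & qc$correlations$r <= 1))
  expect_true(all(qc$pass_fraction$pass_fraction >= 0 &
                    qc$pass_fraction$pass_fraction <= 1))

  # identical duplicate arrays: r = 1 exactly
  dup <- spots %>% mutate(array_id = "arrayX") %>% bind_rows(spots) %>%
    filter(array_id %in% c("array01", "arrayX"))
  dup2 <- bind_rows(
    spots %>% filter(array_id == "array01"),
    spots %>% filter(array_id == "array01") %>% mutate(array_id = "arrayX")
  )
  qc2 <- qc_report(dup2)
  expect_equal(qc2$correlations$r, 1)

  # independent random arrays: |r| small, verdict fail
  set.seed(9)
  rnd <- tibble(
    array_id = rep(c("a1", "a2"), each = 1000),
    spot_id = c(sprintf("S%04d", 1:1000), sprintf("S%04d", 1:1000)),
    gene = rep(sprintf("G%04d", 1:1000), 2),
    A = runif(2000, 6, 14), M = rnorm(2000)
  )
  qc3 <- qc_report(rnd)
  expect_lt(abs(qc3$correlations$r), 0.15)
  expect_false(qc3$verdicts[["replicate_consistency"]])

  # single array: correlations not applicable, not an error
  qc4 <- qc_report(spots %>% filter(array_id == "array01"))
  expect_null(qc4$correlations)
})
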