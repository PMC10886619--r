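test_that("noise-free dilution series are exact powers of ten", {
  s <- simulate_dilution_series(1e9, 0, 8)
  expect_equal(unname(s), 1e9 * 10^-(0:7))
  expect_equal(names(s), as.character(0:7))
  expect_equal(unname(s["6"]), 1e3)  # 5 expected PFU in a 5 uL drop
  expect_error(simulate_dilution_series(0, 0.05, 8), "positive")
})

test_that("pipetting error is multiplicative with median one", {
  set.seed(101)
  r <- replicate(10000, simulate_dilution_series(1e8, 0.05, 2)[["1"]]) / 1e7
  expect_equal(median(r), 1, tolerance = 0.01)
  expect_equal(sd(r), 0.05, tolerance = 0.1)
})

test_that("spot counts are Poisson in the dispensed volume", {
  set.seed(55)
  # expected count 20: concentration 4e3 PFU/mL in a 5 uL drop
  counts <- vapply(1:30000, function(i)
    simulate_spot(4e3, drop_volume_cv = 0, p_no_drop = 0)$plaque_count,
    1L)
  expect_equal(mean(counts), 20, tolerance = 0.005)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
  expect_true(all(counts <= 50))

  set.seed(56)
  z <- simulate_spot(0, p_no_drop = 0)
  expect_equal(z$status, "no_lysis")
  hot <- simulate_spot(4e9, p_no_drop = 0)  # expected count 2e7
  expect_equal(hot$status, "confluent")
  expect_true(is.na(hot$plaque_count))
})

test_that("coalescence merges at most one adjacent pair and conserves plaques", {
  tri <- spot_rows(3, rep("counted", 3), counts = c(10, 12, 7))
  expect_identical(apply_coalescence(tri, 0), tri)

  set.seed(2)
  m <- apply_coalescence(tri, 1)
  expect_equal(m$status, c("merged", "merged", "counted"))
  expect_equal(m$plaque_count, c(22, 22, 7))
  expect_equal(m$merge_partner, c(2, 1, NA))
  # halving the blob across partners conserves the triplicate total
  expect_equal(sum(resolve_anomalies(m)$counts), 10 + 12 + 7)
})

test_that("assay tables are factorial, deterministic and seed-sensitive", {
  set.seed(77)
  pan <- example_susceptibility(5, 3, 6)
  cfg <- simulation_config(pan$susceptibility, pan$strain_ids, pan$phage_ids,
                           seed = 41)
  a <- simulate_assay(cfg)
  expect_equal(nrow(a$spots), 5 * 3 * 8 * 3)
  key <- unique(a$spots[c("phage_id", "strain_id", "dilution_exponent")])
  expect_equal(nrow(key), 5 * 3 * 8)
  expect_identical(a$spots, simulate_assay(cfg)$spots)

  b <- simulate_assay(cfg, seed = 42)
  expect_false(identical(a$spots, b$spots))
  expect_identical(dim(a$spots), dim(b$spots))
  expect_identical(a$spots[c("phage_id", "strain_id", "dilution_exponent",
                             "replicate")],
                   b$spots[c("phage_id", "strain_id", "dilution_exponent",
                             "replicate")])
})

test_that("an empty susceptibility panel yields no plaques anywhere", {
  cfg <- simulation_config(strain_ids = sprintf("s%d", 1:8),
                           phage_ids = c("p1", "p2"), seed = 13)
  a <- simulate_assay(cfg)
  expect_true(all(a$spots$status %in% c("no_lysis", "no_drop", "merged")))
  merged <- a$spots$plaque_count[a$spots$status == "merged"]
  expect_true(all(merged == 0))
  expect_true(all(a$truth$concentrations$concentration == 0))
})

test_that("coalescence never crosses phage or dilution boundaries", {
  set.seed(5)
  pan <- example_susceptibility(12, 4, 10)
  cfg <- simulation_config(pan$susceptibility, pan$strain_ids, pan$phage_ids,
                           p_coalescence = 0.3, seed = 8)
  sp <- simulate_assay(cfg)$spots
  m <- sp[sp$status == "merged", ]
  expect_gt(nrow(m), 0)
  for (i in seq_len(nrow(m))) {
    p <- m[i, ]
    partner <- sp[sp$phage_id == p$phage_id & sp$strain_id == p$strain_id &
                    sp$dilution_exponent == p$dilution_exponent &
                    sp$replicate == p$merge_partner, ]
    expect_equal(nrow(partner), 1)
    expect_equal(partner$status, "merged")
    expect_equal(partner$merge_partner, p$replicate)
    expect_equal(partner$plaque_count, p$plaque_count)
    expect_equal(abs(partner$replicate - p$replicate), 1)
  }
})

test_that("run-plan arithmetic matches the instrument geometry", {
  p <- plan_run(10, 4)
  expect_equal(p$spots_per_plate, 96)
  expect_equal(p$spots_per_run, 960)
  expect_equal(p$aspiration_volume_per_tip_ul, 3 * 5 * 10 + 10)

  q <- plan_run(126, 11)
  expect_equal(q$plates_per_strain, 3)
  expect_equal(q$total_plates, 378)
  expect_equal(q$total_runs, 38)
  expect_equal(q$total_spots, 33264)

  tiny <- plan_run(1, 1)
  expect_equal(tiny$total_spots, 24)
  expect_equal(tiny$total_plates, 1)
  expect_equal(tiny$total_runs, 1)
  expect_equal(tiny$aspiration_volume_per_tip_ul, 3 * 5 * 1 + 10)
  expect_error(plan_run(0, 4), "positive")
})

test_that("anomaly rates are counted correctly on hand-built tables", {
  clean <- do.call(rbind, lapply(1:10, function(i)
    spot_rows(2, rep("counted", 3), counts = c(9, 11, 10), strain = paste0("s", i))))
  r <- estimate_anomaly_rates(clean)
  expect_equal(r$no_drop$rate, 0)
  expect_equal(r$coalescence$rate, 0)
  expect_equal(r$coalescence$opportunities, 20)
  expect_equal(r$merged_spot_fraction, 0)

  # 100 spots with 2 missed drops and one merged pair
  tab <- do.call(rbind, lapply(1:33, function(i)
    spot_rows(2, rep("counted", 3), counts = 10, strain = paste0("s", i))))
  tab <- rbind(tab, spot_rows(2, "counted", counts = 10, strain = "s34")[1, ])
  tab$status[1:2] <- "no_drop"; tab$plaque_count[1:2] <- NA
  tab$status[4:5] <- "merged"; tab$plaque_count[4:5] <- 21
  tab$merge_partner[4:5] <- c(2, 1)
  r2 <- estimate_anomaly_rates(tab)
  expect_equal(r2$no_drop$count, 2)
  expect_equal(r2$no_drop$rate, 2 / 100)
  expect_equal(r2$coalescence$events, 1)
  expect_equal(r2$merged_spot_fraction, 2 / 100)
})

test_that("titration recovers simulated ground truth without noise", {
  cfg <- simulation_config(
    data.frame(phage_id = "p1", strain_id = sprintf("s%02d", 1:40),
               stock_titer = 1e9),
    strain_ids = sprintf("s%02d", 1:40), phage_ids = "p1",
    pipetting_cv = 0, drop_volume_cv = 0, p_no_drop = 0, p_coalescence = 0,
    seed = 31)
  a <- simulate_assay(cfg)
  tt <- titrate_panel(a$spots)
  q <- tt[tt$status == "quantified", ]
  expect_gt(nrow(q), 35)
  err <- log10(q$mean_titer / 1e9)
  # triplicate counts of at least 5 per spot: 4 sigma ~ factor 2
  expect_true(all(abs(err) < log10(2.5)))
  expect_equal(mean(10^err), 1, tolerance = 0.1)
})
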