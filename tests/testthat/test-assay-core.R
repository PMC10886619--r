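test_that("titer arithmetic converts counts, volumes and dilutions", {
  expect_equal(titer_from_count(5, 5, 6), 1e9)
  expect_equal(titer_from_count(0, 5, 0), 0)
  expect_equal(titer_from_count(11, 5, 2), 2.2e5)
  # linear in the count, and one ten-fold step multiplies by 10
  expect_equal(titer_from_count(3 * 7, 5, 2), 3 * titer_from_count(7, 5, 2))
  for (case in list(c(3, 4, 0), c(17, 10, 5), c(50, 5, 7))) {
    expect_equal(titer_from_count(case[1], case[2], case[3]),
                 titer_from_count(case[1], case[2], 0) * 10^case[3])
  }
  expect_error(titer_from_count(5, 0, 1), "volume")
  expect_error(titer_from_count(-1, 5, 1), "non-negative")
})

test_that("replicate aggregation uses the sample SD and matches hand cases", {
  a <- aggregate_replicates(c(1, 2, 3))
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$cv_percent, 50)
  expect_equal(aggregate_replicates(c(4, 4, 4))$cv_percent, 0)
  # tube C of the packaged validation fixture, reference method
  ct <- aggregate_replicates(c(7.33e6, 1.40e7, 1.07e7, 1.00e7))
  expect_equal(ct$mean, 1.05e7, tolerance = 0.005)
  expect_equal(ct$sd, 2.74e6, tolerance = 0.005)
  expect_equal(round(ct$cv_percent, 2), 26.11)
  expect_error(aggregate_replicates(5e6), "two replicate")
  expect_error(aggregate_replicates(c(0, 1e6)), "positive")
})

test_that("aggregation is scale-equivariant and the CV scale-free", {
  set.seed(42)
  for (i in 1:25) {
    x <- 10^runif(sample(2:6, 1), 3, 9)
    k <- 10^runif(1, -3, 3)
    a <- aggregate_replicates(x)
    b <- aggregate_replicates(k * x)
    expect_equal(b$mean, k * a$mean)
    expect_equal(b$sd, k * a$sd)
    expect_equal(b$cv_percent, a$cv_percent)
  }
})

test_that("anomaly resolution halves merged blobs and drops missed spots", {
  clean <- spot_rows(3, rep("counted", 3), counts = c(10, 12, 11))
  r <- resolve_anomalies(clean)
  expect_equal(unname(r$counts), c(10, 12, 11))
  expect_length(r$flags, 0)

  m <- resolve_anomalies(merged_triplicate(24, 13))
  expect_equal(unname(m$counts), c(12, 12, 13))
  expect_true("merged_resolved" %in% m$flags)
  # the blob's combined count is conserved across the two partners
  expect_equal(sum(m$counts), 24 + 13)

  d <- resolve_anomalies(spot_rows(3, c("counted", "no_drop", "counted"),
                                   counts = c(10, NA, 14)))
  expect_equal(unname(d$counts), c(10, 14))
  expect_true("missing_replicate" %in% d$flags)

  asym <- spot_rows(3, c("merged", "counted", "counted"),
                    counts = c(24, 9, 13), partners = c(2, NA, NA))
  expect_error(resolve_anomalies(asym), "symmetric")
})

test_that("merged blobs with fractional halves stay unrounded", {
  m <- resolve_anomalies(merged_triplicate(23, 13))
  expect_equal(unname(m$counts), c(11.5, 11.5, 13))
  expect_equal(sum(m$counts), 23 + 13)
})

test_that("dilution selection picks the countable dilution with most counts", {
  s <- series_spots(list(`0` = "confluent", `1` = "confluent",
                         `2` = c(30, 28, 33), `3` = c(3, 4, 3),
                         `4` = 0, `5` = 0, `6` = 0, `7` = 0))
  sel <- select_quantifiable_dilution(s)
  expect_equal(sel$status, "quantified")
  expect_equal(sel$dilution_exponent, 2L)

  all_clear <- series_spots(setNames(rep(list(0), 8), 0:7))
  expect_equal(select_quantifiable_dilution(all_clear)$status, "no_activity")

  # lawn clearance at low dilutions without individual plaques above
  low <- series_spots(c(list(`0` = "confluent", `1` = "confluent"),
                        setNames(rep(list(0), 6), 2:7)))
  expect_equal(select_quantifiable_dilution(low)$status, "excluded_no_pfu")

  # still beyond the countable ceiling at the highest tested dilution
  hot <- series_spots(c(setNames(rep(list("confluent"), 7), 0:6),
                        list(`7` = c(60, 58, 64))))
  expect_equal(select_quantifiable_dilution(hot)$status,
               "excluded_unreliable_count")
  hot2 <- series_spots(setNames(rep(list("confluent"), 8), 0:7))
  expect_equal(select_quantifiable_dilution(hot2)$status,
               "excluded_unreliable_count")
  expect_error(select_quantifiable_dilution(s[0, ]), "non-empty")
})

test_that("a clearance-only series is never titrated under any rules", {
  low <- series_spots(c(list(`0` = "confluent", `1` = "confluent"),
                        setNames(rep(list(0), 6), 2:7)))
  for (mc in c(1, 2, 5)) {
    for (top in c(30, 50, 100)) {
      t <- titrate(low, quantification_rules(min_countable = mc,
                                             max_countable = top))
      expect_equal(t$status, "excluded_no_pfu")
      expect_true(is.na(t$mean_titer))
      expect_equal(t$n_replicates_used, 0L)
    }
  }
})

test_that("titrate composes selection, resolution and aggregation", {
  s <- series_spots(list(`0` = "confluent", `1` = "confluent", `2` = "confluent",
                         `3` = c(10, 12, 11), `4` = c(1, 1, 1),
                         `5` = 0, `6` = 0, `7` = 0))
  t <- titrate(s)
  expect_equal(t$status, "quantified")
  expect_equal(t$selected_dilution_exponent, 3L)
  expect_equal(sort(t$replicate_titers), c(2.0e6, 2.2e6, 2.4e6))
  expect_equal(t$mean_titer, 2.2e6)
  expect_equal(t$sd_titer, 2.0e5)
  expect_equal(t$cv_percent, 100 * 2e5 / 2.2e6)
  expect_true(t$precision_acceptable)

  # one missed drop: two replicates used, flagged
  s2 <- rbind(series_spots(list(`2` = "confluent")),
              spot_rows(3, c("counted", "no_drop", "counted"),
                        counts = c(10, NA, 14)),
              series_spots(setNames(rep(list(0), 4), 4:7)))
  t2 <- titrate(s2)
  expect_equal(t2$status, "quantified")
  expect_equal(t2$n_replicates_used, 2L)
  expect_true("missing_replicate" %in% t2$anomaly_flags)

  # a merged pair flows through to the titer with conserved plaques
  s3 <- rbind(series_spots(list(`2` = "confluent")),
              merged_triplicate(24, 13, exponent = 3),
              series_spots(setNames(rep(list(0), 4), 4:7)))
  t3 <- titrate(s3)
  expect_true("merged_resolved" %in% t3$anomaly_flags)
  expect_equal(sum(t3$replicate_titers), titer_from_count(24 + 13, 5, 3))
})

test_that("titrate_panel returns one row per phage-strain series", {
  s <- rbind(series_spots(list(`2` = c(20, 22, 21)), phage = "pA"),
             series_spots(setNames(rep(list(0), 8), 0:7), phage = "pB"))
  out <- titrate_panel(s)
  expect_equal(nrow(out), 2)
  expect_setequal(out$status, c("quantified", "no_activity"))
  q <- out[out$status == "quantified", ]
  expect_equal(q$phage_id, "pA")
  expect_equal(q$mean_titer, titer_from_count(21, 5, 2))
})
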