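# Longitudinal monitoring: filtering, method comparison, herd summary,
# series change.

mkRecords <- function(values, source, id = "h1", start = "2021-04-15", by = 7) {
  data.frame(animal_id = id,
             date = as.Date(start) + seq(0, by = by, length.out = length(values)),
             source = source, value = values, stringsAsFactors = FALSE)
}

test_that("the isolated-spike rule removes the worked examples and only them", {
  bcs <- mkRecords(c(2.5, 2.5, 3.2, 2.5, 2.5), "bcsm")
  f <- filterAberrant(bcs)
  expect_equal(f$flag, c("kept", "kept", "removed", "kept", "kept"))

  bw <- mkRecords(c(500, 510, 640, 520), "bw")
  f2 <- filterAberrant(bw)
  expect_equal(f2$flag, c("kept", "kept", "removed", "kept"))

  drift <- mkRecords(c(2.5, 2.9, 3.3), "bcsm")  # steps of 0.4 <= 0.5: kept
  expect_true(all(filterAberrant(drift)$flag == "kept"))

  # endpoints are exempt even when extreme
  ends <- mkRecords(c(4.9, 2.5, 2.5, 0.1), "bcsm")
  expect_true(all(filterAberrant(ends)$flag == "kept"))

  # sources outside the rule pass through untouched
  dev <- mkRecords(c(2.5, 3.3, 2.5), "bcs3d")
  expect_true(all(filterAberrant(dev)$flag == "kept"))
})

test_that("short series warn and pass through; filtering is idempotent", {
  short <- mkRecords(c(2.5, 3.3), "bcsm")
  expect_warning(f <- filterAberrant(short), "filter skipped")
  expect_true(all(f$flag == "kept"))

  set.seed(51)
  for (rep in 1:20) {
    v <- round(2.5 + cumsum(rnorm(12, sd = 0.25)), 2)
    r <- mkRecords(v, "bcsm", id = sprintf("h%d", rep))
    once <- filterAberrant(r)
    twice <- filterAberrant(once)
    expect_identical(once$flag, twice$flag)
  }
})

test_that("compareMethods: identities and the through-origin convention", {
  r <- rbind(mkRecords(c(2.5, 2.6, 2.4, 2.7), "bcsm"),
             mkRecords(c(2.5, 2.6, 2.4, 2.7), "bcs3d"))
  cm <- compareMethods(r)
  expect_equal(cm$slope, 1)
  expect_equal(cm$r_squared, 1)
  expect_equal(cm$n, 4)

  r2 <- rbind(mkRecords(c(2.5, 2.6, 2.4, 2.7), "bcsm"),
              mkRecords(0.9 * c(2.5, 2.6, 2.4, 2.7), "bcs3d"))
  cm2 <- compareMethods(r2)
  expect_equal(cm2$slope, 0.9)
  expect_equal(cm2$r_squared, 1)

  # records further apart than the tolerance do not pair
  far <- rbind(mkRecords(c(2.5, 2.6, 2.4), "bcsm", by = 30),
               mkRecords(c(2.5, 2.6, 2.4), "bcs3d", by = 30,
                         start = "2021-04-25"))
  expect_error(compareMethods(far), "matched")
})

test_that("a simulated herd recovers a planted through-origin slope", {
  set.seed(52)
  recs <- NULL
  for (a in 1:10) {
    bcsm <- runif(12, 2.1, 3.0)
    bcs3d <- 0.97 * bcsm + rnorm(12, sd = 0.25)
    id <- sprintf("h%02d", a)
    recs <- rbind(recs,
                  mkRecords(bcsm, "bcsm", id = id, by = 14),
                  mkRecords(pmax(0.5, bcs3d), "bcs3d", id = id, by = 14))
  }
  cm <- compareMethods(recs)
  expect_equal(cm$n, 120)
  expect_lt(abs(cm$slope - 0.97), 0.03)
})

test_that("summarizeHerd reproduces the packaged herd table's printed summary", {
  herd <- heiferTable1()
  expect_equal(nrow(herd), 13)
  s <- summarizeHerd(herd)
  g <- function(col, what) s[s$column == col, what]
  expect_equal(round(g("bw_kg", "mean")), 505)
  expect_equal(round(g("bw_kg", "sd")), 43)
  expect_equal(round(g("bcs", "mean"), 2), 2.58)
  expect_equal(round(g("bcs", "sd"), 2), 0.26)
  expect_equal(round(g("gestation_mo", "mean"), 2), 2.93)
  expect_equal(round(g("volume_m3", "mean"), 3), 0.581)
  expect_equal(round(g("hip_width_mm", "mean")), 507)
  expect_equal(round(g("withers_height_mm", "mean")), 1376)
  expect_equal(round(g("chest_depth_mm", "mean")), 755)
  expect_equal(round(g("heart_girth_mm", "mean")), 2096)
  # row order invariance of the mean; sample SD of a duplicated row is 0
  s2 <- summarizeHerd(herd[rev(seq_len(nrow(herd))), ])
  expect_equal(s2$mean, s$mean)
  dup <- rbind(herd[3, ], herd[3, ])
  sdup <- summarizeHerd(dup)
  expect_true(all(sdup$sd == 0))
})

test_that("seriesChange: flat, linear BW gain, and a planted BCS decline", {
  flat <- mkRecords(rep(2.5, 10), "bcs3d")
  ch <- seriesChange(flat, "bcs3d", flat$date[2], flat$date[9])
  expect_equal(ch$change, 0, tolerance = 1e-9)

  # exactly linear 500 -> 600 kg over 150 d: 666.7 g/d
  bw <- mkRecords(seq(500, 600, length.out = 11), "bw", by = 15)
  chBW <- seriesChange(bw, "bw", bw$date[1], bw$date[11])
  expect_equal(chBW$change, 100, tolerance = 1e-6)
  expect_equal(chBW$rate_per_day, 1000 * 100 / 150, tolerance = 1e-3)
  expect_equal(round(chBW$rate_per_day, 1), 666.7)

  expect_error(seriesChange(bw, "bw", "2020-01-01", bw$date[5]), "outside")

  # 29 weekly device records per animal (the study's sampling): a planted
  # 0.15-point decline at noise sd 0.05 is recovered within +-0.05 for at
  # least 90% of 100 replicates, and without bias
  set.seed(53)
  est <- replicate(100, {
    weeks <- 0:28
    mu <- 2.5 - pmin(pmax((weeks - 8) / 12, 0), 1) * 0.15
    v <- mu + rnorm(29, sd = 0.05)
    r <- mkRecords(v, "bcs3d")
    seriesChange(r, "bcs3d", r$date[5], r$date[25])$change
  })
  expect_lt(abs(mean(est) - (-0.15)), 0.02)
  expect_gte(mean(abs(est + 0.15) <= 0.05), 0.9)
})
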