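test_that("Mosteller BSA reproduces reference values and is monotone", {
  expect_equal(round(bsa_mosteller(131.3, 28.6), 2), 1.02)
  expect_equal(round(bsa_mosteller(132.5, 29.3), 2), 1.04)
  expect_identical(bsa_mosteller(100, 36), 1)  # bh*bw = 3600
  expect_error(bsa_mosteller(0, 30), "positive")
  expect_error(bsa_mosteller(120, -1), "positive")
  expect_true(all(diff(bsa_mosteller(seq(100, 160, 10), 30)) > 0))
  expect_true(all(diff(bsa_mosteller(130, seq(20, 50, 5))) > 0))
})

test_that("LMS z-scores satisfy the defining identities", {
  expect_equal(lms_zscore(25, -1.2, 25, 0.1), 0)
  # L = 1 reduces to (x - M)/(M S)
  expect_equal(lms_zscore(27, 1, 25, 0.1), (27 - 25) / (25 * 0.1),
               tolerance = 1e-12)
  # tiny L agrees with the log-limit branch
  expect_equal(lms_zscore(1.1 * 25, 1e-12, 25, 0.1),
               lms_zscore(1.1 * 25, 0, 25, 0.1), tolerance = 1e-6)
  expect_error(lms_zscore(-1, 1, 25, 0.1), "positive")
  # round trip: x = M (1 + L S z)^(1/L) recovers z
  set.seed(42)
  for (i in 1:25) {
    l <- stats::runif(1, -2, 2); if (abs(l) < 0.05) l <- 0.5
    m <- stats::runif(1, 10, 150); s <- stats::runif(1, 0.03, 0.2)
    z <- stats::runif(1, -2.5, 2.5)
    x <- m * (1 + l * s * z)^(1 / l)
    expect_equal(lms_zscore(x, l, m, s), z, tolerance = 1e-9)
  }
})

test_that("24-h composite equals hand arithmetic and weighted-mean oracle", {
  v <- fixture_voids(vol = c(300, 500), cre = c(80, 50),
                     hours_day1 = 10, fvu_hour = 6)
  comp <- composite_24h(v)
  expect_equal(comp$uv24_ml, 800)
  expect_equal(comp$creu24_mg_dl, 61.25)
  expect_equal(comp$cre24_mg_day, 490)
  # single void: pooled equals that void
  one <- fixture_voids(hours_day1 = c(), fvu_hour = 6, vol = 400, cre = 88)
  expect_equal(composite_24h(one)$creu24_mg_dl, 88)
  # equal concentrations: pooled invariant to volumes
  eq <- fixture_voids(vol = c(120, 480, 90, 260, 200), cre = 64)
  expect_equal(composite_24h(eq)$creu24_mg_dl, 64)
  expect_error(composite_24h(fixture_voids(vol = 0, hours_day1 = 10)),
               "zero total volume")
  # brute-force oracle on random fixtures; two routes to cre24 agree
  set.seed(1)
  for (i in 1:20) {
    k <- sample(2:7, 1)
    v <- fixture_voids(hours_day1 = sort(stats::runif(k - 1, 8, 22)),
                       vol = stats::runif(k, 40, 500),
                       cre = stats::runif(k, 20, 200))
    comp <- composite_24h(v)
    expect_equal(comp$creu24_mg_dl,
                 sum(v$cre_mg_dl * v$volume_ml) / sum(v$volume_ml),
                 tolerance = 1e-12)
    expect_equal(comp$cre24_mg_day, sum(v$cre_mg_dl * v$volume_ml) / 100,
                 tolerance = 1e-9)
  }
})

test_that("spot designation finds FVU, SVU, TVU and the overnight interval", {
  v <- fixture_voids(hours_day1 = c(9, 12, 15.5, 20, 22), fvu_hour = 6.5,
                     cre = c(60, 70, 80, 90, 95, 104))
  sp <- designate_spots(v)
  expect_equal(sp$cre_f, 104)          # day-2 first void
  expect_equal(sp$cre_s, 60)           # first collected day-1 void
  expect_equal(sp$cre_t, 80)           # earliest at/after 15:00
  expect_equal(sp$interval_fvu_h, 8.5) # 22:00 -> 06:30
  expect_false(sp$tvu_missing)
  # no post-15:00 void: TVU fields NA, flagged not fatal
  sp2 <- designate_spots(fixture_voids(hours_day1 = c(9, 12, 14)))
  expect_true(sp2$tvu_missing)
  expect_true(is.na(sp2$cre_t) && is.na(sp2$sg_t))
  # unordered timestamps are a data error
  bad <- fixture_voids()
  bad$timestamp <- rev(bad$timestamp)
  expect_error(designate_spots(bad), "strictly increasing")
  # a day-1 void at exactly 15:00 qualifies as TVU
  sp3 <- designate_spots(fixture_voids(hours_day1 = c(9, 15, 20),
                                       cre = c(10, 20, 30, 40)))
  expect_equal(sp3$cre_t, 20)
})

test_that("the feature table carries the 25 features (26 with muscle)", {
  coh <- tiny_cohort(n = 15, seed = 4)
  sp <- designate_spots(coh$voids)
  ft <- build_feature_table(coh$children, sp)
  expect_equal(ncol(ft) - 1, 25)  # child_id + 25 features
  ftm <- build_feature_table(coh$children, sp, include_muscle = TRUE)
  expect_equal(ncol(ftm) - 1, 26)
  expect_true("muscle" %in% names(ftm))
  # per-hour feature is concentration / interval
  i <- 1
  expect_equal(ft$cre_f_per_h[i], sp$cre_f[i] / sp$interval_fvu_h[i])
  # hand value: CreF 104 over an 8-hour overnight interval
  sp1 <- sp[1, ]; sp1$cre_f <- 104; sp1$interval_fvu_h <- 8
  ft1 <- build_feature_table(coh$children[1, ], sp1)
  expect_equal(ft1$cre_f_per_h, 13.0)
  # SG = 1 makes the per-SG feature equal the raw concentration
  sp1$sg_f <- 1
  ft1 <- build_feature_table(coh$children[1, ], sp1)
  expect_equal(ft1$cre_f_per_sg, ft1$cre_f)
  # missing TVU propagates NA into TVU-derived features
  spNA <- sp; spNA$cre_t <- NA_real_
  ftNA <- build_feature_table(coh$children, spNA)
  expect_true(all(is.na(ftNA$cre_t_per_sg)))
})

test_that("the shipped synthetic LMS reference loads and centres z-scores", {
  path <- system.file("extdata", "lms_reference_synthetic.csv",
                      package = "crekid")
  ref <- read_lms_reference(path)
  expect_setequal(unique(ref$measure), c("BH", "BW", "BMI"))
  expect_true(all(ref$m > 0) && all(ref$s > 0))
  expect_equal(ref, synthetic_lms_reference()[names(ref)],
               tolerance = 1e-9, ignore_attr = TRUE)
  # z of the median is zero
  row <- ref[ref$sex == "boy" & ref$measure == "BH" &
               ref$age_months == 100, ]
  expect_equal(lms_zscore(row$m, row$l, row$m, row$s), 0)
})
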