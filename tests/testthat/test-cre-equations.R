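test_that("closed-form methods reproduce hand arithmetic", {
  expect_equal(cre_estimate("D", data.frame(x = 1:5)), rep(800, 5))
  expect_equal(cre_estimate("A", data.frame(bw = 28.6)), 592.02)
  expect_equal(cre_estimate("B", data.frame(sex = c("boy", "girl"),
                                            bw = c(30, 30))),
               c(30 * 23, 30 * 18))
  expect_equal(cre_estimate("C", data.frame(sex = "girl", bw = 27.6)), 441.6)
  expect_equal(cre_estimate("E", data.frame(sex = "boy", age = 9,
                                            bw = 30, bh = 130)),
               9 * (-12.63) + 30 * 15.12 + 130 * 7.39 - 79.9)
  expect_equal(cre_estimate("F", data.frame(cre_f = 104, sg_f = 1.020)), 78)
  expect_equal(cre_estimate("G", data.frame(cre_f = 104, sg_f = 1.020)),
               104 * 0.022 / 0.020)
  expect_equal(cre_estimate("J", data.frame(sex = "boy", bh = 140)),
               140 * 1.085 * ((140 - 168) * 0.0564 + 6.265))
  expect_equal(cre_estimate("J", data.frame(sex = "girl", bh = 130)),
               130 * 1.085 * 2.045 * exp((130 - 90) * 0.01552))
  expect_warning(
    kb <- cre_estimate("K", data.frame(sex = c("boy", "girl"),
                                       bh = c(130, 130), bw = c(28, 28))),
    "suspect")
  expect_equal(kb[2], -330 + 2.74 * 130 + 19.57 * 28)
  expect_equal(kb[1], -221 - 0.94 * 130 + 35)
})

test_that("method I unit handling is explicit", {
  d <- data.frame(sex = "boy", uv24 = 686)
  expect_message(v_dl <- cre_estimate("I", d), "ambiguous")
  expect_equal(v_dl, 6.86 * 104.4)
  expect_message(v_ml <- cre_estimate("I", d, uv24_unit = "mL"), "ambiguous")
  expect_equal(v_ml, 686 * 104.4)
})

test_that("input errors name the missing field; SGF=1 is a domain error", {
  expect_error(cre_estimate("A", data.frame(bh = 130)), "bw")
  expect_error(cre_estimate("E", data.frame(sex = "boy", age = 9, bw = 30)),
               "bh")
  expect_error(cre_estimate("F", data.frame(cre_f = 104, sg_f = 1)),
               "SGF")
})

test_that("method H is a registry hook", {
  register_method_h(NULL)
  expect_error(cre_estimate("H", data.frame(bw = 30)), "not configured")
  old <- register_method_h(function(d) d$bw * 15)
  expect_equal(cre_estimate("H", data.frame(bw = 30)), 450)
  register_method_h(NULL)
})

test_that("non-positive estimates are flagged, not silently dropped", {
  suppressWarnings(
    expect_warning(cre_estimate("K", data.frame(sex = "boy", bh = 140,
                                                bw = 30)),
                   "non-positive")
  )
})

test_that("published models evaluate as intercept + dot product", {
  m1 <- cre_model_published(1)
  expect_equal(predict(m1, data.frame(sex = "boy", age = 9, bsa = 1)),
               535.10, tolerance = 1e-9)
  d <- data.frame(sex = c("girl", "boy"), age = 8, bsa = 1.1)
  expect_equal(diff(predict(m1, d)), 38.54, tolerance = 1e-12)
  # oracle dot product across all ten models on random children
  set.seed(31)
  nd <- data.frame(sex = sample(1:2, 20, TRUE),
                   age = sample(6:12, 20, TRUE),
                   bh = stats::runif(20, 110, 160),
                   bsa = stats::runif(20, 0.7, 1.5),
                   cre_f_per_h = stats::runif(20, 2, 30))
  for (no in 1:10) {
    m <- cre_model_published(no)
    manual <- m$intercept +
      as.matrix(nd[m$features]) %*% m$coef[m$features]
    expect_equal(predict(m, nd), as.numeric(manual), tolerance = 1e-12)
  }
})

test_that("model 1R is the published correction of model 1", {
  m1r <- cre_model_1r()
  expect_equal(unname(m1r$coef),
               c(-38.54, 15.43, 633.73) * 1.15, tolerance = 1e-12)
  expect_equal(round(unname(m1r$coef), 2), c(-44.32, 17.74, 728.79))
  expect_equal(m1r$intercept, -198.96 * 1.15 - 49, tolerance = 1e-12)
  expect_equal(cre_model_1r(intercept = "printed")$intercept, -277.40)
  # worked value from printed constants
  expect_equal(predict(m1r, data.frame(sex = "boy", age = 8.7, bsa = 1.02)),
               575.6, tolerance = 0.05)
  # boys exceed girls by the sex coefficient under boy=1/girl=2
  d <- data.frame(sex = c("boy", "girl"), age = 9, bsa = 1)
  p <- predict(m1r, d)
  expect_equal(p[1] - p[2], 44.321, tolerance = 1e-9)
})

test_that("anthropometric methods and fitted models are monotone", {
  bw <- seq(20, 45, 5)
  for (m in c("A", "B", "C")) {
    expect_true(all(diff(cre_estimate(m, data.frame(sex = "boy", bw = bw))) > 0))
    expect_true(all(diff(cre_estimate(m, data.frame(sex = "girl", bw = bw))) > 0))
  }
  bh <- seq(110, 160, 10)
  expect_true(all(diff(cre_estimate("J", data.frame(sex = "girl", bh = bh))) > 0))
  for (mod in list(cre_model_published(1), cre_model_1r())) {
    d_bsa <- data.frame(sex = "boy", age = 9, bsa = seq(0.7, 1.5, 0.1))
    d_age <- data.frame(sex = "boy", age = 6:12, bsa = 1)
    expect_true(all(diff(predict(mod, d_bsa)) > 0))
    expect_true(all(diff(predict(mod, d_age)) > 0))
  }
})

test_that("the battery covers a cohort with no silent nulls", {
  coh <- tiny_cohort(n = 20, seed = 13)
  comp <- composite_24h(coh$voids)
  sp <- designate_spots(coh$voids)
  inp <- battery_inputs(coh$children, sp, comp)
  est <- cre_battery(inp, methods = cre_methods())
  expect_equal(nrow(est), 20 * 11)
  # every method except the unconfigured H yields finite estimates
  ok <- est$method != "H"
  expect_true(all(is.finite(est$cre24_pred_mg_day[ok])))
  h <- est[est$method == "H", ]
  expect_true(all(is.na(h$cre24_pred_mg_day)))
  expect_match(h$note[1], "not configured")
})
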