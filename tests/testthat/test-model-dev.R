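test_that("OLS fitting recovers exact linear data and matches the normal equations", {
  set.seed(21)
  d <- data.frame(sex = sample(1:2, 50, TRUE), age = sample(6:12, 50, TRUE),
                  bsa = stats::runif(50, 0.7, 1.5))
  y <- -200 - 40 * d$sex + 15 * d$age + 600 * d$bsa
  m <- fit_cre_model(d, c("sex", "age", "bsa"), y)
  expect_equal(unname(coef(m)), c(-200, -40, 15, 600), tolerance = 1e-9)
  expect_equal(m$adj_r2, 1, tolerance = 1e-9)
  # textbook normal-equations oracle on random small designs
  for (i in 1:50) {
    n <- sample(10:40, 1); p <- sample(1:4, 1)
    x <- matrix(stats::rnorm(n * p), n)
    colnames(x) <- paste0("f", seq_len(p))
    y <- stats::rnorm(n)
    m <- fit_cre_model(as.data.frame(x), colnames(x), y)
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(unname(coef(m)), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- data.frame(a = stats::rnorm(30))
  d$b <- 2 * d$a
  expect_error(fit_cre_model(d, c("a", "b"), stats::rnorm(30)),
               "collinear.*b")
  expect_no_error(fit_cre_model(d, "a", stats::rnorm(30)))
  expect_error(fit_cre_model(d[1:2, ], "a", stats::rnorm(2)), "n > p")
})

test_that("adjusted R2 never exceeds R2", {
  set.seed(3)
  for (i in 1:10) {
    n <- 40; p <- sample(2:5, 1)
    x <- as.data.frame(matrix(stats::rnorm(n * p), n))
    y <- stats::rnorm(n)
    m <- fit_cre_model(x, names(x), y)
    r2 <- summary(m$fit)$r.squared
    expect_lte(m$adj_r2, r2)
    # the penalty is the (n-1)/(n-p-1) inflation
    expect_equal(m$adj_r2, 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-12)
  }
})

test_that("lasso ranking is deterministic and handles degenerate features", {
  set.seed(14)
  d <- data.frame(a = stats::rnorm(80), b = stats::rnorm(80),
                  cst = rep(2, 80))
  y <- 3 * d$a + stats::rnorm(80, 0, 0.3)
  expect_warning(r1 <- lasso_rank(d, y, cv_folds = 5, seed = 4),
                 "all-constant")
  expect_warning(r2 <- lasso_rank(d, y, cv_folds = 5, seed = 4),
                 "all-constant")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false("cst" %in% r1$feature)
  expect_equal(r1$rank[r1$feature == "a"], 1L)
  # duplicated feature columns share a rank group
  d2 <- data.frame(a = d$a, b = d$b)
  d2$a_copy <- d2$a
  r3 <- suppressWarnings(lasso_rank(d2, y, cv_folds = 5, seed = 4))
  expect_equal(r3$rank[r3$feature == "a"], r3$rank[r3$feature == "a_copy"])
  # every feature appears exactly once and ranks start at 1
  expect_setequal(r3$feature, names(d2))
  expect_equal(min(r3$rank), 1L)
})

test_that("pure-noise features do not survive the 1-SE penalty", {
  set.seed(6)
  d <- as.data.frame(matrix(stats::rnorm(200 * 8), 200))
  y <- stats::rnorm(200)
  r <- lasso_rank(d, y, cv_folds = 10, seed = 2, lambda_rule = "1se")
  expect_length(attr(r, "selected"), 0)
})

test_that("the rank-1 group recovers the generative features", {
  # recovery is stochastic (collinear BH/BW can displace BSA in an
  # occasional draw), so assert over a small batch of cohorts
  hits <- 0
  for (s in 1:6) {
    coh <- tiny_cohort(n = 204, seed = 300 + s)
    sp <- designate_spots(coh$voids)
    ft <- suppressWarnings(build_feature_table(coh$children, sp))
    r <- lasso_rank(ft, coh$truth$true_cre24_mg_day, cv_folds = 20,
                    seed = 310 + s)
    if (all(c("sex", "age", "bsa") %in% attr(r, "rank1"))) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("subset search is exhaustive, sorted and column-order invariant", {
  set.seed(44)
  d <- data.frame(sex = sample(1:2, 120, TRUE),
                  age = sample(6:12, 120, TRUE),
                  bh = stats::rnorm(120, 131, 10),
                  bsa = stats::runif(120, 0.7, 1.4),
                  cre_f_per_h = stats::runif(120, 3, 25))
  y <- -200 - 40 * d$sex + 15 * d$age + 600 * d$bsa +
    stats::rnorm(120, 0, 69)
  cand <- names(d)
  cmp <- subset_search(d, y, cand, cv_folds = 10, seed = 5,
                       must_include_any = cand)
  expect_equal(nrow(cmp), 2^5 - 1)
  expect_true(all(diff(cmp$mean_cv_adj_r2) <= 1e-12))
  # single candidate
  one <- subset_search(d, y, "bsa", cv_folds = 10, seed = 5)
  expect_equal(nrow(one), 1)
  # column order of the data does not change the comparison
  cmp2 <- subset_search(d[rev(names(d))], y, cand, cv_folds = 10, seed = 5,
                        must_include_any = cand)
  expect_equal(as.data.frame(cmp), as.data.frame(cmp2))
  # the generative subset outranks its strict subset most of the time
  wins <- 0
  for (i in 1:20) {
    set.seed(400 + i)
    dd <- d
    yy <- -200 - 40 * dd$sex + 15 * dd$age + 600 * dd$bsa +
      stats::rnorm(120, 0, 69)
    cc <- subset_search(dd, yy, c("sex", "age", "bsa"), cv_folds = 10,
                        seed = 500 + i)
    full <- which(cc$features == "age, bsa, sex")
    part <- which(cc$features == "age, bsa")
    if (full < part) wins <- wins + 1
  }
  expect_gte(wins, 14)
})

test_that("the must-include constraint filters subsets", {
  set.seed(1)
  d <- data.frame(a = stats::rnorm(60), b = stats::rnorm(60),
                  c = stats::rnorm(60))
  y <- d$a + stats::rnorm(60, 0, 0.5)
  cmp <- subset_search(d, y, c("a", "b", "c"), cv_folds = 5, seed = 2,
                       must_include_any = "a")
  expect_equal(nrow(cmp), 4)  # subsets of {a,b,c} containing a
  expect_true(all(grepl("a", cmp$features)))
  expect_error(subset_search(d, y, character(), cv_folds = 5, seed = 2),
               "empty candidate")
})

test_that("train/test evaluation is seeded and exact on noiseless data", {
  set.seed(71)
  d <- data.frame(x1 = stats::rnorm(120), x2 = stats::rnorm(120),
                  x3 = stats::rnorm(120))
  y <- 2 * d$x1 - 3 * d$x2
  a <- train_test_split_eval(d, y, cv_folds = 10, seed = 9)
  b <- train_test_split_eval(d, y, cv_folds = 10, seed = 9)
  expect_identical(a, b)
  expect_gt(a$test_r2, 0.999)
  expect_error(train_test_split_eval(d[1:20, ], y[1:20], seed = 1),
               "n >= 25")
})

test_that("test R2 on cohort-scale data sits in a plausible band", {
  r2 <- numeric(10)
  for (i in 1:10) {
    coh <- tiny_cohort(n = 204, seed = 600 + i)
    sp <- designate_spots(coh$voids)
    ft <- suppressWarnings(build_feature_table(coh$children, sp))
    comp <- composite_24h(coh$voids)
    y <- comp$cre24_mg_day[match(ft$child_id, comp$child_id)]
    ev <- train_test_split_eval(ft, y, split = 0.8, cv_folds = 20,
                                seed = 700 + i)
    r2[i] <- ev$test_r2
  }
  expect_true(all(r2 > 0.5 & r2 < 0.9))
})
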