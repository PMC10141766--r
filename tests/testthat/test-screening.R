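# Two-way ANOVA from direct sums of squares, checked against closed forms
# and an independent reference implementation.

test_that("a pure additive factor-A effect lands entirely in SS_A", {
  # 2x2 design, 3 reps, zero noise, A-effect +/- delta/2
  delta <- 1.6
  A <- gl(2, 6, labels = c("a1", "a2"))
  B <- rep(gl(2, 3, labels = c("b1", "b2")), 2)
  y <- ifelse(A == "a1", -delta / 2, delta / 2)
  expect_warning(res <- twoWayAnova(y, A, B), "degenerate")
  tb <- res@table
  # SS_A = b*r * sum over levels of (delta/2)^2 = 6 * 2 * (delta/2)^2
  expect_equal(tb$ss[tb$term == "class"], 6 * 2 * (delta / 2)^2,
               tolerance = 1e-12)
  expect_equal(tb$ss[tb$term == "channel"], 0)
  expect_equal(tb$ss[tb$term == "interaction"], 0)
})

test_that("identical values in every cell degrade gracefully", {
  A <- gl(2, 8); B <- rep(gl(2, 4), 2)
  expect_warning(res <- twoWayAnova(rep(5, 16), A, B), "degenerate")
  expect_true(res@degenerate)
  expect_true(all(is.na(res@table$F[1:3])))
})

test_that("sums of squares decompose the total exactly", {
  set.seed(61)
  for (i in 1:10) {
    y <- rnorm(4 * 22 * 5)
    A <- gl(4, 22 * 5); B <- rep(gl(22, 5), 4)
    tb <- twoWayAnova(y, A, B)@table
    expect_equal(sum(tb$ss[1:4]), tb$ss[5], tolerance = 1e-8)
  }
})

test_that("F statistics agree with the reference implementation to 1e-8", {
  set.seed(62)
  for (i in 1:50) {
    y <- rnorm(4 * 22 * 3)
    A <- gl(4, 22 * 3); B <- rep(gl(22, 3), 4)
    mine <- twoWayAnova(y, A, B)@table
    ref <- summary(stats::aov(y ~ A * B))[[1]]
    expect_equal(mine$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
    expect_equal(mine$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
  }
})

test_that("null p-values are uniform (KS check at the suite level)", {
  set.seed(63)
  ps <- replicate(150, {
    y <- rnorm(4 * 4 * 3)
    twoWayAnova(y, gl(4, 12), rep(gl(4, 3), 4))@table$p[1]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted-effect detection rate rises with effect size", {
  rate <- vapply(c(0, 0.5, 1), function(effect) {
    hits <- vapply(1:15, function(s) {
      ft <- plantedFeatureTable(seed = 700 + s, effect = effect)
      scr <- screenFeatures(ft, seed = 1)
      scr$summary$significant[scr$summary$feature == "Hur"]
    }, NA)
    mean(hits)
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], rate[1])
  expect_gt(rate[3], 0.8)
})

test_that("screening flags planted features and spares pure noise", {
  ft <- plantedFeatureTable(seed = 71, effect = 1.5)
  scr <- screenFeatures(ft)
  s <- scr$summary
  expect_true(s$significant[s$feature == "Hur"])
  # pure-noise features stay quiet at alpha far below their null rate
  scr2 <- screenFeatures(ft, alpha = 1e-6)
  s2 <- scr2$summary
  expect_false(s2$significant[s2$feature == "DispEn"])
})

test_that("boundary alphas and degenerate tables behave", {
  ft <- plantedFeatureTable(seed = 72, effect = 0)
  s <- screenFeatures(ft, alpha = 1)$summary
  expect_true(all(s$significant))

  one <- new("FeatureTable",
             matrix = ft@matrix[1:10, , drop = FALSE],
             labels = factor(rep("left_hand", 10),
                             levels = levels(ft@labels)),
             subjectId = "x")
  expect_error(screenFeatures(one), "two classes")
})

test_that("unbalanced tables are balanced by seeded down-sampling", {
  ft <- plantedFeatureTable(seed = 73, effect = 1)
  keep <- c(1:10, 11:16, 21:30, 31:40)  # right_hand down to 6 trials
  unb <- new("FeatureTable", matrix = ft@matrix[keep, ],
             labels = ft@labels[keep], subjectId = "x")
  a <- screenFeatures(unb, seed = 5)
  b <- screenFeatures(unb, seed = 5)
  expect_identical(a$summary, b$summary)
})

test_that("malformed designs are rejected with the offending cell named", {
  y <- rnorm(12)
  expect_error(twoWayAnova(y, gl(1, 12), rep(gl(4, 3), 1)), "2 levels")
  A <- factor(c(rep("a", 6), rep("b", 6)))
  B <- factor(c(rep("x", 6), rep("y", 6)))  # cells a:y and b:x empty
  expect_error(twoWayAnova(y, A, B), "empty cell")
  A2 <- gl(2, 6); B2 <- rep(gl(6, 1), 2)
  expect_error(twoWayAnova(y, A2, B2), ">= 2 observations")
})

test_that("the per-subject report carries class means, sds and p-values", {
  ft <- plantedFeatureTable(seed = 74, effect = 1)
  rep <- featureReport(ft)
  expect_equal(nrow(rep), 4 * 4)  # 4 features x 4 classes
  expect_true(all(c("subject", "feature", "class", "mean", "sd", "p") %in%
                    names(rep)))
  hur <- rep[rep$feature == "Hur", ]
  expect_equal(order(hur$mean), 1:4)  # planted monotone class shift
})
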