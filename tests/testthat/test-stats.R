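test_that("pearson cell handles exact linear relationships", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCell(x, x)$r, 1)
  expect_equal(pearsonCell(x, -x)$r, -1)
  expect_equal(pearsonCell(x, x)$p, 0)
  expect_identical(pearsonCell(x, 2 * x + 3)$marker, "***")
  expect_error(pearsonCell(x, rep(1, 5)), "zero variance")
  expect_error(pearsonCell(1:2, 2:3), "complete pairs")
})

test_that("a correlation of 0.561 at n = 17 is significant at the * level", {
  # engineer a pair with exactly that correlation
  set.seed(1)
  x <- 1:17
  e <- stats::residuals(stats::lm(rnorm(17) ~ x))
  y <- 0.561 * as.vector(scale(x)) +
    sqrt(1 - 0.561^2) * as.vector(scale(e) * sqrt(16 / 16))
  cell <- pearsonCell(x, y)
  expect_equal(cell$r, 0.561, tolerance = 1e-10)
  expect_equal(correlationTStat(cell$r, 17), 2.6247, tolerance = 1e-3)
  expect_equal(cell$p, 0.019, tolerance = 0.01)
  expect_identical(cell$marker, "*")
})

test_that("pearson p-values agree with the reference implementation", {
  for (k in 1:50) {
    set.seed(2000 + k)
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    cell <- pearsonCell(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(cell$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(cell$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pearson is symmetric and invariant to positive affine maps", {
  set.seed(31)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(pearsonCell(x, y)$r, pearsonCell(y, x)$r)
  expect_equal(pearsonCell(3 * x + 7, y)$r, pearsonCell(x, y)$r,
               tolerance = 1e-12)
})

test_that("spearman is invariant under monotone transforms and honours ties", {
  set.seed(41)
  x <- rnorm(30)
  expect_equal(spearmanCell(x, exp(x) + x^3)$r, 1)
  expect_equal(spearmanCell(x, -x^3)$r, -1)
  for (k in 1:30) {
    set.seed(3000 + k)
    xi <- sample(1:8, 25, replace = TRUE)  # heavy ties
    yi <- sample(1:8, 25, replace = TRUE)
    cell <- spearmanCell(xi, yi)
    # brute-force oracle: average ranks then product-moment correlation
    expect_equal(cell$r, stats::cor(rank(xi), rank(yi)),
                 tolerance = 1e-12)
    expect_equal(cell$r,
                 stats::cor(xi, yi, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("markers always agree with the p-value rule", {
  expect_identical(significanceMarker(c(0.0009, 0.001, 0.009, 0.01,
                                        0.049, 0.05, 0.9)),
                   c("***", "**", "**", "*", "*", "", ""))
  set.seed(51)
  for (k in 1:40) {
    x <- rnorm(12); y <- rnorm(12)
    cell <- pearsonCell(x, y)
    expect_identical(cell$marker, significanceMarker(cell$p))
  }
})

test_that("normality screen is calibrated under the null and powered", {
  conforms <- vapply(1:100, function(k) {
    set.seed(4000 + k)
    df <- data.frame(v = rnorm(50))
    shapiroScreen(df, "v")$conforms
  }, logical(1))
  expect_gte(mean(conforms), 0.90)
  set.seed(6)
  skewed <- data.frame(v = rlnorm(200, 0, 1))
  row <- shapiroScreen(skewed, "v")
  expect_false(row$conforms)
  expect_gt(row$skewness, 0)
  const <- data.frame(v = rep(2, 20))
  expect_warning(row2 <- shapiroScreen(const, "v"), "constant")
  expect_true(is.na(row2$conforms))
  tiny <- data.frame(v = c(1, 2))
  expect_warning(expect_null(shapiroScreen(tiny, "v")), "fewer than 3")
})

test_that("simple OLS recovers exact lines and flags perfect fits", {
  x <- seq(0, 5, by = 0.5)
  expect_warning(row <- simpleOLS(2 * x + 1, x), "perfect fit")
  expect_equal(row$intercept, 1, tolerance = 1e-10)
  expect_equal(row$slope, 2, tolerance = 1e-10)
  expect_identical(row$t_slope, Inf)
  set.seed(61)
  noise <- simpleOLS(rnorm(40), rnorm(40))
  expect_lt(abs(noise$slope), 0.5)
  expect_identical(noise$marker, "")
  expect_error(simpleOLS(rnorm(5), rep(1, 5)), "zero variance")
})

test_that("OLS slope t equals the Pearson-implied t on any dataset", {
  for (k in 1:50) {
    set.seed(5000 + k)
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- runif(1, -1, 1) * x + rnorm(n)
    row <- simpleOLS(y, x)
    cell <- pearsonCell(x, y)
    expect_equal(row$t_slope, correlationTStat(cell$r, cell$n),
                 tolerance = 1e-10)
    expect_equal(row$p, cell$p, tolerance = 1e-10)
  }
})

test_that("correlation matrix has unit diagonal when features mirror indicators", {
  body <- do.call(rbind, lapply(1:8, function(i)
    makeBodyRecord(sprintf("P%d", i), smi = 5 + i * 0.4,
                   icw = 20 + i * 0.3)))
  feats <- data.frame(participant_id = body$participant_id,
                      mean_directional_shift = body$SMI)
  cells <- suppressWarnings(correlationMatrix(feats, body))
  smiCell <- cells[cells$x == "SMI" &
                   cells$y == "mean_directional_shift", ]
  expect_equal(smiCell$r, 1)
  expect_identical(smiCell$n, 8L)
})

test_that("correlation matrix reports unmatched ids on a failed join", {
  body <- rbind(makeBodyRecord("A"), makeBodyRecord("B"))
  feats <- data.frame(participant_id = c("X", "Y"),
                      mean_directional_shift = c(0.3, 0.4))
  expect_error(correlationMatrix(feats, body), "unmatched ids")
})

test_that("pairwise-complete n is recorded per cell", {
  body <- do.call(rbind, lapply(1:10, function(i)
    makeBodyRecord(sprintf("P%d", i), smi = 5 + 0.5 * i,
                   icw = 20 + 0.3 * (i %% 4))))
  body$SMI[c(2, 5)] <- NA
  feats <- data.frame(participant_id = body$participant_id,
                      mean_directional_shift = seq(0.2, 0.65, 0.05))
  cells <- suppressWarnings(correlationMatrix(feats, body))
  expect_identical(
    cells$n[cells$x == "SMI" & cells$y == "mean_directional_shift"], 8L)
  expect_identical(
    cells$n[cells$x == "ICW" & cells$y == "mean_directional_shift"], 10L)
})

test_that("Benjamini-Hochberg adjustment rewrites markers consistently", {
  set.seed(71)
  body <- do.call(rbind, lapply(1:12, function(i)
    makeBodyRecord(sprintf("P%d", i), smi = rnorm(1, 8),
                   icw = rnorm(1, 21), bmi = rnorm(1, 22))))
  feats <- data.frame(participant_id = body$participant_id,
                      mean_directional_shift = rnorm(12, 0.36, 0.15))
  cells <- suppressWarnings(correlationMatrix(feats, body, adjust = "BH"))
  expect_true(all(cells$p_adjusted >= cells$p - 1e-15, na.rm = TRUE))
  expect_identical(cells$marker, significanceMarker(cells$p_adjusted))
})

test_that("formatted correlation table renders r marker(p) cells", {
  cells <- data.frame(x = c("SMI", "SMI"), y = c("mean_directional_shift",
                                                 "mean_displacement"),
                      method = "pearson", r = c(0.561, 0.130), n = 17,
                      p = c(0.019, 0.619), marker = c("*", ""),
                      stringsAsFactors = FALSE)
  wide <- formatCorrelationTable(cells)
  expect_identical(wide$mean_directional_shift[1], "0.561 *(0.019)")
  expect_identical(wide$mean_displacement[1], "0.130 (0.619)")
})

test_that("stratified analysis returns identical grids for identical strata", {
  body <- do.call(rbind, lapply(1:8, function(i)
    makeBodyRecord(sprintf("P%d", i), sex = "male",
                   smi = 5 + 0.4 * i, icw = 20 + 0.2 * i)))
  body2 <- body
  body2$participant_id <- sprintf("Q%d", 1:8)
  body2$sex <- "female"
  both <- rbind(body, body2)
  feats <- data.frame(participant_id = both$participant_id,
                      mean_directional_shift = rep(seq(0.2, 0.55, 0.05),
                                                   2))
  out <- suppressWarnings(stratifiedAnalysis(feats, both))
  expect_setequal(names(out), c("male", "female"))
  expect_equal(out$male$cells$r, out$female$cells$r, tolerance = 1e-12)
  expect_equal(out$male$summary[-1], out$female$summary[-1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("small strata carry a low-n warning but still produce grids", {
  body <- do.call(rbind, lapply(1:9, function(i)
    makeBodyRecord(sprintf("P%d", i),
                   sex = if (i <= 3) "female" else "male",
                   smi = 5 + 0.4 * i, icw = 20 + 0.2 * i)))
  feats <- data.frame(participant_id = body$participant_id,
                      mean_directional_shift = seq(0.2, 0.6, 0.05))
  expect_warning(out <- stratifiedAnalysis(feats, body),
                 "small sample")
  expect_true(out$female$low_n)
  expect_identical(out$female$n, 3L)
  expect_gt(nrow(out$female$cells), 0)
  body$sex[1] <- "other"
  expect_error(stratifiedAnalysis(feats, body), "unknown stratum labels")
})
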