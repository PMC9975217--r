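test_that("diversity indices match closed forms and vegan", {
  d <- diversity_summary(c(1, 1, 1, 1))
  expect_equal(d$richness_S, 4L)
  expect_equal(d$shannon_H, log(4), tolerance = 1e-12)
  expect_equal(d$pielou_J, 1, tolerance = 1e-12)

  d1 <- diversity_summary(c(5, 0, 0))
  expect_equal(d1$richness_S, 1L)
  expect_equal(d1$shannon_H, 0)
  expect_equal(d1$pielou_J, 0)

  d2 <- diversity_summary(c(2, 1, 1))
  expect_equal(d2$shannon_H,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(diversity_summary(c(2, 1, 1), one_minus_pielou = TRUE)$pielou_J,
               1 - d2$pielou_J)
  expect_error(diversity_summary(c(0, 0)), "all-zero")

  skip_if_not_installed("vegan")
  set.seed(41)
  for (k in 1:10) {
    x <- rpois(12, 5)
    if (sum(x) == 0) next
    expect_equal(diversity_summary(x)$shannon_H,
                 unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("RV coefficient has its scale and orthogonality properties", {
  set.seed(42)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  expect_equal(rv_coefficient(X, 3 * X), 1, tolerance = 1e-12)

  # Y built from residuals of projection: orthogonal column spaces
  Z <- matrix(rnorm(30), 10, 3)
  Xc <- scale(X, scale = FALSE)
  Zc <- scale(Z, scale = FALSE)
  Yres <- Zc - Xc %*% solve(crossprod(Xc), crossprod(Xc, Zc))
  expect_equal(rv_coefficient(X, Yres), 0, tolerance = 1e-12)
  expect_error(rv_coefficient(matrix(1, 5, 2), X[1:5, ]), "zero-variance")
})

test_that("escoufier_select is greedy-optimal, monotone and respects level", {
  set.seed(43)
  m <- matrix(abs(rnorm(20 * 6)), 20, 6,
              dimnames = list(NULL, paste0("cc", 1:6)))
  tr <- escoufier_select(m, level = 0.75, min_occurrence = 1)
  expect_equal(sort(tr$order), sort(colnames(m)))
  expect_true(all(diff(tr$cumulative_rv) >= -1e-10))
  expect_equal(tr$cumulative_rv[length(tr$cumulative_rv)], 1,
               tolerance = 1e-9)
  expect_gte(tr$cumulative_rv[length(tr$selected)], 0.75)
  if (length(tr$selected) > 1L) {
    expect_lt(tr$cumulative_rv[length(tr$selected) - 1L], 0.75)
  }

  # per-step greedy choice equals exhaustive search with the independent
  # RV implementation
  sel <- character(0)
  for (step in seq_len(ncol(m))) {
    cand <- setdiff(colnames(m), sel)
    rvs <- vapply(cand, function(j) {
      rv_coefficient(m[, c(sel, j), drop = FALSE], m)
    }, 0)
    expect_equal(tr$order[step], cand[which.max(rvs)])
    expect_equal(tr$cumulative_rv[step], max(rvs), tolerance = 1e-10)
    sel <- c(sel, tr$order[step])
  }

  # level 1 returns every column
  tr1 <- escoufier_select(m, level = 1, min_occurrence = 1)
  expect_equal(sort(tr1$selected), sort(colnames(m)))

  single <- m[, 1, drop = FALSE]
  trs <- escoufier_select(single, min_occurrence = 1)
  expect_equal(trs$selected, "cc1")
  expect_equal(trs$cumulative_rv, 1, tolerance = 1e-12)

  expect_error(escoufier_select(m, level = 0), "level")
})

test_that("occurrence screen excludes rare components before selection", {
  set.seed(44)
  m <- cbind(common = abs(rnorm(20)),
             rare = c(1, 2, rep(0, 18)))
  colnames(m) <- c("common", "rare")
  tr <- escoufier_select(m, min_occurrence = 5)
  expect_equal(tr$excluded, "rare")
  expect_false("rare" %in% tr$order)
})

test_that("rhythmic_set applies a strict threshold", {
  res <- data.frame(cc_id = c("a", "b", "c"),
                    pn_max = c(10, 10.1, 25))
  expect_equal(rhythmic_set(res), c("b", "c"))
  expect_equal(rhythmic_set(res[0, ]), character(0))
})

test_that("rhythmic_indicators intersects selection and rhythmicity", {
  tr <- structure(list(selected = c("a", "b")), class = "rv_trace")
  expect_equal(rhythmic_indicators(tr, c("c", "d")), character(0))
  expect_equal(rhythmic_indicators(tr, c("b", "a")), c("a", "b"))
})

test_that("seasonal_prevalence counts distinct seasons with presence", {
  dates <- as.Date(c("2015-01-10", "2015-02-20", "2015-04-05",
                     "2015-07-15", "2015-10-01"))
  expect_equal(seasonal_prevalence(dates, c(1, 2, 0, 0, 0), 2015), 1L)
  expect_equal(seasonal_prevalence(dates, c(1, 0, 1, 1, 1), 2015), 4L)
  expect_equal(seasonal_prevalence(dates, rep(0, 5), 2015), 0L)
  expect_equal(seasonal_prevalence(dates, rep(1, 5), 2014), 0L)
})

test_that("annual mean monthly abundance averages within months first", {
  dates <- as.Date(c("2015-01-10", "2015-01-20", "2015-07-15"))
  # January mean 0.2, July mean 0.4 -> 0.3
  expect_equal(annual_mean_monthly_abundance(dates, c(0.1, 0.3, 0.4), 2015),
               0.3)
  expect_equal(annual_mean_monthly_abundance(dates, c(0.5, 0.5, 0.5), 2015),
               0.5)
  expect_true(is.na(annual_mean_monthly_abundance(dates, c(1, 1, 1), 2012)))
})
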