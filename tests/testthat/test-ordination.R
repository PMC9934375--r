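test_that("chord transform normalizes rows and is idempotent", {
  expect_equal(chord_transform(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  m <- matrix(runif(20), 4)
  tm <- chord_transform(m)
  expect_equal(unname(sqrt(rowSums(tm^2))), rep(1, 4), tolerance = 1e-12)
  expect_equal(chord_transform(tm), tm, tolerance = 1e-12)
  # scale invariance: multiplying a row by c > 0 changes nothing
  m2 <- m; m2[2, ] <- 7 * m[2, ]
  expect_equal(chord_transform(m2), tm, tolerance = 1e-12)
  bad <- m; bad[3, ] <- 0; rownames(bad) <- paste0("s", 1:4)
  expect_error(chord_transform(bad), "all-zero row.*s3")
  # matches vegan's normalize standardization
  expect_equal(unname(tm), unname(vegan::decostand(m, "normalize")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dummy coding produces X-1 columns against a reference", {
  y <- c("2007", "2008-2010", "2011-2014", "2008-2010")
  d <- dummy_code(y, reference = "2011-2014", prefix = "year")
  expect_equal(ncol(d), 2L)
  expect_equal(colnames(d), c("year_2007", "year_2008-2010"))
  expect_equal(d[3, ], c(`year_2007` = 0, `year_2008-2010` = 0))
  expect_equal(ncol(dummy_code(c("a", "b", "a"))), 1L)
  expect_error(dummy_code(c("a", "a")), "at least 2")
})

test_that("noise-free linear responses are fully constrained", {
  set.seed(1)
  X <- cbind(x1 = rnorm(40), x2 = rnorm(40))
  Y <- X %*% matrix(rnorm(6), 2) # exact linear map, no noise
  f <- fit_rda(Y, X)
  expect_equal(f$total_constrained_fraction, 1, tolerance = 1e-10)
  expect_equal(sum(f$axis_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(f$axis_fractions) <= 1e-12))
})

test_that("single predictor, single response reduces to squared correlation", {
  set.seed(2)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  f <- fit_rda(matrix(y), matrix(x, dimnames = list(NULL, "x")))
  expect_equal(f$total_constrained_fraction, cor(x, y)^2, tolerance = 1e-10)
})

test_that("constrained fraction matches vegan and is invariant to recoding", {
  set.seed(3)
  n <- 50
  Y <- chord_transform(matrix(rpois(n * 6, 3), n))
  grp <- sample(c("a", "b", "c"), n, replace = TRUE)
  X1 <- cbind(z = rnorm(n), dummy_code(grp, reference = "a"))
  X2 <- cbind(z = 10 * X1[, "z"] + 3, dummy_code(grp, reference = "c"))
  f1 <- fit_rda(Y, X1)
  f2 <- fit_rda(Y, X2)
  expect_equal(f1$total_constrained_fraction, f2$total_constrained_fraction,
               tolerance = 1e-10)
  expect_equal(f1$axis_fractions, f2$axis_fractions, tolerance = 1e-8)
  v <- vegan::rda(Y ~ X1)
  expect_equal(f1$total_constrained_fraction, v$CCA$tot.chi / v$tot.chi,
               tolerance = 1e-10)
})

test_that("null predictors explain about p/(n-1) and pseudo-F is near 1", {
  set.seed(4)
  fracs <- c(); fs <- c()
  for (r in 1:30) {
    n <- 100; p <- 4
    Y <- matrix(rnorm(n * 5), n)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    f <- fit_rda(Y, X)
    fracs <- c(fracs, f$total_constrained_fraction)
    fs <- c(fs, f$pseudo_f)
  }
  expect_equal(mean(fracs), 4 / 99, tolerance = 0.15)
  expect_equal(mean(fs), 1, tolerance = 0.1)
})

test_that("adding a pure-noise predictor never decreases the fit", {
  set.seed(5)
  Y <- matrix(rnorm(40 * 3), 40)
  X <- matrix(rnorm(40), dimnames = list(NULL, "x1"))
  base <- fit_rda(Y, X)$total_constrained_fraction
  for (r in 1:5) {
    X2 <- cbind(X, noise = rnorm(40))
    expect_gte(fit_rda(Y, X2)$total_constrained_fraction, base - 1e-12)
  }
})

test_that("collinear predictors are reported by name", {
  set.seed(6)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x, c = rnorm(30))
  expect_error(fit_rda(matrix(rnorm(60), 30), X), "collinear.*b")
})

test_that("permutation test attains the 0.005 floor on strong effects", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  Y <- cbind(5 * x + rnorm(n, sd = 0.1), -3 * x + rnorm(n, sd = 0.1))
  f <- fit_rda(Y, matrix(x, dimnames = list(NULL, "x")))
  pt <- rda_permutation_test(f, "x", n_permutations = 199, seed = 8)
  expect_equal(pt$p_value, 0.005)
  # determinism
  pt2 <- rda_permutation_test(f, "x", n_permutations = 199, seed = 8)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(rda_permutation_test(f, "x", n_permutations = 9), "19")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(9)
  ps <- vapply(1:40, function(r) {
    Y <- matrix(rnorm(30 * 3), 30)
    X <- cbind(x = rnorm(30), z = rnorm(30))
    f <- fit_rda(Y, X)
    rda_permutation_test(f, "x", n_permutations = 39, seed = r)$p_value
  }, 0)
  expect_lte(mean(ps <= 0.05), 0.175)  # ~alpha with Monte-Carlo slack
  expect_gt(mean(ps), 0.3)             # p not systematically tiny
})

test_that("rda_design removes rare taxa and builds the study predictors", {
  fx <- study_scale_fixture()
  d <- rda_design(fx, min_stomachs = 4)
  pres <- diet_matrix(fx, "presence")
  expect_true(all(colSums(pres[, colnames(d$response)]) >= 4))
  expect_true(all(c("EFL", "SST", "area_within_SCB", "half_year_first",
                    "year_2007", "year_2008-2010") %in%
                    colnames(d$predictors)))
  # stomachs without EFL are excluded from the design
  expect_false(any(is.na(
    fx$stomachs$efl_cm[match(d$stomach_ids, fx$stomachs$stomach_id)])))
  f <- fit_rda(d$response, d$predictors, d$terms)
  expect_true(f$total_constrained_fraction > 0 &&
                f$total_constrained_fraction < 1)
  expect_equal(sum(f$axis_fractions), 1, tolerance = 1e-9)
})
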