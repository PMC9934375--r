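test_that("degenerate rarefaction curves are exact", {
  # every stomach holds the same single taxon: flat curve at 1, sd 0
  same <- make_dataset(replicate(4, occ("tx1", 1L, 1), simplify = FALSE))
  rc <- rarefaction_curve(same, 20, seed = 1)
  expect_equal(rc$mean_taxa, rep(1, 4))
  expect_equal(rc$sd_taxa, rep(0, 4))
  # k stomachs with k private taxa: identity line, sd 0
  priv <- make_dataset(lapply(1:5, function(i)
    occ(sprintf("tx%d", i), 1L, 1)))
  rc <- rarefaction_curve(priv, 20, seed = 1)
  expect_equal(rc$mean_taxa, 1:5)
  expect_equal(rc$sd_taxa, rep(0, 5))
  expect_error(rarefaction_curve(make_dataset(list(NULL))), "no stomachs")
})

test_that("exhaustive rarefaction equals the closed-form expectation", {
  ds <- make_dataset(list(
    occ(c("tx1", "tx2"), c(1L, 1L), c(1, 1)),
    occ("tx1", 2L, 2),
    occ("tx3", 1L, 1),
    occ(c("tx2", "tx3"), c(1L, 1L), c(1, 1)),
    occ("tx1", 1L, 1)))
  rc <- rarefaction_curve(ds, "all")
  expect_equal(rc$n_permutations, 120L)
  pres <- diet_matrix(ds, "presence")
  expect_equal(rc$mean_taxa, rarefaction_expectation(pres),
               tolerance = 1e-12)
  expect_equal(tail(rc$sd_taxa, 1), 0)
  expect_true(all(diff(rc$mean_taxa) >= 0))
  # Monte-Carlo mean converges to the same expectation
  mc <- rarefaction_curve(ds, 3000, seed = 4)
  se <- mc$sd_taxa / sqrt(3000)
  expect_true(all(abs(mc$mean_taxa - rc$mean_taxa) < 4 * se + 1e-9))
})

test_that("rarefaction is seed-reproducible and label-invariant", {
  ds <- random_dataset(11, k = 15, n_taxa = 6)
  a <- rarefaction_curve(ds, 50, seed = 7)
  b <- rarefaction_curve(ds, 50, seed = 7)
  expect_identical(a$mean_taxa, b$mean_taxa)
  expect_identical(a$sd_taxa, b$sd_taxa)
  # relabeling stomachs (consistent rename) leaves the curve unchanged
  ds2 <- ds
  ds2$stomachs$stomach_id <- paste0("Z", ds$stomachs$stomach_id)
  ds2$prey$stomach_id <- paste0("Z", ds$prey$stomach_id)
  c1 <- rarefaction_curve(ds2, 50, seed = 7)
  expect_identical(a$mean_taxa, c1$mean_taxa)
})

test_that("rarefaction agrees with vegan's random accumulation curve", {
  ds <- random_dataset(13, k = 20, n_taxa = 8)
  rc <- rarefaction_curve(ds, 400, seed = 2)
  sp <- vegan::specaccum(diet_matrix(ds, "presence"), method = "random",
                         permutations = 400)
  se <- rc$sd_taxa / sqrt(400) + sp$sd / sqrt(400)
  expect_true(all(abs(rc$mean_taxa - sp$richness) <= 4 * se + 1e-9))
})

test_that("asymptote slope test handles flat, sloped and noisy tails", {
  flat <- structure(list(n_stomachs = 1:6, mean_taxa = c(10, 15, 20, 20, 20,
                                                         20),
                         sd_taxa = rep(0, 6), n_permutations = 1L, seed = 1L),
                    class = "rarefaction_result")
  r <- asymptote_slope_test(flat)
  expect_equal(r$slope, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$asymptote_reached)

  line <- flat; line$mean_taxa <- c(1, 2, 3, 3.5, 4, 4.5)
  expect_warning(r2 <- asymptote_slope_test(line), "degenerate")
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$p_value, 0)
  expect_false(r2$asymptote_reached)

  noisy <- flat; noisy$mean_taxa <- c(5, 9, 12, 12.1, 11.9, 12.05)
  r3 <- asymptote_slope_test(noisy)
  expect_true(r3$p_value > 0 && r3$p_value < 1)
  expect_error(asymptote_slope_test(flat, n_points = 10), "fewer than")
})

test_that("slope test rarely rejects on saturating accumulation curves", {
  # richness saturates quickly: few shared taxa, many stomachs
  rejections <- 0L
  for (s in 1:60) {
    ds <- random_dataset(1000 + s, k = 25, n_taxa = 4)
    rc <- rarefaction_curve(ds, 60, seed = s)
    r <- asymptote_slope_test(rc)
    rejections <- rejections + !r$asymptote_reached
  }
  expect_lte(rejections / 60, 0.15)
})

test_that("bootstrap comparison is reproducible and enforces group minima", {
  ds <- simulate_dataset(sim_config(n_stomachs = 80, seed = 21))
  ds <- apply_exclusions(ds)$dataset
  a <- bootstrap_gii_compare(ds, "area", "within_SCB", "beyond_SCB",
                             taxa = c("T01", "T02"), n_replicates = 200,
                             seed = 5)
  b <- bootstrap_gii_compare(ds, "area", "within_SCB", "beyond_SCB",
                             taxa = c("T01", "T02"), n_replicates = 200,
                             seed = 5)
  expect_identical(a$prop_a_gt_b, b$prop_a_gt_b)
  expect_equal(a$seed, c(5L, 5L))
  tiny <- random_dataset(2, k = 12, n_taxa = 3)
  expect_error(
    bootstrap_gii_compare(tiny, "area", "within_SCB", "beyond_SCB",
                          taxa = "tx1"),
    "beyond_SCB")
})

test_that("an exclusive dominant taxon is always called for its group", {
  contents <- c(
    lapply(1:12, function(i) occ(c("dom", "bg"), c(5L, 1L), c(50, 1))),
    lapply(1:12, function(i) occ("bg", 2L, 2)))
  ds <- make_dataset(contents, lon = c(rep(-119, 12), rep(-122, 12)))
  b <- bootstrap_gii_compare(ds, "area", "within_SCB", "beyond_SCB",
                             taxa = "dom", n_replicates = 300, seed = 9)
  expect_equal(b$prop_a_gt_b, 1)
  expect_true(b$significant)
  expect_equal(b$direction, "a")
})

test_that("identical groups give a balanced bootstrap proportion", {
  one_group <- lapply(1:15, function(i)
    occ(c("tx1", "tx2")[seq_len(1 + i %% 2)], c(2L, 1L)[seq_len(1 + i %% 2)],
        c(4, 1)[seq_len(1 + i %% 2)]))
  ds <- make_dataset(c(one_group, one_group),
                     lon = c(rep(-119, 15), rep(-122, 15)))
  b <- bootstrap_gii_compare(ds, "area", "within_SCB", "beyond_SCB",
                             taxa = "tx1", n_replicates = 1000, seed = 31)
  # exchangeable groups: proportion near 1/2 (ties counted in neither tail)
  expect_lt(abs(b$prop_a_gt_b - 0.5), 3 * sqrt(0.25 / 1000) + 0.05)
  expect_false(b$significant)
})
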