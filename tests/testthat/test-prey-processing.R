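test_that("minimum_number pairs hard parts and adds intact prey", {
  expect_equal(minimum_number(5L, 3L, 0L, 0L, 2L), 7L)
  expect_equal(minimum_number(0L, 0L, 4L, 4L, 0L), 4L)
  expect_equal(minimum_number(0L, 0L, 0L, 0L, 1L), 1L)
  expect_equal(minimum_number(), 0L)
  expect_error(minimum_number(-1L), "non-negative")
})

test_that("minimum_number is monotone in every argument", {
  set.seed(42)
  for (i in 1:50) {
    args <- as.list(sample(0:6, 5, replace = TRUE))
    base <- do.call(minimum_number, args)
    for (j in 1:5) {
      bumped <- args; bumped[[j]] <- bumped[[j]] + 1L
      expect_gte(do.call(minimum_number, bumped), base)
    }
    expect_equal(minimum_number(0L, 0L, 0L, 0L, args[[5]]), args[[5]])
  }
})

test_that("exclusions remove flagged occurrences and reclassify stomachs", {
  ds <- make_dataset(list(
    occ("tx1", 2L, 10, net_feeding_flag = TRUE),
    occ(c("tx1", "tx2"), c(1L, 3L), c(2, 6),
        secondary_prey_flag = c(FALSE, TRUE)),
    occ("tx2", 1L, 1)))
  out <- apply_exclusions(ds)
  rep <- out$report
  expect_equal(rep$n_removed[rep$reason == "net_feeding"], 1L)
  expect_equal(rep$n_removed[rep$reason == "secondary_prey"], 1L)
  # stomach whose sole occurrence was net feeding becomes empty
  expect_equal(out$dataset$stomachs$status,
               c("empty", "with_food", "with_food"))
  expect_equal(attr(rep, "statuses_changed"), 1L)
  # idempotent: a second application is the identity
  again <- apply_exclusions(out$dataset)
  expect_identical(again$dataset$prey, out$dataset$prey)
  expect_identical(again$dataset$stomachs$status, out$dataset$stomachs$status)
  expect_equal(sum(again$report$n_removed), 0L)
  # unflagged dataset passes through untouched
  clean <- make_dataset(list(occ("tx1", 1L, 1)))
  expect_equal(sum(apply_exclusions(clean)$report$n_removed), 0L)
})

test_that("prey sizes report truncated means/medians for n >= 2", {
  ds <- make_dataset(list(
    occ("cock_eyed", 2L, 5, ds1 = 2L, lengths_mm = I(list(c(150, 210)))),
    occ("splitnose", 2L, 5, ds2 = 2L, lengths_mm = I(list(c(290, 310)))),
    occ("onycho", 2L, 5, ds1 = 2L, lengths_mm = I(list(c(165, 270)))),
    occ("single", 1L, 1, ds1 = 1L, lengths_mm = I(list(230)))))
  tab <- prey_size_table(ds)
  row <- function(t) tab[tab$taxon_id == t, ]
  expect_equal(row("cock_eyed")[, c("mean_mm", "median_mm")],
               data.frame(mean_mm = 180, median_mm = 180),
               ignore_attr = TRUE)
  expect_equal(row("splitnose")$mean_mm, 300)
  # half values truncate toward zero while raw precision is retained
  expect_equal(row("onycho")$mean_mm, 217)
  expect_equal(row("onycho")$raw_mean_mm, 217.5)
  # single specimen: range only
  expect_equal(row("single")[, c("min_mm", "max_mm")],
               data.frame(min_mm = 230, max_mm = 230), ignore_attr = TRUE)
  expect_true(is.na(row("single")$mean_mm))
  expect_true(all(tab$min_mm <= tab$median_mm | is.na(tab$median_mm)))
})

test_that("lengths from fully digested occurrences are excluded by state", {
  ds <- make_dataset(list(
    occ("tx1", 2L, 5, ds3 = 2L, lengths_mm = I(list(c(100, 120)))),
    occ("tx1", 1L, 2, ds5 = 1L, lengths_mm = I(list(999)))))
  expect_equal(nrow(prey_size_table(ds)), 0L)
  with3 <- prey_size_table(ds, include_state3 = TRUE)
  expect_equal(with3$n_measured, 2L)
  expect_equal(with3$max_mm, 120)
})

test_that("digestion profile sums to one and flags empty input", {
  ds <- make_dataset(list(occ("tx1", 3L, 5, ds6 = 3L)))
  expect_equal(unname(digestion_profile(ds)), c(0, 0, 0, 0, 0, 1))
  mixed <- make_dataset(list(occ("tx1", 4L, 5, ds4 = 2L, ds5 = 1L,
                                 ds1 = 1L)))
  expect_equal(sum(digestion_profile(mixed)), 1)
  none <- make_dataset(list(occ("tx1", 1L, 1, ds4 = 0L)))
  none$prey[paste0("ds", 1:6)] <- 0L
  expect_error(digestion_profile(none), "no items")
})

test_that("simulated digestion profile matches the configured state law", {
  probs <- c(0.015, 0.02, 0.02, 0.60, 0.31, 0.035)
  ds <- simulate_dataset(sim_config(n_stomachs = 400,
                                    digestion_probs = probs, seed = 9))
  prof <- digestion_profile(ds)
  n_items <- sum(ds$prey$count)
  # each state proportion within 4 binomial SEs of its generating value
  se <- sqrt(probs * (1 - probs) / n_items)
  expect_true(all(abs(prof - probs) < 4 * se + 1e-6))
  # the advanced-digestion mass (states 4-5) dominates, as in real material
  expect_gt(prof[4] + prof[5], 0.85)
})
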