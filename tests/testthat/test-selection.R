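test_that("age window keeps the closed interval [min, max]", {
  rec <- make_records(age = c(0, 1, 70, 138, 139, 500),
                      weight = rep(100, 6))
  kept <- apply_age_window(rec)
  expect_setequal(kept$age_days, c(1, 70, 138))
  rec$age_days[2] <- NA_integer_
  expect_equal(nrow(apply_age_window(rec)), 2L)
  expect_equal(nrow(apply_age_window(rec[0, ])), 0L)
})

test_that("farm activity filter drops spans of a year or less entirely", {
  rec <- dplyr::bind_rows(
    make_records(age = c(1, 10), weight = c(50, 60), farm = "A",
                 calf = c("a1", "a2")),
    make_records(age = c(1, 10), weight = c(50, 60), farm = "B",
                 calf = c("b1", "b2")))
  # farm A spans 366 days, farm B 365
  rec$recording_date[2] <- rec$recording_date[1] + 366
  rec$recording_date[4] <- rec$recording_date[3] + 365
  kept <- apply_farm_activity(rec)
  expect_setequal(unique(kept$farm_id), "A")
  # single-recording farm has span 0 and is dropped
  one <- make_records(age = 5, weight = 50, farm = "C", calf = "c1")
  expect_equal(nrow(apply_farm_activity(one)), 0L)
})

test_that("estimate removal keeps exactly the unflagged records", {
  rec <- make_records(age = 1:10, weight = rep(50, 10),
                      estimate = rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(remove_estimates(rec)), 5L)
  all_flagged <- make_records(age = 1:3, weight = rep(50, 3),
                              estimate = TRUE)
  expect_equal(nrow(remove_estimates(all_flagged)), 0L)
  none <- make_records(age = 1:3, weight = rep(50, 3))
  expect_identical(remove_estimates(none), none)
})

test_that("birth records are appended only for calves already present", {
  rec <- make_records(age = c(10, 20, 30), weight = c(50, 55, 60),
                      calf = rep("C1", 3))
  bw <- tibble::tibble(calf_id = c("C1", "C2"), weight_kg = c(41, 39))
  out <- append_birth_records(rec, bw)
  expect_equal(nrow(out), 4L)
  birth <- dplyr::filter(out, is_birth_weight)
  expect_equal(birth$calf_id, "C1")
  expect_equal(birth$age_days, 0L)
  expect_equal(birth$recording_date, birth$birth_date)
  # duplicate birth weights: first kept, message emitted
  dup <- tibble::tibble(calf_id = c("C1", "C1"), weight_kg = c(41, 45))
  expect_message(out2 <- append_birth_records(rec, dup), "duplicate")
  expect_equal(dplyr::filter(out2, is_birth_weight)$weight_kg, 41)
})

test_that("weight bounds are open below and closed above", {
  rec <- make_records(age = 1:4, weight = c(30, 30.1, 225, 225.1))
  expect_setequal(apply_weight_bounds(rec)$weight_kg, c(30.1, 225))
  inside <- make_records(age = 1:3, weight = c(31, 100, 225))
  expect_identical(apply_weight_bounds(inside), inside)
})

test_that("cascade removals match the generator's injected defect tallies", {
  cfg <- flat_config(seed = 21,
    corruption = list(age = 0.10, estimate = 0.06, weight = 0.05,
                      short_window = 0.25))
  sim <- simulate_population(cfg)
  t <- sim$truth$tallies
  expect_equal(t$natural_out_of_range, 0L)
  sel <- run_selection(sim$records, sim$birth_weights)
  n <- sel$report$recordings

  expect_equal(n[1] - n[2], t$age)                    # age window
  expect_equal(n[2] - n[3], t$short_window_records)   # farm activity
  expect_equal(n[3] - n[4], t$estimate)               # estimates
  # birth stage adds one record per confirmed-birth-weight calf surviving
  surviving <- unique(sel$records$calf_id[!sel$records$is_birth_weight])
  expect_equal(n[5] - n[4],
               sum(sim$birth_weights$calf_id %in% surviving))
  expect_equal(n[5] - n[6], t$weight)                 # weight bounds
  # farm count at the activity stage drops by the short-window farms
  expect_equal(sel$report$farms[2] - sel$report$farms[3],
               t$short_window_farms)
})

test_that("clean populations pass the structural filters unchanged", {
  sim <- simulate_population(small_clean_config(seed = 12))
  rec <- sim$records
  expect_identical(apply_age_window(rec), rec)
  expect_identical(apply_farm_activity(rec), rec)
  expect_identical(remove_estimates(rec), rec)
  # the bounds stage removes exactly the naturally out-of-range records
  sel <- run_selection(rec, sim$birth_weights)
  nat_birth <- sum(sim$birth_weights$weight_kg <= 30 |
                   sim$birth_weights$weight_kg > 225)
  removed_at_bounds <- sel$report$recordings[5] - sel$report$recordings[6]
  expect_equal(removed_at_bounds,
               sim$truth$tallies$natural_out_of_range + nat_birth)
})

test_that("the cascade is idempotent and its report self-consistent", {
  cfg <- small_clean_config(seed = 44,
    corruption = list(age = 0.05, estimate = 0.05, short_window = 0.2))
  sim <- simulate_population(cfg)
  sel1 <- run_selection(sim$records, sim$birth_weights)
  # rerunning the full cascade on its own output changes nothing
  sel2 <- run_selection(sel1$records, sim$birth_weights)
  expect_equal(dplyr::arrange(sel2$records, calf_id, age_days),
               dplyr::arrange(sel1$records, calf_id, age_days))
  # counts are non-increasing except at the birth-injection stage
  rep <- sel1$report
  expect_true(all(diff(rep$practices) <= 0))
  expect_true(all(diff(rep$farms) <= 0))
  expect_equal(rep$recordings[nrow(rep)], nrow(sel1$records))
  expect_equal(rep$farms[nrow(rep)],
               dplyr::n_distinct(sel1$records$farm_id))
})

test_that("a single short farm empties the pipeline with zero counts", {
  rec <- make_records(age = c(1, 5, 9), weight = c(40, 45, 50),
                      calf = c("x", "y", "z"))
  sel <- run_selection(rec, NULL)
  expect_equal(nrow(sel$records), 0L)
  last <- sel$report[nrow(sel$report), ]
  expect_equal(unlist(last[c("practices", "farms", "calves", "recordings")]),
               c(practices = 0L, farms = 0L, calves = 0L, recordings = 0L))
})
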