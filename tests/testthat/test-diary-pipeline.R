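test_that("a person-day sums portion-scaled contents per component", {
  db <- toy_db()
  # 100 g white bread: 0.27 g fructose, 1.02 g fructan, 0.20 g GOS
  one <- compute_daily_intake(toy_diary_row(food_id = "white_bread",
                                            amount_g = 100), db)
  expect_equal(one$fructose_g, 0.27)
  expect_equal(one$fructan_g, 1.02)
  expect_equal(one$gos_g, 0.20)
  expect_equal(one$lactose_g, 0)
  expect_false(one$completeness_flag)

  # empty day: all-zero vector
  empty <- compute_daily_intake(toy_diary_row(food_id = "x",
                                              amount_g = 1)[0, ], db)
  expect_equal(empty$total_fodmap_g, 0)
  expect_false(empty$completeness_flag)

  # additivity: two 50 g entries equal one 100 g entry
  twice <- compute_daily_intake(
    toy_diary_row(food_id = rep("white_bread", 2), amount_g = c(50, 50)), db)
  expect_equal(twice$fructan_g, one$fructan_g)
  expect_equal(twice$total_fodmap_g, one$total_fodmap_g)
})

test_that("unresolved foods fail loudly by default and flag in permissive mode", {
  db <- toy_db()
  diary <- tibble::tibble(person_id = "p1", day_index = c(1L, 1L, 2L),
                          food_id = c("white_bread", "mystery_stew", "milk"),
                          amount_g = c(100, 200, 300))
  expect_error(compute_daily_intakes(diary, db), "mystery_stew")
  daily <- compute_daily_intakes(diary, db, permissive = TRUE)
  expect_equal(nrow(daily), 2)
  expect_true(daily$completeness_flag[daily$day_index == 1])
  expect_false(daily$completeness_flag[daily$day_index == 2])
  # the resolved entry of the flagged day still counts
  expect_equal(daily$fructan_g[daily$day_index == 1], 1.02)
})

test_that("day-level excess fructose never exceeds item-level on the same diary", {
  withr::with_seed(53, {
    for (i in 1:10) {
      db <- random_db(15)
      diary <- tibble::tibble(
        person_id = rep(sprintf("p%d", 1:4), each = 6),
        day_index = rep(rep(1:2, each = 3), 4),
        food_id = sample(db$id, 24, replace = TRUE),
        amount_g = runif(24, 20, 300))
      day <- compute_daily_intakes(diary, db, mode = "day_level")
      item <- compute_daily_intakes(diary, db, mode = "item_level")
      expect_true(all(day$excess_fructose_g <= item$excess_fructose_g + 1e-12))
      # the non-excess components agree between modes
      expect_equal(day$fructan_g, item$fructan_g)
    }
  })
})

test_that("person means average recorded days component-wise", {
  db <- toy_db()
  diary <- tibble::tibble(
    person_id = "p1", day_index = c(1L, 2L),
    food_id = "crispbread_rye", amount_g = c(200 / 4.4, 400 / 4.4))
  pm <- person_means(compute_daily_intakes(diary, db))
  expect_equal(pm$fructan_g, 3) # days of 2 g and 4 g
  expect_equal(pm$n_days, 2)

  single <- person_means(compute_daily_intakes(diary[1, ], db))
  expect_equal(single$fructan_g, 2)

  # four days with known values -> hand-computed mean
  diary4 <- tibble::tibble(
    person_id = "p2", day_index = 1:4, food_id = "milk",
    amount_g = c(100, 200, 300, 400))
  pm4 <- person_means(compute_daily_intakes(diary4, db))
  expect_equal(pm4$lactose_g, mean(c(1, 2, 3, 4) * 4.8))

  expect_error(person_means(compute_daily_intakes(diary[0, ], db)),
               "no recorded days")
})

test_that("population summaries use Student-t intervals on person means", {
  pm <- tibble::tibble(person_id = c("a", "b"))
  for (col in c("fructose_g", "glucose_g", "fructan_g", "gos_g",
                "lactose_g", "polyols_g", "excess_fructose_g",
                "total_oligo_g", "total_fodmap_g", "energy_mj")) {
    pm[[col]] <- c(2, 4)
  }
  s <- population_summary(pm)
  fr <- s[s$component == "fructan_g", ]
  expect_equal(fr$mean_g_day, 3)
  # n=2: t(0.975, 1) = 12.7062, sd = sqrt(2), se = 1
  expect_equal(fr$ci_low, 3 - qt(0.975, 1), tolerance = 1e-9)
  expect_equal(fr$ci_high, 3 + qt(0.975, 1), tolerance = 1e-9)

  same <- pm
  same[2, -1] <- as.list(rep(2, 10))
  z <- population_summary(same)
  expect_equal(z$ci_low, z$ci_high) # identical persons: zero-width CI
  expect_error(population_summary(pm[1, ]), "insufficient")

  # concatenating two identical groups leaves the mean unchanged and can
  # only tighten the interval
  pm2 <- dplyr::bind_rows(pm, dplyr::mutate(pm, person_id = c("c", "d")))
  s2 <- population_summary(pm2)
  expect_equal(s2$mean_g_day, s$mean_g_day)
  expect_true(all(s2$ci_high - s2$ci_low <= s$ci_high - s$ci_low))

  # a 117-person synthetic draw puts the estimate's CI around the truth
  study <- generate_study(sim_config(), seed = 5)
  summ <- population_summary(person_means(
    compute_daily_intakes(study$diary, study$db, study$recipes)))
  fr <- summ[summ$component == "fructan_g", ]
  expect_true(fr$ci_low <= study$truth$fructan_g &&
                study$truth$fructan_g <= fr$ci_high)
})

test_that("sample size inverts the confidence half-width", {
  expect_equal(sample_size(1.96, 1.0, 0.196), 100)
  expect_true(sample_size(1.96, 2.5, 0.47) %in% 109:110)
  expect_equal(sample_size(1.96, 3, margin = 1.96 * 3), 1) # unit case
  expect_equal(sample_size(1.96, 2.5, relative_margin = 0.1,
                           expected_mean = 4.7),
               sample_size(1.96, 2.5, 0.47))
  expect_error(sample_size(1.96, 0, 1), "> 0")
  expect_error(sample_size(1.96, 2.5), "supply")
})

test_that("BMR is linear in weight within the configured sex/age band", {
  expect_equal(bmr("female", 40, 65), 0.034 * 65 + 3.538)
  expect_equal(bmr("male", 25, 80), 0.063 * 80 + 2.896)
  expect_equal(bmr("female", 40, 75) - bmr("female", 40, 65), 0.034 * 10)
  expect_error(bmr("female", 40, 0), "weight_kg")
  expect_error(bmr("female", 5, 20), "band") # uncovered age band
})

test_that("the EI:EE screen reproduces ratio arithmetic and flags strictly below cutoff", {
  expect_equal(round(ei_ee_ratio(8.1, 11.2), 2), 0.72)
  expect_equal(ei_ee_ratio(9.3, 9.3), 1)
  expect_equal(ei_ee_ratio(0, 5), 0)
  expect_error(ei_ee_ratio(5, 0), "mean_ee_mj")
  expect_true(underreport_flag(0.72, 0.76))
  expect_false(underreport_flag(1.0, 0.76))
  expect_false(underreport_flag(0.76, 0.76)) # strict inequality
})

test_that("the energy assessment combines BMR, PAL and reported intake per person", {
  pm <- tibble::tibble(person_id = c("a", "b"), energy_mj = c(8, 10))
  persons <- tibble::tibble(person_id = c("a", "b"),
                            sex = c("female", "male"), age = c(40, 25),
                            weight_kg = c(65, 80), pal = c(1.5, NA))
  expect_message(ea <- energy_assessment(pm, persons, pal_default = 1.6),
                 "default PAL")
  expect_equal(ea$per_person$ee_mj[1], (0.034 * 65 + 3.538) * 1.5)
  expect_equal(ea$per_person$ee_mj[2], (0.063 * 80 + 2.896) * 1.6)
  expect_equal(ea$population$ratio_of_means,
               mean(c(8, 10)) / mean(ea$per_person$ee_mj))
  expect_equal(ea$population$n_flagged,
               sum(ea$per_person$ratio < 0.76))
})

test_that("removing dairy zeroes lactose and lowers total FODMAP by exactly its mean", {
  study <- generate_study(small_sim_config(), seed = 7)
  dairy_ids <- study$db$id[study$db$category == "dairy"]
  composite_ids <- unique(study$recipes$composite_id)
  # baseline without composite dishes, so dairy enters only as plain dairy
  # foods (composites may hide dairy ingredients behind their recipes)
  base_diary <- study$diary[!study$diary$food_id %in% composite_ids, ]
  full <- person_means(compute_daily_intakes(base_diary, study$db))
  nodairy_diary <- base_diary[!base_diary$food_id %in% dairy_ids, ]
  # keep the person-day frame comparable: all persons still have entries
  nodairy <- person_means(compute_daily_intakes(nodairy_diary, study$db))
  joined <- dplyr::inner_join(full, nodairy, by = "person_id",
                              suffix = c("", "_nd"))
  # dropped days (all-dairy days) would change denominators; require none
  expect_equal(joined$n_days, joined$n_days_nd)
  expect_true(all(joined$lactose_g_nd == 0))
  expect_equal(joined$total_fodmap_g - joined$total_fodmap_g_nd,
               joined$lactose_g, tolerance = 1e-9)
})
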