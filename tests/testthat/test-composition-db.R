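test_that("dry-to-fresh conversion follows mass balance and round-trips", {
  expect_equal(dry_to_fresh(2.0, 0.5), 1.0)
  expect_equal(dry_to_fresh(3.7, 0.0), 3.7)
  # wheat-flour scale: ~1.49 g/100 g dry at 13% water is ~1.30 g fresh
  expect_equal(dry_to_fresh(1.494, 0.13), 1.30, tolerance = 0.005)

  withr::with_seed(11, {
    v <- runif(50, 0, 10)
    w <- runif(50, 0, 0.99)
    fresh <- dry_to_fresh(v, w)
    expect_true(all(fresh <= v))
    expect_equal(fresh / (1 - w), v) # round trip
    expect_equal(dry_to_fresh(2 * v, w), 2 * fresh) # linear in value
    # monotone decreasing in water fraction
    expect_true(all(dry_to_fresh(1, sort(w)) == sort(dry_to_fresh(1, w),
                                                     decreasing = TRUE)))
  })

  expect_error(dry_to_fresh(1, 1), "water_fraction")
  expect_error(dry_to_fresh(1, -0.1), "water_fraction")
  expect_error(dry_to_fresh(-1, 0.5), "value_dry")
})

test_that("component sums are additive, commutative and guarded", {
  expect_equal(gos_from_components(0.1, 0.3), 0.4)
  expect_equal(gos_from_components(0, 0), 0)
  expect_equal(gos_from_components(0.19, 0), 0.19) # canned-chickpea scale
  expect_equal(polyols_from_components(0.2, 0.1), 0.3)
  expect_equal(polyols_from_components(0, 0.5), 0.5)
  expect_equal(fructan_from_oligomers(c(0.3, 0.2, 0.1)), 0.6)
  expect_equal(fructan_from_oligomers(0.5), 0.5)
  expect_equal(fructan_from_oligomers(0), 0)

  withr::with_seed(7, {
    for (i in 1:20) {
      x <- runif(sample(1:6, 1), 0, 5)
      expect_equal(fructan_from_oligomers(x),
                   fructan_from_oligomers(x[sample(length(x))]))
    }
    a <- runif(10); b <- runif(10)
    expect_equal(gos_from_components(a, b), gos_from_components(b, a))
  })

  expect_error(fructan_from_oligomers(numeric(0)), "at least one")
  expect_error(gos_from_components(-0.1, 0), "raffinose")
  expect_error(polyols_from_components(0, -1), "mannitol")
})

test_that("the loader converts dry-weight rows, sums components and applies precedence", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,category,water_fraction,energy_kj_100g,fructan_g_100g,raffinose_g_100g,stachyose_g_100g,sorbitol_g_100g,mannitol_g_100g,oligomer_gf2_g_100g,oligomer_gf3_g_100g,dry_weight,precedence",
    "rye_flake,rye flake,cereal_grain,0.10,1400,2.0,,,,,,,TRUE,1",
    "lentils,lentils,vegetable_root_legume,0.70,420,,0.1,0.3,,,,,FALSE,1",
    "plum,plum,fruit_berry,0.85,200,,,,0.2,0.1,,,FALSE,1",
    "cereal_bar,cereal bar,cereal_grain,0.12,1600,,,,,,0.3,0.2,FALSE,1",
    "plum,plum,fruit_berry,0.85,210,,,,0.25,,,,FALSE,2"),
    path)
  db <- read_composition_db(path)

  # dry-weight fructan 2.0 at 10% water -> 1.8 fresh, provenance re-tagged
  rye <- db[db$id == "rye_flake", ]
  expect_equal(rye$fructan_g_100g, 1.8)
  expect_equal(rye$fructan_provenance, "dry_weight_converted")

  # raffinose + stachyose -> GOS with component_sum provenance
  len <- db[db$id == "lentils", ]
  expect_equal(len$gos_g_100g, 0.4)
  expect_equal(len$gos_provenance, "component_sum")

  # oligomer columns -> fructan approximation
  bar <- db[db$id == "cereal_bar", ]
  expect_equal(bar$fructan_g_100g, 0.5)
  expect_match(bar$fructan_source, "approximation")

  # duplicate id: higher precedence row wins per value; sorbitol-only row
  # still yields a polyol sum from its own components
  expect_equal(sum(db$id == "plum"), 1)
  expect_equal(db$polyols_g_100g[db$id == "plum"], 0.25)
  expect_equal(db$energy_kj_100g[db$id == "plum"], 210)
})

test_that("the loader accepts tab-delimited decimal-comma input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("id", "name", "category", "water_fraction", "energy_kj_100g",
          "fructan_g_100g", sep = "\t"),
    paste("bread", "bread", "cereal_grain", "0,38", "1100", "1,02",
          sep = "\t")), path)
  db <- read_composition_db(path, decimal_comma = TRUE)
  expect_equal(db$fructan_g_100g, 1.02)
  expect_equal(db$water_fraction, 0.38)
  expect_error(read_composition_db(path, delim = ",", decimal_comma = TRUE),
               "delimiter")
})

test_that("similarity assignment copies values without touching existing ones", {
  db <- toy_db()
  frozen <- tibble::tibble(
    id = "broccoli_frozen", name = "frozen broccoli",
    category = "vegetable_root_legume", water_fraction = 0.9,
    energy_kj_100g = 140)
  db2 <- fodmap_db(dplyr::bind_rows(db, frozen))
  # give the fresh analogue a profile to copy (chickpeas stand in here)
  out <- assign_by_similarity(db2, "broccoli_frozen", "chickpeas_canned")
  tgt <- out[out$id == "broccoli_frozen", ]
  expect_equal(tgt$gos_g_100g, 0.19)
  expect_equal(tgt$gos_provenance, "similarity_assigned")
  expect_match(tgt$gos_source, "chickpeas_canned")

  # pre-existing values are never overwritten
  out2 <- assign_by_similarity(out, "white_bread", "crispbread_rye")
  expect_equal(out2$fructan_g_100g[out2$id == "white_bread"], 1.02)
  expect_equal(out2$fructan_provenance[out2$id == "white_bread"],
               "direct_measurement")

  # empty-profile source is a warning no-op
  expect_warning(out3 <- assign_by_similarity(db2, "broccoli_frozen", "water"),
                 "empty profile")
  expect_identical(out3, db2)

  expect_error(assign_by_similarity(db2, "nope", "milk"), "unknown target")
  expect_error(assign_by_similarity(db2, "milk", "nope"), "unknown source")
})

test_that("similarity assignment only adds values and grows the census by the copy count", {
  withr::with_seed(23, {
    for (i in 1:10) {
      db <- random_db(20)
      ids <- sample(db$id, 2)
      before <- provenance_census(db)
      copied <- sum(vapply(fodmap_groups(), function(g) {
        vc <- paste0(g, "_g_100g")
        !is.na(db[[vc]][db$id == ids[2]]) && is.na(db[[vc]][db$id == ids[1]])
      }, logical(1)))
      src_empty <- all(vapply(fodmap_components(), function(comp) {
        is.na(db[[paste0(comp, "_g_100g")]][db$id == ids[2]])
      }, logical(1)))
      out <- if (src_empty) {
        suppressWarnings(assign_by_similarity(db, ids[1], ids[2]))
      } else {
        assign_by_similarity(db, ids[1], ids[2])
      }
      after <- provenance_census(out)
      expect_equal(after$total_n, before$total_n + copied)
      # no existing amount changed
      for (comp in fodmap_components()) {
        vc <- paste0(comp, "_g_100g")
        keep <- !is.na(db[[vc]])
        expect_identical(out[[vc]][keep], db[[vc]][keep])
      }
    }
  })
})

test_that("the provenance census counts by group and provenance conservatively", {
  # census over a database holding the published per-group value counts
  counts <- c(fructose = 627, fructan = 482, lactose = 328, gos = 205,
              polyols = 163)
  n_direct <- 1350
  rows <- sum(counts)
  items <- tibble::tibble(
    id = sprintf("v%04d", seq_len(rows)),
    name = "x", category = "composite_other",
    water_fraction = 0.5, energy_kj_100g = 100)
  comp_of_row <- rep(names(counts), counts)
  prov_of_row <- rep(c("direct_measurement", "similarity_assigned"),
                     c(n_direct, rows - n_direct))
  for (g in names(counts)) {
    items[[paste0(g, "_g_100g")]] <- ifelse(comp_of_row == g, 1, NA_real_)
    items[[paste0(g, "_provenance")]] <-
      ifelse(comp_of_row == g, prov_of_row, NA_character_)
  }
  census <- provenance_census(fodmap_db(items))
  expect_equal(census$total_n, 1805)
  expect_equal(unname(census$per_fodmap[paste0(names(counts), "_n")]),
               unname(counts))
  expect_equal(census$direct_n, 1350)
  expect_equal(census$direct_share, 75) # 74.79% rounds half-up to 75

  # empty database: zero counts with an explicit flag
  empty <- provenance_census(toy_db()[0, ])
  expect_true(empty$empty)
  expect_equal(empty$total_n, 0)
  expect_equal(empty$direct_share, 0)

  # 3 direct + 1 assigned on a 4-value toy db -> 75%
  toy <- fodmap_db(tibble::tibble(
    id = c("a", "b"), name = c("a", "b"), category = "dairy",
    water_fraction = 0.5, energy_kj_100g = 100,
    fructose_g_100g = c(1, 2), fructan_g_100g = c(1, NA),
    lactose_g_100g = c(1, NA),
    fructose_provenance = c("direct_measurement", "similarity_assigned"),
    fructan_provenance = c("direct_measurement", NA),
    lactose_provenance = c("direct_measurement", NA)))
  expect_equal(provenance_census(toy)$direct_share, 75)
})

test_that("census totals equal the sum of per-group counts on random databases", {
  withr::with_seed(31, {
    for (i in 1:20) {
      db <- random_db(sample(5:60, 1))
      census <- provenance_census(db)
      expect_equal(census$total_n, sum(census$per_fodmap))
      expect_equal(census$total_n, count_census_values(db))
      expect_equal(sum(unlist(census$per_provenance)), census$total_n)
    }
  })
})

test_that("validation reports findings as data, not exceptions", {
  expect_equal(nrow(validate_db(toy_db())), 0)

  bad <- toy_db()
  bad$fructan_g_100g[1] <- -1
  f <- validate_db(bad)
  expect_equal(nrow(f), 1)
  expect_equal(f$level, "error")
  expect_match(f$message, "negative")

  dup <- dplyr::bind_rows(toy_db(), toy_db()[1, ])
  expect_true(any(grepl("duplicate", validate_db(dup)$message)))

  noncarb <- toy_db()
  noncarb$lactose_g_100g[noncarb$id == "beef"] <- 1
  expect_true(any(grepl("non-carbohydrate", validate_db(noncarb)$message)))

  wf <- toy_db()
  wf$water_fraction[2] <- 1.4
  expect_true(any(validate_db(wf)$field == "water_fraction"))

  glc <- toy_db()
  glc$glucose_g_100g[glc$id == "milk"] <- 2
  fg <- validate_db(glc)
  expect_true(any(fg$level == "warning" & fg$field == "glucose_g_100g"))
})
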