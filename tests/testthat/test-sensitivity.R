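# Rigged simulators keep OAT tests fast and their expected values exact: the
# simulator is just a function of the named parameter vector.
rigged_table <- function() {
  tab <- data.frame(
    name = c("a", "b", "c"),
    category = c("meteorology", "behavior", "morphology"),
    min = c(0, 0, 1), max = c(2, 4, 1),
    applies_to = paste0("traits.", c("a", "b", "c")),
    inflatable = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  tab$mean <- (tab$min + tab$max) / 2
  tab[, c("name", "category", "min", "mean", "max", "applies_to", "inflatable")]
}

test_that("the OAT plan is 2P+1 with degenerate parameters folded into baseline", {
  tab5 <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(name = letters[i], category = "behavior", min = 0, mean = 1,
               max = 2, applies_to = paste0("traits.", letters[i]),
               inflatable = TRUE, stringsAsFactors = FALSE)
  }))
  plan <- oat_design(tab5)
  expect_identical(nrow(plan), 11L)

  tab_degen <- rigged_table()  # parameter c has min == mean == max
  plan2 <- oat_design(tab_degen)
  expect_identical(nrow(plan2), 5L)  # baseline + low/high for a and b only

  dir <- withr::local_tempdir()
  path <- file.path(dir, "plan.csv")
  write_oat_plan_csv(plan2, path)
  back <- read_oat_plan_csv(path)
  expect_equal(back$run_id, plan2$run_id)
  expect_equal(back$value, plan2$value)
  expect_equal(attr(back, "params"), attr(plan2, "params"))

  dup <- rbind(tab5, tab5[1, ])
  expect_error(oat_design(dup), "duplicate")
  bad <- tab5; bad$category[1] <- "weather"
  expect_error(oat_design(bad), "category")
})

test_that("importance equals the range of the three means, non-monotone included", {
  tab <- rigged_table()
  lin <- function(values) rep(100 + 5 * values[["a"]], 4)
  res <- run_oat(oat_design(tab), lin)
  expect_equal(res$importance[res$parameter == "a"], 10)  # a in {0,1,2} -> 5x
  expect_equal(res$importance[res$parameter == "b"], 0)
  expect_equal(res$importance[res$parameter == "c"], 0)  # zero span

  # non-monotone response {100, 90, 100} at {min, mean, max}
  vee <- function(values) rep(100 - 10 * (values[["a"]] == 1), 3)
  res2 <- run_oat(oat_design(tab), vee)
  expect_equal(res2$importance[res2$parameter == "a"], 10)

  # order of runs cannot matter: importance is a range, hence non-negative
  expect_true(all(res$importance >= 0))
})

test_that("the baseline run executes exactly once and matches a naive 3P design", {
  tab <- rigged_table()
  counter <- new.env(); counter$baseline <- 0L
  mean_vals <- setNames(tab$mean, tab$name)
  f <- function(values) {
    if (all(values[tab$name] == mean_vals)) counter$baseline <- counter$baseline + 1L
    100 + 5 * values[["a"]] - 2 * values[["b"]]
  }
  res <- run_oat(oat_design(tab), f)
  expect_identical(counter$baseline, 1L)

  naive <- vapply(seq_len(nrow(tab)), function(i) {
    vals <- vapply(c(tab$min[i], tab$mean[i], tab$max[i]), function(v) {
      x <- mean_vals; x[tab$name[i]] <- v; f(x)
    }, numeric(1))
    max(vals) - min(vals)
  }, numeric(1))
  expect_equal(res$importance, naive)
})

test_that("category shares normalize to 100% and recover a known driver", {
  fake <- data.frame(parameter = c("m1", "g1", "b1"),
                     category = c("meteorology", "geography", "behavior"),
                     importance = c(30, 20, 10), stringsAsFactors = FALSE)
  att <- category_attribution(fake)
  expect_equal(sum(att$share_pct), 100, tolerance = 1e-9)
  expect_equal(att$share_pct[att$category == "meteorology"], 50)
  expect_equal(att$share_pct[att$category == "geography"], 100 * 20 / 60)
  expect_equal(att$share_pct[att$category == "behavior"], 100 * 10 / 60)

  # a single nonzero parameter takes 100% and all others 0%
  tab <- rigged_table()
  only_a <- function(values) 100 + 3 * values[["a"]]
  res <- run_oat(oat_design(tab), only_a)
  att2 <- category_attribution(res)
  expect_equal(att2$share_pct[att2$category == "meteorology"], 100)
  expect_true(all(att2$share_pct[att2$category != "meteorology"] == 0))
  expect_equal(res$share_pct[res$parameter == "a"], 100)

  # all-missing responses are flagged, not silently zeroed
  dead <- function(values) rep(NA_real_, 3)
  res3 <- run_oat(oat_design(tab), dead)
  expect_true(all(res3$flagged))
  expect_true(all(is.na(res3$importance)))
  expect_error(category_attribution(res3), "finite")
})

test_that("trait-range inflation widens about the mean with overrides and clipping", {
  tab <- default_parameter_table()
  # explicit override: favorable hours 1-24 h inflated to 1-96 h
  infl <- inflate_trait_ranges(tab, list(favorable_consecutive_hours = c(1, 96)))
  row <- infl[infl$name == "favorable_consecutive_hours", ]
  expect_equal(c(row$min, row$max), c(1, 96))

  # factor 1 is the identity
  expect_equal(inflate_trait_ranges(tab, 1), tab)

  # mass 7.6-15.6 g about mean 11.6 at factor 2 -> 3.6-19.6 g
  infl2 <- inflate_trait_ranges(tab, 2)
  m <- infl2[infl2$name == "mass", ]
  expect_equal(c(m$min, m$max), c(3.6, 19.6))
  expect_equal(m$mean, 11.6)
  # exogenous rows untouched by the scalar factor
  expect_equal(infl2[!infl2$inflatable, ], tab[!tab$inflatable, ])
  # clipping keeps non-negative parameters physical
  infl8 <- inflate_trait_ranges(tab, 8)
  expect_gte(min(infl8$min[infl8$name == "mass"]), 0)

  expect_error(inflate_trait_ranges(tab, list(temp_offset = c(-4, 4))),
               "not inflatable")
  expect_error(inflate_trait_ranges(tab, list(mass = c(5, 2))), "min <= max")
})

test_that("microclimate sensitivity passes offsets through additively and rejects traits", {
  exo <- default_parameter_table()
  exo <- exo[exo$category %in% c("meteorology", "geography"), ]
  sim <- oat_simulator(exo, weather_config(seed = 14), n_years = 4,
                       response = "microclimate")
  ms <- microclimate_sensitivity(exo, sim)
  # a +/-2 C offset moves every hourly temperature by the same amount
  off <- ms[ms$parameter == "temp_offset", ]
  expect_equal(off$air_min, 4, tolerance = 1e-9)
  expect_equal(off$air_max, 4, tolerance = 1e-9)
  # canopy damping acts on the warm tail more than the cold tail
  can <- ms[ms$parameter == "canopy_cover", ]
  expect_gt(can$air_max, can$air_min)
  # a zero-span parameter has zero importance everywhere
  zero <- exo; zero$min <- zero$mean; zero$max <- zero$mean
  ms0 <- microclimate_sensitivity(zero, sim)
  expect_true(all(as.matrix(ms0[, c("air_min", "air_max", "soil_min", "soil_max")]) == 0))

  expect_error(microclimate_sensitivity(default_parameter_table(), sim),
               "meteorological and geographical")
})
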