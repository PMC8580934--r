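make_study <- function(dice, volume = rep(10, length(dice)),
                       set = rep("inter_1", length(dice)),
                       type = rep("osteolytic", length(dice))) {
  out <- tibble::tibble(
    femur_id = sprintf("F%02d", seq_along(dice)), lesion_type = type,
    kind = ifelse(grepl("^inter", set), "inter", "intra"), set = set,
    dice = dice, volume_a = volume, volume_b = volume,
    volume_intersection = dice * volume, non_overlap_volume = 2 * volume * (1 - dice),
    mean_volume = volume
  )
  class(out) <- c("segrel_study", class(out))
  out
}

test_that("per-type summaries use sample mean and SD", {
  s <- make_study(c(0.4, 0.8))
  out <- summarize_by_type(s)
  expect_equal(out$dice_mean, 0.6)
  expect_equal(out$dice_sd, sqrt(((0.4 - 0.6)^2 + (0.8 - 0.6)^2) / 1))
  expect_equal(out$dice_sd, 0.2828427, tolerance = 1e-6)

  # all equal -> SD 0; single observation -> SD absent (NA), not zero
  expect_equal(summarize_by_type(make_study(c(0.6, 0.6, 0.6)))$dice_sd, 0)
  one <- summarize_by_type(make_study(0.5))
  expect_identical(one$n, 1L)
  expect_true(is.na(one$dice_sd))

  # absent (set x type) cells yield no row rather than a zero row
  s2 <- make_study(c(0.5, 0.7), type = c("osteolytic", "mixed"))
  expect_identical(nrow(summarize_by_type(s2)), 2L)
})

test_that("overall mean DC equals the n-weighted mean of per-type means", {
  withr::local_seed(5)
  dice <- runif(54)
  type <- rep(c("osteolytic", "osteoblastic", "mixed"), c(19, 17, 18))
  s <- make_study(dice, type = type)
  per_type <- summarize_by_type(s)
  overall <- summarize_overall(s)
  expect_equal(pool_group_means(per_type$dice_mean, per_type$n),
               overall$dice_mean)
  expect_identical(sum(per_type$n), 54L)
  expect_equal(overall$dice_sd, sd(dice))
})

test_that("good_dc_fraction uses a strict threshold", {
  expect_equal(good_dc_fraction(c(0.8, 0.6)), 0.5)
  expect_equal(good_dc_fraction(rep(0.9, 5)), 1.0)
  expect_equal(good_dc_fraction(0.7), 0.0)  # exactly at threshold: not good
  expect_equal(good_dc_fraction(c(0.5, 0.9), threshold = 0.5), 0.5)
  expect_error(good_dc_fraction(numeric(0)), "no Dice")
})

test_that("size stratification is strict with at-threshold rows going small", {
  s <- make_study(c(0.8, 0.4, 0.6), volume = c(61, 59, 60))
  out <- split_by_size(s, size_threshold = 60)
  large <- out[out$size_stratum == "large", ]
  small <- out[out$size_stratum == "small", ]
  expect_identical(large$n, 1L)
  expect_identical(small$n, 2L)  # the exactly-60 row is in the lower stratum
  expect_equal(large$dice_mean, 0.8)
  expect_equal(small$dice_mean, 0.5)
  expect_equal(large$good_dc_fraction, 1.0)
  expect_equal(small$good_dc_fraction, 0.0)

  # strict-threshold consistency with good_dc_fraction's convention
  expect_equal(small$good_dc_fraction, good_dc_fraction(c(0.4, 0.6)))

  # empty stratum is absent, and inter/intra are pooled separately
  s2 <- make_study(c(0.5, 0.9), volume = c(10, 20),
                   set = c("inter_1", "intra_I"))
  out2 <- split_by_size(s2)
  expect_identical(nrow(out2), 2L)
  expect_setequal(out2$kind, c("inter", "intra"))
  expect_true(all(out2$size_stratum == "small"))
})

test_that("reports compile, print, glance and round-trip through JSON", {
  withr::local_seed(8)
  dice <- runif(24)
  type <- rep(c("osteolytic", "osteoblastic", "mixed"), each = 2, times = 4)
  set <- rep(c("inter_1", "inter_2", "intra_I", "intra_II"), each = 6)
  s <- make_study(dice, volume = runif(24, 1, 100), set = set, type = type)
  rep_ <- compile_report(s)
  expect_s3_class(rep_, "segrel_report")
  g <- glance(rep_)
  expect_identical(g$n_comparisons, 24L)
  expect_equal(g$dice_inter_1,
               rep_$overall$dice_mean[rep_$overall$set == "inter_1"])

  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c("per_femur.csv", "per_type.csv",
                                               "overall.csv", "per_size.csv",
                                               "tests.csv", "report.json")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  # full-precision copy round-trips losslessly
  expect_equal(js$full$overall$dice_mean, rep_$overall$dice_mean)
  expect_equal(js$rounded$overall$dice_mean, round(rep_$overall$dice_mean, 2))
  per_type_csv <- readr::read_csv(file.path(dir, "per_type.csv"),
                                  show_col_types = FALSE)
  expect_identical(nrow(per_type_csv), nrow(rep_$per_type))
})
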