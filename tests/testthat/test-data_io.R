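test_that("reading a toy long-format file builds a validated cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,sex,age_years,stature_cm",
    "a,F,8.0,125.2", "a,F,9.1,130.9",
    "b,M,8.5,127.0", "b,M,9.6,133.3"
  ), f)
  co <- suppressMessages(read_long_csv(f))
  expect_s3_class(co, "growth_cohort")
  expect_equal(nrow(co), 4)
  expect_equal(sort(unique(co$id)), c("a", "b"))
  expect_equal(unname(table(co$id)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("column maps and sex recodings are applied on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child,gender,agedec,ht", "x,0,7.5,120", "x,0,8.5,126"), f)
  co <- suppressMessages(read_long_csv(
    f,
    column_map = list(id = "child", sex = "gender", age = "agedec", stature = "ht"),
    sex_codes = c("0" = "F", "1" = "M")
  ))
  expect_equal(unique(co$sex), "F")
})

test_that("malformed files are rejected with named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age_years", "a,F,8.0"), f)
  expect_error(suppressMessages(read_long_csv(f)), class = "sitargrowth_format_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age_years,stature_cm", "a,F,8.0,125", "a,F,oops,130"), f2)
  expect_error(suppressMessages(read_long_csv(f2)),
               regexp = "row 2", class = "sitargrowth_parse_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age_years,stature_cm",
               "a,F,8.0,125", "a,F,8.0,126"), f3)
  expect_error(suppressMessages(read_long_csv(f3)),
               regexp = "duplicate", class = "sitargrowth_validation_error")
})

test_that("cohort invariants reject out-of-range values and mixed sex", {
  base <- data.frame(id = "a", sex = "F", age = 8, stature = 125)
  expect_error(growth_cohort(transform(base, age = 31)),
               class = "sitargrowth_validation_error")
  expect_error(growth_cohort(transform(base, stature = 45)),
               class = "sitargrowth_validation_error")
  expect_error(growth_cohort(transform(base, stature = NA_real_)),
               class = "sitargrowth_parse_error")
  two <- rbind(base, data.frame(id = "a", sex = "M", age = 9, stature = 130))
  expect_error(growth_cohort(two), class = "sitargrowth_validation_error")
})

test_that("write/read round-trip preserves every value to full precision", {
  co <- small_sim()$cohort
  f <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(co, f)
  back <- suppressMessages(read_long_csv(f))
  expect_identical(back$id, co$id)
  expect_identical(back$sex, co$sex)
  expect_equal(back$age, co$age, tolerance = 0)
  expect_equal(back$stature, co$stature, tolerance = 0)
})

test_that("inclusion rules match their definitions on hand-built subjects", {
  girl3 <- data.frame(id = "g", sex = "F",
                      age = c(7, 10.5, 11.5, 12.5), stature = c(118, 135, 141, 148))
  # entry at 7, only 3 measurements inside [9.9, 14], last below 14
  expect_warning(res <- apply_inclusion_filter(growth_cohort(girl3)),
                 "excluded every subject")
  expect_false(res$report$rule_a)
  expect_equal(nrow(res$cohort), 0)

  boy <- data.frame(id = "b", sex = "M",
                    age = c(8.0, 11.0, 11.8, 12.7, 13.5, 14.2, 14.9, 16.1),
                    stature = c(124, 140, 144, 149, 155, 162, 168, 174))
  res2 <- suppressWarnings(apply_inclusion_filter(growth_cohort(boy)))
  expect_true(all(unlist(res2$report[, c("rule_a", "rule_b", "rule_c")])))
  expect_equal(nrow(res2$cohort), 8)
})

test_that("filtering agrees with a brute-force re-check and is idempotent", {
  sim <- simulate_cohort(girls_curve(),
                         generator_config(n_subjects = 100, sex = "F", seed = 77))
  co <- sim$cohort
  crit <- inclusion_criteria()
  res <- apply_inclusion_filter(co, crit)
  # independent subject-by-subject evaluation of the three rules
  expected <- vapply(unique(co$id), function(i) {
    a <- co$age[co$id == i]
    sum(a >= 9.9 & a <= 14.0) >= 4 && min(a) >= 6 && min(a) <= 9.9 && max(a) >= 14.0
  }, logical(1))
  expect_equal(length(unique(res$cohort$id)), sum(expected))
  expect_setequal(unique(res$cohort$id), names(expected)[expected])
  # idempotent, and surviving rows untouched
  twice <- apply_inclusion_filter(res$cohort, crit)
  expect_identical(twice$cohort, res$cohort)
  kept <- co[co$id %in% res$cohort$id, ]
  expect_equal(res$cohort$stature, kept$stature)
})

test_that("measurement count table partitions the cohort", {
  toy <- growth_cohort(data.frame(
    id = rep(c("a", "b", "c"), c(4, 4, 7)),
    sex = rep(c("F", "F", "M"), c(4, 4, 7)),
    age = c(7:10, 7:10, 7:13) + 0.5,
    stature = 100 + seq_len(15) * 2
  ))
  tab <- measurement_count_table(toy)
  expect_equal(tab$count, c(4, 7))
  expect_equal(tab$all, c(2L, 1L))
  expect_equal(sum(tab$all), 3)
  # on a generated cohort: column sums equal subject counts, counts in 4..11
  co <- small_sim()$cohort
  tab2 <- measurement_count_table(co)
  expect_equal(sum(tab2$all), length(unique(co$id)))
  expect_equal(tab2$all, tab2$F + tab2$M)
  expect_true(all(tab2$count >= 4 & tab2$count <= 11))
})
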