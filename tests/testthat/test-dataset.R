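test_that("reader partitions rows by EVID and counts match the file", {
  path <- toy_csv()
  co <- read_pk_data(path)
  expect_s3_class(co, "pk_cohort")
  expect_equal(n_subjects(co), 2)
  expect_equal(sum(co$data$EVID == 1), 6)
  expect_equal(n_observations(co), 4)
  subj <- cohort_subjects(co)
  expect_equal(nrow(subj$A$doses), 3)
  expect_equal(nrow(subj$A$obs), 2)
  expect_equal(subj$B$aaa, 1)
})

test_that("missing mandatory columns are reported by name", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ID = c("A", "A")), path, row.names = FALSE)
  expect_error(read_pk_data(path), "TIME")
  expect_error(read_pk_data(path), "DV")
})

test_that("write/read round trip preserves all data values", {
  co <- toy_cohort()
  path <- tempfile(fileext = ".csv")
  write_pk_data(co, path)
  back <- read_pk_data(path)
  expect_equal(back$data[names(toy_data())], co$data[names(toy_data())])
  ## a second round trip is byte-identical at the file level
  path2 <- tempfile(fileext = ".csv")
  write_pk_data(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("row validation rejects malformed records with line numbers", {
  d <- toy_data()
  d$TIME[4] <- -1
  expect_error(pk_cohort(d), "line 5")
  d <- toy_data()
  d$AMT[1] <- 0
  expect_error(pk_cohort(d), "AMT > 0")
  d <- toy_data()
  d$EVID[2] <- 2
  expect_error(pk_cohort(d), "EVID")
  ## subject with observations but no dose
  d <- toy_data()
  d <- d[!(d$ID == "B" & d$EVID == 1), ]
  expect_error(pk_cohort(d), "no dose")
})

test_that("column remapping and the hours-only time unit contract work", {
  d <- toy_data()
  names(d)[names(d) == "DV"] <- "CONC"
  path <- toy_csv(d)
  co <- read_pk_data(path, columns = c(DV = "CONC"))
  expect_equal(n_observations(co), 4)
  cfg <- tempfile(fileext = ".json")
  writeLines('{"time_unit": "days"}', cfg)
  expect_error(read_pk_data(path, config = cfg), "hours")
})

test_that("imputation fills per-subject means, then the grand mean", {
  d <- toy_data()
  d$ALB <- c(3.0, NA, 4.0, NA, NA,  NA, NA, NA, NA, NA)
  was_na <- is.na(pk_cohort(d)$data$ALB)
  co <- impute_covariates(pk_cohort(d))
  a <- co$data$ID == "A"
  expect_true(all(co$data$ALB[a & was_na] == 3.5))
  expect_setequal(co$data$ALB[a & !was_na], c(3.0, 4.0))
  ## subject B has no albumin: gets the mean of the other subjects' means
  expect_true(all(co$data$ALB[co$data$ID == "B"] == 3.5))
  expect_true(co$meta$covariates_complete)
  ## per-subject covariates collapse to the imputed constant
  expect_equal(cohort_subjects(co)$A$alb, mean(c(3.0, 3.5, 3.5, 3.5, 4.0)))
})

test_that("imputation is idempotent and never alters observed values", {
  d <- toy_data()
  d$ALB[2] <- NA
  co1 <- impute_covariates(pk_cohort(d))
  co2 <- impute_covariates(co1)
  expect_equal(co1$data, co2$data)
  expect_equal(co1$data$ALB[1], 3.5)   # untouched observed value
})

test_that("imputation with a covariate missing everywhere is an error", {
  d <- toy_data()
  d$ALB <- NA
  expect_error(impute_covariates(pk_cohort(d)), "nothing to impute")
})

test_that("hold_out_last flags exactly the chronologically last trough", {
  co <- hold_out_last(toy_cohort())
  held <- co$data[co$data$HELD, ]
  expect_equal(nrow(held), n_subjects(co))
  expect_equal(held$TIME, c(671, 671))
  ## per subject it is the maximum observation time
  for (s in cohort_subjects(co)) {
    expect_equal(s$obs$time[s$obs$held_out], max(s$obs$time))
  }
})

test_that("hold_out_last enforces the two-trough inclusion criterion", {
  d <- toy_data()[-5, ]   # subject A left with one observation
  expect_error(hold_out_last(pk_cohort(d)), "fewer than 2")
})

test_that("writing a cohort with duplicate subject ids is rejected", {
  co <- toy_cohort()
  ## corrupt: two separate row blocks end up under the same id
  co$data <- rbind(co$data, transform(co$data[co$data$ID == "A", ],
                                      TIME = TIME + 5000))
  expect_error(write_pk_data(co, tempfile()), "duplicate")
})
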