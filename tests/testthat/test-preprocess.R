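test_that("well-formed CSVs round-trip through read_monitoring", {
  tbl <- toy_monitoring(10)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  got <- read_monitoring(path)
  expect_equal(nrow(got), 10)
  expect_equal(got$CHLA, tbl$CHLA)
})

test_that("physical-range violations are reported with their row", {
  tbl <- toy_monitoring(8)
  tbl$TP[5] <- -0.01
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  expect_error(read_monitoring(path), "TP at row 5",
               class = "bloomregime_input_error")
})

test_that("comma decimal separators raise a parse error, not a misread", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,WT,EC,TN,TP,Q,CHLA",
               "2015-01-01,12.5,400,3.8,0.03,120,25.0",
               "2015-01-02,\"13,2\",401,3.8,0.03,118,24.0"), path)
  expect_error(read_monitoring(path), "line 3",
               class = "bloomregime_parse_error")
})

test_that("rows with missing fields are dropped with a message; empty tables error", {
  tbl <- toy_monitoring(6)
  tbl$EC[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  expect_message(got <- read_monitoring(path), "1 row")
  expect_equal(nrow(got), 5)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("date,WT,EC,TN,TP,Q,CHLA", empty)
  expect_error(read_monitoring(empty), class = "bloomregime_input_error")

  bad_hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,temp,EC,TN,TP,Q,CHLA", "2015-01-01,1,2,3,4,5,6"), bad_hdr)
  expect_error(read_monitoring(bad_hdr), class = "bloomregime_parse_error")
})

test_that("min-max normalizer stores extrema and maps them to 0 and 1", {
  tbl <- toy_monitoring(12)
  tbl$WT <- seq(2.9, 33.6, length.out = 12)
  spec <- fit_normalizer(tbl, c("WT", "Q"))
  expect_equal(spec$min[spec$variable == "WT"], 2.9)
  expect_equal(spec$max[spec$variable == "WT"], 33.6)

  norm <- apply_normalizer(spec, tbl)
  expect_equal(min(norm$WT), 0)
  expect_equal(max(norm$WT), 1)

  # direct arithmetic on the station's WT summary values
  x <- apply_normalizer(spec, tibble::tibble(WT = 17.6), "WT")
  expect_equal(x$WT, (17.6 - 2.9) / (33.6 - 2.9))
  expect_equal(x$WT, 0.47882736156, tolerance = 1e-10)
})

test_that("values beyond the fitted range are not clipped and round-trip exactly", {
  tbl <- toy_monitoring(10)
  spec <- fit_normalizer(tbl, c("WT", "CHLA"))
  below <- apply_normalizer(spec, tibble::tibble(WT = 1), "WT")
  expect_lt(below$WT, 0)

  x <- c(-3.7, 0.2, 55.1)
  norm <- apply_normalizer(spec, tibble::tibble(CHLA = x), "CHLA")
  expect_equal(denormalize(spec, norm$CHLA, "CHLA"), x, tolerance = 1e-12)

  expect_error(apply_normalizer(spec, tbl, "TP"),
               class = "bloomregime_contract_error")
  expect_error(denormalize(spec, 0.5, "TP"),
               class = "bloomregime_contract_error")
})

test_that("constant columns are rejected as degenerate scales", {
  tbl <- toy_monitoring(10)
  tbl$TN <- 3.8
  expect_error(fit_normalizer(tbl, c("WT", "TN")),
               class = "bloomregime_degenerate_scale_error")
})

test_that("normalization is affine and order-preserving", {
  tbl <- toy_monitoring(25)
  spec <- fit_normalizer(tbl)
  for (v in c("WT", "EC", "TN", "TP", "Q", "CHLA")) {
    x <- sort(stats::runif(50, min(tbl[[v]]) - 1, max(tbl[[v]]) + 1))
    y <- apply_normalizer(spec, tibble::as_tibble(setNames(list(x), v)), v)[[v]]
    expect_false(is.unsorted(y))
    slopes <- diff(y) / diff(x)
    expect_equal(slopes, rep(slopes[1], length(slopes)), tolerance = 1e-9)
  }
})

test_that("the 70/30 split has the stated sizes and is a seeded partition", {
  big <- toy_monitoring(12)[rep(1:12, length.out = 1031), ]
  big$date <- as.Date("2013-01-01") + seq_len(1031) - 1
  split <- split_train_test(big, seed = 5)
  expect_length(split$train, 721)
  expect_length(split$test, 310)

  expect_identical(split_train_test(big, seed = 5), split)
  expect_false(identical(split_train_test(big, seed = 6)$train, split$train))

  small <- split_train_test(toy_monitoring(10), seed = 1)
  expect_length(small$train, 7)
  expect_length(small$test, 3)

  for (seed in 1:5) {
    n <- 10 + seed * 13
    tbl <- toy_monitoring(12)[rep(1:12, length.out = n), ]
    s <- split_train_test(tbl, seed = seed)
    expect_setequal(c(s$train, s$test), seq_len(n))
    expect_length(intersect(s$train, s$test), 0)
  }

  expect_error(split_train_test(toy_monitoring(9), seed = 1),
               class = "bloomregime_input_error")
})
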