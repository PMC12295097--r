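test_that("panel construction enforces structural invariants", {
  m <- matrix(runif(12, 100, 200), 3, 4)
  p <- region_year_panel(m, 2000:2003, c("A", "B", "C"))
  expect_s3_class(p, "region_year_panel")
  expect_identical(p$years, 2000:2003)

  expect_error(region_year_panel(m, c(2000, 2001, 2003, 2004), c("A", "B", "C")),
               class = "fpca_structural_error")
  expect_error(region_year_panel(m[, 1:3], 2000:2002, c("A", "B", "C")),
               class = "fpca_structural_error")           # T < 4
  expect_error(region_year_panel(m[1, , drop = FALSE], 2000:2003, "A"),
               class = "fpca_structural_error")           # R < 2
  m2 <- m; m2[2, 2] <- -5
  expect_error(region_year_panel(m2, 2000:2003, c("A", "B", "C")),
               class = "fpca_value_error")
  expect_error(region_year_panel(m, 2000:2003, c("A", "A", "C")),
               class = "fpca_value_error")
})

test_that("read/write round-trips both layouts and cross-layout", {
  for (seed in 1:3) {
    p <- tiny_panel(R = 3, T_ = 5, seed = seed)
    for (layout in c("wide", "long")) {
      f <- tempfile(fileext = ".csv")
      write_panel(p, f, layout)
      q <- read_panel(f, layout)
      expect_equal(q$counts, p$counts, tolerance = 1e-12)
      expect_identical(q$years, p$years)
      expect_identical(q$regions, p$regions)
    }
    # write long, reread, rewrite wide: same panel
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    write_panel(p, f1, "long")
    write_panel(read_panel(f1, "long"), f2, "wide")
    expect_equal(read_panel(f2, "wide")$counts, p$counts, tolerance = 1e-12)
  }
  # a full-size generated panel survives the round trip too
  p16 <- generate_panel(synthetic_spec(seed = 4))$panel
  f <- tempfile(fileext = ".csv")
  write_panel(p16, f, "wide")
  expect_equal(read_panel(f, "wide")$counts, p16$counts, tolerance = 1e-12)
})

test_that("malformed CSV inputs are rejected with typed errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("year,A,B", "2000,1,2", "2001,3,4", "2003,5,6", "2004,7,8"), f)
  expect_error(read_panel(f, "wide"), class = "fpca_structural_error")
  writeLines(c("region,year,count", "A,2000,1", "A,2000,2"), f)
  expect_error(read_panel(f, "long"), class = "fpca_value_error")
  writeLines(c("region,year,count", "A,2000,100"), f)
  expect_error(read_panel(f, "long"), class = "fpca_error")  # grid too small
  expect_error(read_panel(tempfile(), "wide"), class = "fpca_value_error")
})

test_that("region ranking assigns codes by decreasing baseline, stable on ties", {
  expect_identical(rank_and_encode_regions(c("A", "B", "C"), c(10, 30, 20)),
                   c(A = 3L, B = 1L, C = 2L))
  expect_identical(rank_and_encode_regions("X", 7), c(X = 1L))
  expect_identical(rank_and_encode_regions(c("p", "q"), c(5, 5)),
                   c(p = 1L, q = 2L))
  # stable-sort oracle over all permutations of a 4-element list with a tie
  vals <- c(4, 9, 9, 2)
  nms <- c("a", "b", "c", "d")
  for (perm in list(1:4, 4:1, c(2, 1, 4, 3), c(3, 2, 4, 1), c(2, 3, 1, 4))) {
    v <- vals[perm]; nm <- nms[perm]
    codes <- rank_and_encode_regions(nm, v)
    # oracle: enumerate ranks via repeated max with first-occurrence tie-break
    remaining <- seq_along(v); oracle <- integer(length(v))
    for (code in seq_along(v)) {
      pick <- remaining[which.max(v[remaining])]
      oracle[pick] <- code
      remaining <- setdiff(remaining, pick)
    }
    expect_identical(unname(codes), oracle)
  }
  expect_error(rank_and_encode_regions(c("a", "a"), c(1, 2)),
               class = "fpca_value_error")
})

test_that("corrections interpolate linearly, override cells, and touch nothing else", {
  p <- tiny_panel(R = 3, T_ = 6, seed = 2, start_year = 2017)
  p$counts["R2", c("2018", "2021")] <- c(100, 160)
  p <- region_year_panel(p$counts, p$years, p$regions)

  rule <- correction_rule("R2", "linear_interpolation", c(2018, 2021))
  q <- apply_corrections(p, list(rule))
  expect_equal(unname(q$counts["R2", c("2019", "2020")]), c(120, 140))
  # untouched cells are bit-identical
  mask <- matrix(TRUE, 3, 6, dimnames = dimnames(p$counts))
  mask["R2", c("2019", "2020")] <- FALSE
  expect_identical(q$counts[mask], p$counts[mask])
  # idempotent: interior already on the line
  expect_identical(apply_corrections(q, list(rule))$counts, q$counts)

  ov <- correction_rule("R1", "manual_override", 2019, override_value = 2090)
  p2 <- p; p2$counts["R1", "2019"] <- 1834
  p2 <- region_year_panel(p2$counts, p2$years, p2$regions)
  q2 <- apply_corrections(p2, list(ov))
  expect_equal(unname(q2$counts["R1", "2019"]), 2090)
  expect_identical(apply_corrections(q2, list(ov))$counts, q2$counts)

  expect_identical(apply_corrections(p, list())$counts, p$counts)
  expect_error(apply_corrections(p, list(correction_rule("R9", "manual_override",
                                                         2019, 5))),
               class = "fpca_value_error")
  expect_error(apply_corrections(p, list(correction_rule("R1", "linear_interpolation",
                                                         c(2016, 2019)))),
               class = "fpca_value_error")
  expect_error(correction_rule("R1", "manual_override", 2019, override_value = -1),
               class = "fpca_value_error")
})

test_that("correction rules round-trip through YAML and JSON files", {
  rules <- list(
    list(region_code = "R2", kind = "linear_interpolation",
         anchor_years = c(2018, 2021)),
    list(region_code = "R1", kind = "manual_override", anchor_years = 2019,
         override_value = 2090))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rules, fy)
  got <- read_corrections(fy)
  expect_length(got, 2)
  expect_s3_class(got[[1]], "correction_rule")
  expect_identical(got[[2]]$override_value, 2090)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(rules, fj, auto_unbox = TRUE)
  expect_identical(read_corrections(fj)[[1]]$anchor_years, c(2018L, 2021L))
})
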