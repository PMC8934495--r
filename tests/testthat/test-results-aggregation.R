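test_that("percent change uses round-half-away-from-zero", {
  expect_equal(percent_change(36.6, 118), 222)
  expect_equal(percent_change(213.6, 58.6), -73)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(100, 111.5), 12)   # 11.5 rounds away from zero
  expect_equal(percent_change(100, 88.5), -12)   # -11.5 rounds away from zero
  expect_error(percent_change(0, 10), "positive")
  expect_error(percent_change(-3, 10), "positive")
})

test_that("group peak forces sum element peaks, not the peak of the sum", {
  forces <- cbind(e1 = c(10, 40, 5), e2 = c(30, 8, 6))
  groups <- c(e1 = "g", e2 = "g")
  expect_equal(peak_group_force(forces, groups, "g"), 70)
  expect_equal(peak_group_force(forces, groups, "g", reducer = "peak_of_sum"),
               48)
  expect_gte(peak_group_force(forces, groups, "g"),
             peak_group_force(forces, groups, "g", reducer = "peak_of_sum"))
  # single element: its own peak; constant series: the constant
  expect_equal(peak_group_force(cbind(e1 = c(1, 7, 3)), c(e1 = "g"), "g"), 7)
  expect_equal(peak_group_force(cbind(e1 = rep(4, 5)), c(e1 = "g"), "g"), 4)
  expect_error(peak_group_force(forces, groups, "nope"), "no elements")

  expect_equal(group_activation(c(100, 200), c(100, 200)), 1)
  expect_equal(group_activation(c(0, 0), c(100, 200)), 0)
  expect_error(group_activation(1, 0), "positive")
})

test_that("the packaged fixture is checksummed and carries the printed values", {
  tab <- load_table1_fixture()
  expect_s3_class(tab, "peak_table")
  pick <- function(model, motion, row, col) {
    tab[tab$model == model & tab$motion == motion & tab$row == row, col]
  }
  expect_equal(pick("NS", "ABD", "anterior_deltoid", "force_N"), 136.3)
  expect_equal(pick("NS", "ABD", "anterior_deltoid", "activation"), 0.27)
  expect_equal(pick("DBSP", "ABD", "JRF", "force_N"), 957.5)
  # supraspinatus rows are absent for the prosthesis models
  expect_equal(nrow(tab[tab$model == "RSP" & tab$row == "supraspinatus", ]), 0)
  expect_equal(nrow(tab[tab$model == "NS" & tab$row == "supraspinatus", ]), 4)

  # tampering breaks the checksum
  tmp <- tempfile(fileext = ".csv")
  src <- system.file("extdata", "table1_peaks.csv", package = "shouldersim")
  writeLines(c(readLines(src), "ZZ"), tmp)
  expect_false(unname(tools::md5sum(tmp)) == unname(tools::md5sum(src)))
})

test_that("every printed percent-change cell is recomputed exactly", {
  tab <- load_table1_fixture()
  cells <- tab[tab$model != "NS" & !is.na(tab$pct_change) & tab$asserted, ]
  expect_gt(nrow(cells), 50)
  for (i in seq_len(nrow(cells))) {
    ns <- tab$force_N[tab$model == "NS" & tab$motion == cells$motion[i] &
                        tab$row == cells$row[i]]
    expect_equal(percent_change(ns, cells$force_N[i]), cells$pct_change[i],
                 label = sprintf("%s %s %s", cells$model[i], cells$motion[i],
                                 cells$row[i]))
  }
  # the comparison_table operation reproduces the same cells
  cmp <- comparison_table(tab)
  merged <- merge(cells, cmp, by = c("model", "motion", "row"))
  expect_equal(merged$percent_change_from_ns, merged$pct_change)
})

test_that("deltoid and rotator cuff aggregates match the printed sums", {
  tab <- load_table1_fixture()
  ns_abd <- aggregate_muscle_groups(tab[tab$model == "NS" &
                                          tab$motion == "ABD", ])
  expect_equal(ns_abd$deltoid_total, 136.3 + 292.4 + 330)
  db_abd <- aggregate_muscle_groups(tab[tab$model == "DBSP" &
                                          tab$motion == "ABD", ])
  expect_equal(db_abd$rotator_cuff_total, 130.2 + 68.9 + 58.6)
  # missing mandatory subgroup errors; missing supraspinatus contributes 0
  broken <- tab[tab$model == "NS" & tab$motion == "ABD" &
                  tab$row != "middle_deltoid", ]
  expect_error(aggregate_muscle_groups(broken), "middle_deltoid")
})

test_that("headline comparisons reproduce the study-level percentages", {
  tab <- load_table1_fixture()
  hc <- headline_comparisons(tab)
  g <- function(qn, model, motion) {
    hc$percent_change_from_ns[hc$quantity == qn & hc$model == model &
                                hc$motion == motion]
  }
  # dual-bearing vs natural, deltoid group: -18 ABD, +3 SCP, +52 IR, +64 ER
  expect_equal(g("deltoid_total", "DBSP", "ABD"), -18)
  expect_equal(g("deltoid_total", "DBSP", "SCP"), 3)
  expect_equal(g("deltoid_total", "DBSP", "IR"), 52)
  expect_equal(g("deltoid_total", "DBSP", "ER"), 64)
  # rotator cuff: -36 ABD, +1 SCP, -27 in both rotations
  expect_equal(g("rotator_cuff_total", "DBSP", "ABD"), -36)
  expect_equal(g("rotator_cuff_total", "DBSP", "SCP"), 1)
  expect_equal(g("rotator_cuff_total", "DBSP", "IR"), -27)
  expect_equal(g("rotator_cuff_total", "DBSP", "ER"), -27)
  # joint reaction forces vs natural
  expect_equal(g("JRF", "RSP", "ABD"), 8)
  expect_equal(g("JRF", "DBSP", "ABD"), -9)
  expect_equal(g("JRF", "RSP", "SCP"), 14)
  expect_equal(g("JRF", "RSP", "IR"), 13)
  expect_equal(g("JRF", "DBSP", "IR"), 14)
  expect_equal(g("JRF", "RSP", "ER"), 20)
  expect_equal(g("JRF", "DBSP", "ER"), 26)
})

test_that("group force/activation ratios are mutually consistent in the fixture", {
  # infraspinatus: force/activation across the three models in internal
  # rotation all imply the same group capacity within the 2-decimal
  # activation rounding band
  tab <- load_table1_fixture()
  sub <- tab[tab$row == "infraspinatus" & tab$motion == "IR", ]
  lo <- max(sub$force_N / (sub$activation + 0.005))
  hi <- min(sub$force_N / (sub$activation - 0.005))
  expect_lt(lo, hi)
  expect_gt(lo, 1300)  # ~1.4 kN group capacity
  expect_lt(hi, 1600)
})
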