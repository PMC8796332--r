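test_that("available working time follows the leave arithmetic", {
  expect_equal(compute_awt(leave_policy(300, 0, 0, 0, 0, 8)), 2400)
  expect_equal(compute_awt(leave_policy(313, 12, 10, 17, 10, 8)), 2112)
  expect_equal(compute_awt(leave_policy()), 2112)  # package default
  expect_error(compute_awt(leave_policy(100, 100, 0, 0, 0, 8)), "AWT")
})

test_that("standard workload converts minutes per unit into units per year", {
  expect_equal(compute_standard_workload(2000, 10), 12000)
  expect_equal(compute_standard_workload(2000, 60), 2000)
  expect_equal(compute_standard_workload(2112, 15), 8448)
  expect_error(compute_standard_workload(0, 10))
  expect_error(compute_standard_workload(2000, -1))
})

test_that("health-service requirement sums workload over standard workload", {
  # one service at exactly the standard workload -> one staff member
  expect_equal(compute_hsa_requirement(c(visits = 12000), c(visits = 10), 2000), 1)
  # two services each needing 0.75 staff are additive
  expect_equal(
    compute_hsa_requirement(c(a = 9000, b = 1500), c(a = 10, b = 60), 2000),
    1.5)
  expect_equal(compute_hsa_requirement(c(a = 0, b = 0), c(a = 10, b = 60), 2000), 0)
  expect_error(
    compute_hsa_requirement(c(a = 100, mystery = 5), c(a = 10), 2000),
    "mystery")
})

test_that("category allowance factor inflates for support-activity shares", {
  expect_equal(compute_caf(c(0.1, 0.1)), list(total_cas_pct = 20, caf = 1.25))
  expect_equal(compute_caf(numeric(0))$caf, 1)
  expect_equal(compute_caf(0.5)$caf, 2)
  expect_error(compute_caf(c(0.6, 0.4)), "all working time")
})

test_that("individual allowance factor is total IAS hours over AWT", {
  expect_equal(compute_iaf(240, 2, awt = 2400),
               list(total_ias_hours = 480, iaf = 0.2))
  expect_equal(compute_iaf(numeric(0), awt = 2400)$iaf, 0)
  expect_equal(compute_iaf(2400, 1, awt = 2400)$iaf, 1)
  expect_error(compute_iaf(-5, 1, awt = 2400))
})

test_that("WISN combines HSA, CAF and IAF with the configured rounding", {
  expect_equal(compute_wisn(2, 1.25, 0.5),
               list(wisn_raw = 3, wisn_rounded = 3L))
  expect_equal(compute_wisn(0, 1, 0)$wisn_rounded, 0L)
  expect_equal(compute_wisn(1, 1, 0.45)$wisn_rounded, 1L)
  expect_equal(compute_wisn(1, 1, 0.45, rounding = "ceiling")$wisn_rounded, 2L)
  expect_equal(compute_wisn(1, 1, 0.5)$wisn_rounded, 2L)   # half-up at .5
  expect_equal(round_half_up(14.5), 15)
})

test_that("facility composition equals the single-expression oracle", {
  panel <- random_panel(200, seed = 42)
  res <- wisn_panel(panel, default_standards())
  awt <- compute_awt(leave_policy())
  for (i in seq_len(nrow(panel))) {
    expect_equal(res$wisn_raw[i], oracle_wisn_row(panel[i, ], default_standards(), awt),
                 tolerance = 1e-12)
  }
})

test_that("raw WISN is monotone in volumes, shares and additional times", {
  base <- tiny_record(volume = 10000, cas = 0.2, ias_hours = 200, ias_staff = 2)
  std <- tiny_standards()
  w0 <- wisn_panel(base, std)$wisn_raw
  up_vol <- base; up_vol$svc_visits <- 12000
  up_cas <- base; up_cas$cas_support <- 0.3
  up_ias <- base; up_ias$ias_extra_hours <- 300
  expect_gt(wisn_panel(up_vol, std)$wisn_raw, w0)
  expect_gt(wisn_panel(up_cas, std)$wisn_raw, w0)
  expect_gt(wisn_panel(up_ias, std)$wisn_raw, w0)
})

test_that("doubling all volumes doubles raw WISN when allowances are zero", {
  r1 <- tiny_record(volume = 8000, cas = 0, ias_hours = 0)
  r2 <- tiny_record(volume = 16000, cas = 0, ias_hours = 0)
  std <- tiny_standards()
  expect_equal(wisn_panel(r2, std)$wisn_raw, 2 * wisn_panel(r1, std)$wisn_raw)
})

test_that("support time accepted as annual hours matches the share form", {
  awt <- compute_awt(leave_policy())
  frac <- tiny_record(volume = 10000, cas = 0.25)
  hrs <- frac; hrs$cas_support <- 0.25 * awt
  std <- tiny_standards()
  expect_equal(wisn_panel(hrs, std, cas_unit = "hours")$wisn_raw,
               wisn_panel(frac, std)$wisn_raw)
})

test_that("exclusion filters flag each reason with the stated precedence", {
  std <- tiny_standards()
  panel <- rbind(
    tiny_record(volume = 10000, ias_hours = 100, facility_id = "keep_doc"),
    tiny_record(volume = 10000, ias_hours = 100, cadre = "nurses",
                facility_id = "keep_nurse"),
    tiny_record(volume = 0, ias_hours = 0, facility_id = "null_wisn"),
    tiny_record(volume = 10000, ias_hours = 0, cadre = "nurses",
                facility_id = "nurse_no_ias"),
    tiny_record(volume = 10000, ias_hours = 100, weekly_hours = 20,
                facility_id = "partial"),
    # partial workweek beats the null-WISN reason
    tiny_record(volume = 0, ias_hours = 0, weekly_hours = 10,
                facility_id = "partial_and_null")
  )
  std_nurse <- rbind(std, within(tiny_standards(), cadre <- "nurses"))
  res <- apply_exclusions(wisn_panel(panel, std_nurse))
  reason <- setNames(res$exclusion_reason, res$facility_id)
  expect_equal(unname(reason[c("keep_doc", "keep_nurse")]), rep("none", 2))
  expect_equal(unname(reason["null_wisn"]), "null_wisn")
  expect_equal(unname(reason["nurse_no_ias"]), "null_iaf_nurse")
  expect_equal(unname(reason["partial"]), "under_half_workweek")
  expect_equal(unname(reason["partial_and_null"]), "under_half_workweek")
  expect_identical(res$excluded, res$exclusion_reason != "none")
  # a doctor record with zero IAS is retained (nurse-only rule)
  doc_no_ias <- apply_exclusions(wisn_panel(
    tiny_record(volume = 10000, ias_hours = 0), std))
  expect_false(doc_no_ias$excluded)
})

test_that("the null-WISN rule can be switched to the raw value", {
  # raw 0.4 rounds to 0: excluded under the rounded rule, kept under raw
  rec <- tiny_record(volume = 1000, cas = 0, ias_hours = 0)
  std <- tiny_standards(unit_time_min = 2112 * 60 / 2500)  # SW 2500 -> HSA 0.4
  res <- wisn_panel(rec, std)
  expect_equal(res$wisn_rounded, 0L)
  expect_true(apply_exclusions(res)$excluded)
  expect_false(apply_exclusions(res, null_rule = "raw")$excluded)
})
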