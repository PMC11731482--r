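test_that("medication-use inference follows the active-order rule", {
  sent <- function(yr, drug = "ezetimibe")
    data.frame(id = "s", medication = drug, status = "Sent", year = yr)
  disc <- function(yr, drug = "ezetimibe")
    data.frame(id = "s", medication = drug, status = "Discontinued",
               year = yr)

  # order sent at -5, never discontinued: active from -5 on
  expect_equal(infer_medication_use(sent(-5), -10:0),
               c(rep(FALSE, 5), rep(TRUE, 6)))

  # no orders at all
  empty <- data.frame(id = character(), medication = character(),
                      status = character(), year = integer())
  expect_equal(infer_medication_use(empty, -10:0), rep(FALSE, 11))

  # discontinued at -3 but replaced the same year: active -6..0
  orders <- rbind(sent(-6), disc(-3), sent(-3, "gemfibrozil"))
  expect_equal(infer_medication_use(orders, -10:0),
               c(rep(FALSE, 4), rep(TRUE, 7)))

  # discontinued without replacement: inactive strictly after the
  # discontinuation year
  orders2 <- rbind(sent(-6), disc(-3))
  expect_equal(infer_medication_use(orders2, c(-4, -3, -2)),
               c(TRUE, TRUE, FALSE))

  # insensitive to row permutation
  perm <- orders[c(3, 1, 2), ]
  expect_equal(infer_medication_use(perm, -10:0),
               infer_medication_use(orders, -10:0))

  bad <- data.frame(id = "s", medication = "x", status = "Pending",
                    year = 0)
  expect_error(infer_medication_use(bad, 0), "unknown medication-order")
})

test_that("lipid derivation applies Friedewald with its validity bound", {
  d <- derive_lipids(200, 50, 100)
  expect_equal(d$ldl, 130)
  expect_equal(d$non_hdl, 150)
  expect_equal(d$ln_tg, log(100))

  # TG above 400 mg/dl: LDL missing, non-HDL still derived
  d2 <- derive_lipids(200, 50, 500)
  expect_true(is.na(d2$ldl))
  expect_equal(d2$non_hdl, 150)

  # recorded LDL takes precedence over Friedewald
  d3 <- derive_lipids(200, 50, 100, ldl_recorded = 128)
  expect_equal(d3$ldl, 128)

  # HDL >= TC flags the record invalid
  expect_false(derive_lipids(150, 160, 100)$valid)
  expect_error(derive_lipids(-1, 50, 100), "positive")

  # non_hdl + hdl = tc exactly on random panels
  set.seed(1)
  tc <- runif(50, 120, 300); hdl <- runif(50, 30, 90)
  dd <- derive_lipids(tc, hdl, runif(50, 50, 350))
  expect_equal(dd$non_hdl + hdl, tc)
})

test_that("comorbidity flags match the ICD prefix lists", {
  f <- comorbidity_flags("I10")
  expect_true(f[["hypertension"]])
  expect_false(any(f[setdiff(names(f), "hypertension")]))

  expect_false(any(comorbidity_flags(character())))

  # I25 appears in both the atherosclerosis and ischemic-heart lists
  f2 <- comorbidity_flags(c("E11.9", "I25.1"))
  expect_true(f2[["diabetes"]])
  expect_true(f2[["atherosclerosis"]])
  expect_true(f2[["ihd_mi"]])
  expect_false(f2[["hypertension"]])

  # range membership: ICD-9 neoplasm block and dotted codes
  expect_true(comorbidity_flags("174.9")[["malignancy"]])
  expect_true(comorbidity_flags("C50.9")[["malignancy"]])
  expect_false(comorbidity_flags("Z99")[["malignancy"]])
})

test_that("inclusion filter requires three distinct measured years", {
  m <- data.frame(id = c("a", "a", "a", "b", "b", "b", "c", "c"),
                  rel_year = c(-9, -5, 0, -2, -2, -2, -9, -5))
  keep <- apply_inclusion_filter(m)
  expect_equal(sort(keep), "a")   # b: one distinct year; c: two years

  # monotone: adding a measurement never removes eligibility
  m2 <- rbind(m, data.frame(id = "c", rel_year = -1))
  expect_true(all(keep %in% apply_inclusion_filter(m2)))
  expect_true("c" %in% apply_inclusion_filter(m2))

  # years outside the window do not count
  m3 <- data.frame(id = "d", rel_year = c(-12, -11, -5, -4, 0))
  expect_equal(apply_inclusion_filter(m3), "d")
  m4 <- data.frame(id = "e", rel_year = c(-13, -12, -11))
  expect_length(apply_inclusion_filter(m4), 0)
})

test_that("annual aggregation averages duplicates before transformation", {
  m <- data.frame(id = "a", rel_year = -2,
                  lipid = c("tc", "tc", "hdl", "tg"),
                  value = c(190, 210, 50, 100),
                  on_med = c(FALSE, TRUE, FALSE, FALSE))
  ann <- aggregate_annual(m)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$tc, 200)
  expect_equal(ann$non_hdl, 150)
  expect_equal(ann$ln_tg, log(100))
  expect_true(ann$on_med)   # any measurement on medication flags the year

  # averaging commutes with the non-HDL derivation when HDL is constant
  set.seed(2)
  tcs <- runif(20, 150, 250)
  m2 <- data.frame(id = "a", rel_year = 0, lipid = "tc", value = tcs,
                   on_med = FALSE)
  m2 <- rbind(m2, data.frame(id = "a", rel_year = 0, lipid = "hdl",
                             value = 55, on_med = FALSE),
              data.frame(id = "a", rel_year = 0, lipid = "tg",
                         value = 120, on_med = FALSE))
  expect_equal(aggregate_annual(m2)$non_hdl, mean(tcs) - 55)
})

test_that("score standardization yields mean 0 and sample SD 1", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  z <- standardize_scores(rnorm(100, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)
  expect_error(standardize_scores(rep(2, 10)), "constant")
})
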