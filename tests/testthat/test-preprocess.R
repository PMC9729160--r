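test_that("mULN conversion and log transform follow their definitions", {
  expect_equal(to_mULN(0.5, uln = 0.5), 1.0)
  expect_equal(to_mULN(2.5, uln = 0.5), 5.0)
  expect_equal(to_mULN(0, uln = 3), 0.0)
  expect_error(to_mULN(1, uln = 0), "uln")
  expect_error(to_mULN(-1, uln = 1), "raw_level")

  expect_equal(log_level(1), 0)
  expect_equal(log_level(exp(1)), 1)
  expect_equal(log_level(0, floor = 0.01), log(0.01))
  # monotone nondecreasing in mULN, floor included
  x <- sort(c(0, 0.005, 0.01, runif(50, 0, 10)))
  expect_true(all(diff(log_level(x)) >= 0))
})

test_that("seroconversion detection returns the first confirmed pair", {
  expect_equal(detect_seroconversion_antibody(c(0.5, 2.0, 3.0)), c(2L, 3L))
  # an isolated positive does not qualify; first consecutive pair wins
  expect_equal(detect_seroconversion_antibody(c(2.0, 0.5, 2.0, 2.0, 0.4)), c(3L, 4L))
  expect_null(detect_seroconversion_antibody(c(0.9, 0.9, 0.9)))
  expect_null(detect_seroconversion_antibody(c(2.0)))
  # threshold is strict: exactly 1 mULN is not positive
  expect_null(detect_seroconversion_antibody(c(1.0, 1.0)))
  # NA counts as not positive
  expect_null(detect_seroconversion_antibody(c(2.0, NA, 2.0)))
})

test_that("detection matches a brute-force scan and is prefix-stable", {
  withr::local_seed(421)
  for (rep in 1:2000) {
    lv <- round(runif(sample(2:12, 1), 0, 2.2), 2)
    got <- detect_seroconversion_antibody(lv)
    want <- oracle_detect(lv)
    expect_identical(got, want)
    if (!is.null(got)) {
      # visits appended after the confirmatory visit never change the pair
      lv2 <- c(lv[seq_len(got[2])], round(runif(3, 0, 2.2), 2))
      expect_identical(detect_seroconversion_antibody(lv2), got)
    }
  }
})

test_that("child-level record anchors at the earliest confirmatory visit", {
  child <- data.frame(child_id = "K", diagnosis_age_years = NA_real_,
                      last_followup_age_years = 10)
  # IAA confirms at (1.4, 1.5), GADA at (1.2, 1.4): GADA wins since 1.4 < 1.5
  visits <- data.frame(
    age_years = c(1.0, 1.2, 1.4, 1.5),
    iaa_mULN = c(0.3, 0.4, 1.8, 1.7),
    gada_mULN = c(0.5, 2.0, 2.2, 0.4),
    ia2a_mULN = c(0.1, 0.2, 0.3, 0.4))
  rec <- build_seroconversion_record(child, visits)
  expect_equal(rec$antibody, "GADA")
  expect_equal(rec$age_initial, 1.2)
  expect_equal(rec$age_confirm, 1.4)
  # all three antibodies' levels carried at both anchor visits
  expect_equal(rec$iaa_mULN_init, 0.4)
  expect_equal(rec$ia2a_mULN_conf, 0.3)
  expect_false(rec$pos_iaa_init)
  expect_true(rec$pos_iaa_conf)
  expect_true(rec$pos_gada_init)

  # single candidate antibody
  v2 <- data.frame(age_years = c(1, 2), iaa_mULN = c(0.2, 0.3),
                   gada_mULN = c(1.5, 1.5), ia2a_mULN = c(0.1, 0.1))
  expect_equal(build_seroconversion_record(child, v2)$antibody, "GADA")

  # diagnosed before any confirmed pair -> excluded
  child_dx <- transform(child, diagnosis_age_years = 1.3)
  expect_null(build_seroconversion_record(child_dx, visits))

  # missing level at an anchor visit -> excluded
  v3 <- visits; v3$ia2a_mULN[3] <- NA
  expect_null(build_seroconversion_record(child, v3))
})

test_that("ties on confirmatory age break by initial age then antibody order", {
  child <- data.frame(child_id = "K", diagnosis_age_years = NA_real_,
                      last_followup_age_years = 10)
  # GADA confirms (1.0, 2.0), IA-2A confirms (1.5, 2.0): GADA earlier initial
  v <- data.frame(age_years = c(1.0, 1.5, 2.0),
                  iaa_mULN = c(0.1, 0.1, 0.1),
                  gada_mULN = c(1.5, 1.6, 1.7),
                  ia2a_mULN = c(0.2, 1.4, 1.6))
  expect_equal(build_seroconversion_record(child, v)$antibody, "GADA")
  # identical pairs for IAA and GADA: fixed order picks IAA
  v2 <- data.frame(age_years = c(1.0, 2.0),
                   iaa_mULN = c(1.5, 1.5), gada_mULN = c(1.5, 1.5),
                   ia2a_mULN = c(0.1, 0.1))
  expect_equal(build_seroconversion_record(child, v2)$antibody, "IAA")
})

test_that("cohort-level records exclude never-confirmed children", {
  toy <- toy_cohort()
  sc <- seroconversion_records(toy$children, toy$visits)
  expect_equal(sort(sc$child_id), c("A", "B"))
  expect_equal(sc$antibody[sc$child_id == "A"], "IAA")
  expect_equal(sc$antibody[sc$child_id == "B"], "GADA")
  # remove child A's confirmatory visit: A drops out
  v <- toy$visits[-3, ]
  sc2 <- seroconversion_records(toy$children, v)
  expect_equal(sc2$child_id, "B")
  # empty input: zero-row frame with the full schema
  sc0 <- seroconversion_records(toy$children[0, ], toy$visits[0, ])
  expect_equal(nrow(sc0), 0)
  expect_true(all(c("antibody", "age_confirm", "pos_iaa_conf") %in% names(sc0)))
})
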