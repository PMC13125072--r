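# The six worked initial sensor facts (body temp 38 C, HR 90, BOS 80,
# blood sugar 85, ECG 0.9, BP 120/80) must all evaluate non-alert under the
# reference profile.
worked_record <- function() {
  one_record(body_temp_c = 38, heart_rate = 90, spo2 = 80, blood_sugar = 85,
             ecg = 0.9, systolic_bp = 120, diastolic_bp = 80)
}

test_that("all worked initial facts evaluate to Normal with no Tell messages", {
  st <- evaluate_vitals(worked_record())
  expect_setequal(st$vital, c("body_temp", "heart_rate", "spo2", "blood_sugar",
                              "ecg", "bp"))
  expect_true(all(st$level == "Normal"))
  expect_equal(st$rule[st$vital == "body_temp"], "R11")
  expect_equal(st$rule[st$vital == "heart_rate"], "R15")
  expect_equal(st$rule[st$vital == "ecg"], "R23")
  expect_equal(st$rule[st$vital == "bp"], "R27")
  expect_equal(nrow(tell_messages(st)), 0)
})

test_that("boundary values fire the inclusive extreme rules", {
  cases <- tibble::tribble(
    ~record,                                        ~vital,       ~level, ~rule,
    one_record(heart_rate = 100),                   "heart_rate", "High", "R12",
    one_record(heart_rate = 60),                    "heart_rate", "Low",  "R14",
    one_record(body_temp_c = 39),                   "body_temp",  "High", "R7",
    one_record(body_temp_c = 37),                   "body_temp",  "Low",  "R9",
    one_record(spo2 = 90),                          "spo2",       "High", "R4",
    one_record(blood_sugar = 150),                  "blood_sugar","High", "R16",
    one_record(ecg = 1.2),                          "ecg",        "High", "R20",
    one_record(ecg = 0.6),                          "ecg",        "Low",  "R22",
    one_record(room_temp_c = 35),                   "room_temp",  "High", "R2",
    one_record(room_temp_c = 15),                   "room_temp",  "Low",  "R3"
  )
  for (i in seq_len(nrow(cases))) {
    st <- evaluate_vitals(cases$record[[i]])
    expect_equal(st$level, cases$level[i], label = cases$rule[i])
    expect_equal(st$rule, cases$rule[i])
  }
})

test_that("Fahrenheit temperatures are converted before threshold comparison", {
  st <- evaluate_vitals(one_record(body_temp_f = 102.2))  # 39 C
  expect_equal(st$level, "High")
  st2 <- evaluate_vitals(one_record(body_temp_f = 100.4))  # 38 C
  expect_equal(st2$level, "Normal")
})

test_that("index-scale ECG values are mapped through the configured divisor", {
  thr <- threshold_profile("reference", ecg_divisor = 100)
  st <- evaluate_vitals(one_record(ecg_index = 90), thr)
  expect_equal(st$level, "Normal")
  st2 <- evaluate_vitals(one_record(ecg_index = 125), thr)
  expect_equal(st2$level, "High")
})

test_that("compound blood pressure: either component triggers, High wins", {
  expect_equal(evaluate_vitals(one_record(systolic_bp = 150, diastolic_bp = 80))$level, "High")
  expect_equal(evaluate_vitals(one_record(systolic_bp = 120, diastolic_bp = 100))$level, "High")
  expect_equal(evaluate_vitals(one_record(systolic_bp = 95, diastolic_bp = 70))$level, "Low")
  expect_equal(evaluate_vitals(one_record(systolic_bp = 120, diastolic_bp = 55))$level, "Low")
  # systolic low and diastolic high simultaneously: High precedence
  expect_equal(evaluate_vitals(one_record(systolic_bp = 95, diastolic_bp = 105))$level, "High")
})

test_that("the status partition covers every input exactly once", {
  # sweep a grid across and beyond each vital's cutoffs
  grid <- seq(-50, 400, by = 0.5)
  for (v in c("heart_rate", "blood_sugar", "spo2", "room_temp_c")) {
    rec <- tibble::tibble(patient_id = as.character(seq_along(grid)),
                          tick = 0L, !!v := grid)
    st <- evaluate_vitals(rec)
    expect_equal(nrow(st), length(grid))
    expect_true(all(st$level %in% c("High", "Low", "Normal")))
  }
})

test_that("Tell messages exist iff the generating status is non-Normal with a Tell rule", {
  rec <- one_record(heart_rate = 120, body_temp_c = 36, spo2 = 95,
                    blood_sugar = 40, ecg = 1.5, systolic_bp = 150,
                    diastolic_bp = 80, room_temp_c = 40)
  st <- evaluate_vitals(rec)
  tells <- tell_messages(st)
  # High HR, hypothermia, high BOS, abnormal ECG, high BP all Tell;
  # low blood sugar (R18) and room temperature (R2/R3) have no Tell clause.
  expect_setequal(tells$predicate,
                  c("High_Heart_Rate", "Has_Hypothermia", "Current_BOS_Level",
                    "Abnormal_ECG", "High_Blood_Pressure"))
  expect_false(any(tells$predicate %in% c("Low_Blood_Sugar", "Room_Temperature_Status")))
  # no tells at all from an all-Normal record
  expect_equal(nrow(tell_messages(evaluate_vitals(worked_record()))), 0)
})

test_that("the clinical profile flags desaturation instead of high BOS", {
  clin <- threshold_profile("clinical")
  st_low <- evaluate_vitals(one_record(spo2 = 85), clin)
  expect_equal(st_low$level, "Low")
  expect_equal(nrow(tell_messages(st_low, clin)), 1)
  st_high <- evaluate_vitals(one_record(spo2 = 98), clin)
  expect_equal(st_high$level, "Normal")
  # same reading under the reference profile is a High alert
  expect_equal(evaluate_vitals(one_record(spo2 = 98))$level, "High")
})

test_that("threshold profiles round-trip through YAML with identical output", {
  thr <- threshold_profile("clinical", ecg_divisor = 100)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_threshold_profile(thr, path)
  thr2 <- read_threshold_profile(path)
  rec <- small_cohort(n_patients = 6, records = 4, missing_rate = 0)
  expect_identical(evaluate_vitals(rec, thr), evaluate_vitals(rec, thr2))
})

test_that("the fire sensor relays unconditionally and validates its level", {
  for (lvl in c("High", "Low", "No_Risk")) {
    msg <- evaluate_fire(lvl, tick = 3L)
    expect_equal(msg$predicate, "Current_Fire_Level")
    expect_equal(msg$level, lvl)
    expect_equal(msg$rule, "R28")
  }
  expect_error(evaluate_fire("Medium"), "level")
})

test_that("unknown vital columns are ignored with a warning", {
  rec <- one_record(heart_rate = 80, shoe_size = 42)
  expect_warning(st <- evaluate_vitals(rec), "shoe_size")
  expect_equal(st$vital, "heart_rate")
})
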