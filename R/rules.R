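#' Threshold profiles for the sensor-agent rules
#'
#' Builds the per-vital High/Low cutoff table used by [evaluate_vitals()].
#' The `"reference"` profile encodes the canonical sensor-agent rule
#' table: room temperature high at 35 / low at 15 degrees C, blood oxygen
#' saturation flagged *High* at >= 90 (and never Low), fever at >= 39 C with
#' hypothermia at <= 37 C, heart rate high at >= 100 / low at <= 60 bpm,
#' blood sugar high at >= 150 / low at <= 70 mg/dL, ECG abnormal at >= 1.2 /
#' low at <= 0.6 on the ratio scale, and compound blood pressure high at
#' 145/100 with low at 100/60 mmHg. The `"clinical"` profile differs only for
#' blood oxygen saturation, flagging SpO2 <= 90 as a *Low* alert (desaturation
#' is the clinically actionable direction) instead of the high-saturation
#' rule.
#'
#' Each vital's rule identifiers (e.g. `R12` for high heart rate) ride along
#' so derived statuses can cite the rule that fired. Cutoffs are inclusive at
#' the extremes: a value equal to the high cutoff is High, equal to the low
#' cutoff is Low, and Normal means strictly between.
#'
#' @param name `"reference"` (default) or `"clinical"`.
#' @param ecg_divisor Divisor applied to incoming ECG values before comparing
#'   against the ratio-scale cutoffs; use 100 for index-scale data
#'   (80-120 range), 1 (default) for ratio-scale data (0.6-1.2 range).
#' @return A `vw_thresholds` object: a list with the profile `name`, the
#'   per-vital cutoff tibble `vitals`, the compound blood-pressure cutoffs
#'   `bp`, and `ecg_divisor`.
#' @export
threshold_profile <- function(name = c("reference", "clinical"),
                              ecg_divisor = 1) {
  name <- match.arg(name)
  vitals <- tibble::tribble(
    ~vital,        ~low, ~high, ~unit,    ~rule_low, ~rule_high, ~rule_normal,
    ~predicate_low,      ~predicate_high,     ~tell_low, ~tell_high,
    "room_temp",    15,   35,   "degC",   "R3",      "R2",       NA,
    "Room_Temperature_Status", "Room_Temperature_Status", FALSE, FALSE,
    "spo2",         NA,   90,   "%",      NA,        "R4",       NA,
    NA,                  "Current_BOS_Level", FALSE,     TRUE,
    "body_temp",    37,   39,   "degC",   "R9",      "R7",       "R11",
    "Has_Hypothermia",   "Has_Fever",         TRUE,      TRUE,
    "heart_rate",   60,   100,  "bpm",    "R14",     "R12",      "R15",
    "Low_Heart_Rate",    "High_Heart_Rate",   FALSE,     TRUE,
    "blood_sugar",  70,   150,  "mg/dL",  "R18",     "R16",      "R19",
    "Low_Blood_Sugar",   "High_Blood_Sugar",  FALSE,     TRUE,
    "ecg",          0.6,  1.2,  "ratio",  "R22",     "R20",      "R23",
    "Low_Abnormal_ECG",  "Abnormal_ECG",      FALSE,     TRUE,
    "bp",           NA,   NA,   "mmHg",   "R26",     "R24",      "R27",
    "Low_Blood_Pressure", "High_Blood_Pressure", FALSE,   TRUE
  )
  if (name == "clinical") {
    i <- vitals$vital == "spo2"
    vitals$low[i] <- 90
    vitals$high[i] <- NA
    vitals$rule_low[i] <- "R4c"
    vitals$rule_high[i] <- NA
    vitals$predicate_low[i] <- "Current_BOS_Level"
    vitals$predicate_high[i] <- NA
    vitals$tell_low[i] <- TRUE
    vitals$tell_high[i] <- FALSE
  }
  bad <- !is.na(vitals$low) & !is.na(vitals$high) & vitals$low >= vitals$high
  if (any(bad)) abort("low cutoff must be below high cutoff for every vital")
  structure(
    list(name = name, vitals = vitals,
         bp = list(high_sys = 145, high_dia = 100, low_sys = 100, low_dia = 60),
         ecg_divisor = ecg_divisor),
    class = "vw_thresholds"
  )
}

#' @export
print.vw_thresholds <- function(x, ...) {
  cat(sprintf("<vw_thresholds: profile `%s`, %d vitals, ecg_divisor %g>\n",
              x$name, nrow(x$vitals), x$ecg_divisor))
  invisible(x)
}

#' Serialize and reload a threshold profile
#'
#' Round-trips a [threshold_profile()] through YAML so deployments can pin
#' and audit the exact cutoffs in use; reloading yields bit-identical
#' evaluation output.
#'
#' @param thresholds A `vw_thresholds` object.
#' @param path File path.
#' @export
write_threshold_profile <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "vw_thresholds"))
  obj <- list(
    name = thresholds$name,
    ecg_divisor = thresholds$ecg_divisor,
    bp = thresholds$bp,
    vitals = lapply(seq_len(nrow(thresholds$vitals)), function(i) {
      row <- as.list(thresholds$vitals[i, ])
      lapply(row, function(v) if (is.na(v)) NULL else v)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_threshold_profile
#' @export
read_threshold_profile <- function(path) {
  obj <- yaml::read_yaml(path)
  template <- threshold_profile()$vitals[0, ]
  vitals <- purrr::map_dfr(obj$vitals, function(row) {
    filled <- purrr::map(names(template), ~ row[[.x]] %||%
                           vector(class(template[[.x]]), 1)[NA])
    names(filled) <- names(template)
    tibble::as_tibble(filled)
  })
  structure(
    list(name = obj$name, vitals = vitals, bp = obj$bp,
         ecg_divisor = obj$ecg_divisor),
    class = "vw_thresholds"
  )
}

# Map record columns onto the profile's vital names, converting units.
# Returns a long tibble: patient_id, tick, vital, value (in threshold units).
collect_vital_values <- function(records, thresholds) {
  records <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(records)) records$patient_id <- seq_len(nrow(records))
  if (!"tick" %in% names(records)) records$tick <- 0L
  meta <- c("patient_id", "tick", "label", "severity",
            grep("_missing$", names(records), value = TRUE))
  col <- function(d, nm) if (nm %in% names(d)) d[[nm]] else NULL
  value_of <- list(
    heart_rate = function(d) col(d, "heart_rate"),
    blood_sugar = function(d) col(d, "blood_sugar"),
    spo2 = function(d) col(d, "spo2"),
    room_temp = function(d) col(d, "room_temp_c") %||% col(d, "room_temp"),
    body_temp = function(d) {
      c_val <- col(d, "body_temp_c")
      f_val <- col(d, "body_temp_f")
      if (!is.null(c_val)) c_val
      else if (!is.null(f_val)) (f_val - 32) * 5 / 9
      else NULL
    },
    ecg = function(d) {
      v <- col(d, "ecg_index") %||% col(d, "ecg")
      if (is.null(v)) NULL else v / thresholds$ecg_divisor
    }
  )
  known_cols <- c(meta, "heart_rate", "blood_sugar", "spo2", "room_temp",
                  "room_temp_c", "body_temp_c", "body_temp_f", "ecg",
                  "ecg_index", "systolic_bp", "diastolic_bp")
  unknown <- setdiff(names(records), known_cols)
  if (length(unknown)) {
    warn(sprintf("ignoring unrecognized vital column(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  long <- purrr::imap_dfr(value_of, function(f, vital) {
    v <- f(records)
    if (is.null(v)) return(NULL)
    tibble::tibble(patient_id = records$patient_id, tick = records$tick,
                   vital = vital, value = as.numeric(v))
  })
  if (all(c("systolic_bp", "diastolic_bp") %in% names(records))) {
    long <- dplyr::bind_rows(
      long,
      tibble::tibble(patient_id = records$patient_id, tick = records$tick,
                     vital = "bp", value = NA_real_,
                     sys = records$systolic_bp, dia = records$diastolic_bp)
    )
  }
  long
}

#' Evaluate vital-sign records against the sensor-agent rules
#'
#' Derives one High/Low/Normal status per configured vital per record,
#' citing the threshold rule that fired. A value equal to an inclusive
#' extreme cutoff takes the extreme status (e.g. heart rate exactly 100 is
#' High, exactly 60 is Low); blood pressure is compound — High when systolic
#' >= 145 *or* diastolic >= 100, Low when systolic <= 100 *or* diastolic
#' <= 60, with High taking precedence if both fire. Body temperatures in
#' Fahrenheit (`body_temp_f`) are converted to Celsius before comparison;
#' ECG values are divided by the profile's `ecg_divisor`. Records with a
#' missing measurement contribute no status for that vital.
#'
#' @param records A data frame of vital-sign records (one row per patient
#'   per tick); recognized columns include `heart_rate`, `ecg_index` (or
#'   `ecg`), `body_temp_f` (or `body_temp_c`), `systolic_bp`, `diastolic_bp`,
#'   `spo2`, `room_temp_c`, `blood_sugar`, plus `patient_id`/`tick`/`label`
#'   metadata.
#' @param thresholds A [threshold_profile()].
#' @return A tibble with columns `patient_id`, `tick`, `vital`, `value`,
#'   `level` (`"High"`, `"Low"`, `"Normal"`), `rule`.
#' @examples
#' rec <- tibble::tibble(heart_rate = 100, body_temp_c = 38)
#' evaluate_vitals(rec)
#' @export
evaluate_vitals <- function(records, thresholds = threshold_profile()) {
  stopifnot(inherits(thresholds, "vw_thresholds"))
  long <- collect_vital_values(records, thresholds)
  if (nrow(long) == 0) {
    return(tibble::tibble(patient_id = character(), tick = integer(),
                          vital = character(), value = numeric(),
                          level = character(), rule = character()))
  }
  cfg <- thresholds$vitals
  out <- dplyr::inner_join(long, cfg, by = "vital")
  is_bp <- out$vital == "bp"
  high <- !is.na(out$high) & !is.na(out$value) & out$value >= out$high
  low <- !is.na(out$low) & !is.na(out$value) & out$value <= out$low
  if (any(is_bp)) {
    bp <- thresholds$bp
    high[is_bp] <- out$sys[is_bp] >= bp$high_sys | out$dia[is_bp] >= bp$high_dia
    low[is_bp] <- out$sys[is_bp] <= bp$low_sys | out$dia[is_bp] <= bp$low_dia
  }
  measured <- if (any(is_bp)) {
    ifelse(is_bp, !is.na(out$sys) & !is.na(out$dia), !is.na(out$value))
  } else {
    !is.na(out$value)
  }
  out <- out[measured, , drop = FALSE]
  high <- high[measured]
  low <- low[measured] & !high  # High precedence when both fire
  out$level <- ifelse(high, "High", ifelse(low, "Low", "Normal"))
  out$rule <- ifelse(high, out$rule_high,
                     ifelse(low, out$rule_low, out$rule_normal))
  dplyr::arrange(
    dplyr::select(out, "patient_id", "tick", "vital", "value", "level", "rule"),
    .data$patient_id, .data$tick, .data$vital
  )
}

#' Tell-message emission
#'
#' Converts non-Normal statuses into the outbound `Tell[...]` assertions the
#' sensor agents broadcast. Only statuses whose rule has a Tell
#' clause emit (fever, hypothermia, high heart rate, high blood sugar,
#' abnormal ECG, high blood pressure, and the blood-oxygen rule of the
#' active profile); Normal statuses never emit.
#'
#' @param statuses Output of [evaluate_vitals()].
#' @param thresholds The [threshold_profile()] used to derive `statuses`.
#' @return A tibble with columns `tick`, `patient_id`, `predicate`, `level`,
#'   `rule`.
#' @export
tell_messages <- function(statuses, thresholds = threshold_profile()) {
  cfg <- thresholds$vitals
  joined <- dplyr::inner_join(
    dplyr::filter(statuses, .data$level != "Normal"),
    dplyr::select(cfg, "vital", "predicate_low", "predicate_high",
                  "tell_low", "tell_high"),
    by = "vital"
  )
  emits <- ifelse(joined$level == "High", joined$tell_high, joined$tell_low)
  joined <- joined[emits, , drop = FALSE]
  tibble::tibble(
    tick = joined$tick,
    patient_id = joined$patient_id,
    predicate = ifelse(joined$level == "High",
                       joined$predicate_high, joined$predicate_low),
    level = joined$level,
    rule = joined$rule
  )
}

#' Fire-level relay
#'
#' The fire-detection sensor unconditionally relays its current level: every
#' call emits a `Current_Fire_Level` Tell message regardless of the level.
#'
#' @param level One of `"High"`, `"Low"`, `"No_Risk"`.
#' @param tick Tick stamp for the emitted message.
#' @return A one-row tibble in the [tell_messages()] format.
#' @export
evaluate_fire <- function(level, tick = 0L) {
  if (!is.character(level) || length(level) != 1 ||
      !level %in% c("High", "Low", "No_Risk")) {
    abort("`level` must be one of \"High\", \"Low\", \"No_Risk\"")
  }
  tibble::tibble(tick = as.integer(tick), patient_id = NA_character_,
                 predicate = "Current_Fire_Level", level = level,
                 rule = "R28")
}
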