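#' Simulation configuration
#'
#' Parameters of the tick-based multi-agent monitoring world: patient and
#' doctor counts, grid geometry, escalation cutoffs, and the probability
#' dynamics linking sensor-rule statuses to each patient's risk score.
#'
#' Each tick, every patient's risk probability is recomputed as a logistic
#' squashing of a weighted count of their non-Normal vital statuses,
#' \eqn{p = \sigma(b_0 + w \cdot n_{abnormal})}, plus Gaussian drift, then
#' clipped to \[0, 1\]. Severity follows the escalation cutoffs: `critical`
#' notifies the nearest doctor, `extremely_critical` generates an alert,
#' `life_threatening` calls an ambulance. Patients' vitals come from an
#' embedded synthetic cohort (one record per tick, wrapping around);
#' sensor agents are stateless forwarders reading their channel through the
#' threshold rules.
#'
#' @param n_patients,n_doctors Agent counts (>= 0).
#' @param grid_size Side length of the square world.
#' @param cutoffs Named increasing cutoffs `critical`, `extremely_critical`,
#'   `life_threatening` in (0, 1).
#' @param drift_sd Standard deviation of the per-tick Gaussian drift.
#' @param intercept,abnormal_weight Parameters of the logistic status-count
#'   squashing.
#' @param records_per_patient Length of each patient's embedded vital-sign
#'   stream.
#' @param risk_fraction Fraction of simulated patients drawn from the
#'   SARS-risk class.
#' @param seed Master seed; named sub-streams (setup, movement, drift) are
#'   derived so one concern's draws cannot perturb another's.
#' @return A `vw_sim_config` list.
#' @export
sim_config <- function(n_patients = 5, n_doctors = 1, grid_size = 33,
                       cutoffs = c(critical = 0.6, extremely_critical = 0.8,
                                   life_threatening = 0.95),
                       drift_sd = 0.02, intercept = -3, abnormal_weight = 1.2,
                       records_per_patient = 120, risk_fraction = 0.4,
                       seed = 1) {
  n_patients <- check_count(n_patients, "n_patients", min = 0)
  n_doctors <- check_count(n_doctors, "n_doctors", min = 0)
  if (grid_size <= 0) abort("`grid_size` must be positive")
  need <- c("critical", "extremely_critical", "life_threatening")
  if (!all(need %in% names(cutoffs)) || any(diff(cutoffs[need]) <= 0)) {
    abort("`cutoffs` must name critical < extremely_critical < life_threatening")
  }
  structure(
    list(n_patients = n_patients, n_doctors = n_doctors,
         grid_size = grid_size, cutoffs = cutoffs[need],
         drift_sd = drift_sd, intercept = intercept,
         abnormal_weight = abnormal_weight,
         records_per_patient = records_per_patient,
         risk_fraction = risk_fraction, seed = seed),
    class = "vw_sim_config"
  )
}

sensor_kinds <- c("blood_oxygen", "environmental", "body_temperature",
                  "heart_rate", "ecg", "blood_pressure", "room_temperature")

#' Set up the simulation world
#'
#' Creates the agent population: mobile patient and doctor agents at seeded
#' random positions, plus the seven stationary sensor agents (blood oxygen,
#' environmental, body temperature, heart rate, ECG, blood pressure, room
#' temperature). Each patient is bound to a synthetic vital-sign stream.
#' The tick counter starts at 0 and the event log empty. With zero doctors
#' and escalation enabled, a configuration warning is issued and doctor
#' calls degrade to alerts.
#'
#' @param config A [sim_config()].
#' @return A `vw_world` object.
#' @examples
#' w <- sim_setup(sim_config(n_patients = 2, n_doctors = 1, seed = 7))
#' w$tick
#' @export
sim_setup <- function(config = sim_config()) {
  stopifnot(inherits(config, "vw_sim_config"))
  if (config$n_doctors == 0 && config$n_patients > 0) {
    warn("no doctor agents: doctor calls will degrade to alerts")
  }
  np <- config$n_patients
  nd <- config$n_doctors
  n_mobile <- np + nd
  pos <- with_stream(config$seed, "setup", {
    matrix(runif((n_mobile + length(sensor_kinds)) * 2, 0, config$grid_size),
           ncol = 2)
  })
  agents <- tibble::tibble(
    agent_id = seq_len(n_mobile + length(sensor_kinds)),
    kind = c(rep("patient", np), rep("doctor", nd),
             paste0("sensor:", sensor_kinds)),
    x = pos[, 1], y = pos[, 2],
    probability = c(rep(0.05, np), rep(NA_real_, nd + length(sensor_kinds))),
    is_doctor = c(rep(FALSE, np), rep(TRUE, nd),
                  rep(FALSE, length(sensor_kinds)))
  )
  cohort <- if (np > 0) {
    generate_cohort(cohort_config(
      n_patients = np,
      records_per_patient = config$records_per_patient,
      normal_fraction = 1 - config$risk_fraction,
      missing_rate = 0,
      seed = stream_seed(config$seed, "sim_cohort")
    ))
  } else {
    NULL
  }
  patient_map <- if (np > 0) {
    tibble::tibble(agent_id = seq_len(np),
                   patient_id = sprintf("P%04d", seq_len(np)))
  } else {
    tibble::tibble(agent_id = integer(), patient_id = character())
  }
  structure(
    list(agents = agents, tick = 0L,
         events = tibble::tibble(tick = integer(), patient_id = character(),
                                 severity = character(), action = character(),
                                 responder_id = integer()),
         config = config, cohort = cohort, patient_map = patient_map,
         thresholds = threshold_profile("reference", ecg_divisor = 100),
         streams = list(movement = make_stream(config$seed, "movement"),
                        drift = make_stream(config$seed, "drift")),
         average_probability = average_probability_of(agents)),
    class = "vw_world"
  )
}

#' @export
print.vw_world <- function(x, ...) {
  cat(sprintf("<vw_world: tick %d, %d agents, %d events, avg probability %s>\n",
              x$tick, nrow(x$agents), nrow(x$events),
              ifelse(is.na(x$average_probability), "NA",
                     sprintf("%.3f", x$average_probability))))
  invisible(x)
}

average_probability_of <- function(agents) {
  p <- agents$probability[!is.na(agents$probability)]
  if (length(p) == 0) NA_real_ else mean(p)
}

#' Average probability across probability-bearing agents
#'
#' The population-level health statistic: total probability divided by the
#' number of probability-bearing agents, guarded to `NA` when there are
#' none.
#'
#' @param world A `vw_world`.
#' @return A number in \[0, 1\], or `NA` for an empty population.
#' @export
average_probability <- function(world) {
  stopifnot(inherits(world, "vw_world"))
  average_probability_of(world$agents)
}

severity_of <- function(p, cutoffs) {
  ifelse(p >= cutoffs["life_threatening"], "life_threatening",
         ifelse(p >= cutoffs["extremely_critical"], "extremely_critical",
                ifelse(p >= cutoffs["critical"], "critical", NA_character_)))
}

#' Dispatch the nearest doctor to a patient
#'
#' Selects the doctor agent minimizing Euclidean distance to the patient
#' (ties broken by lowest agent id) and returns the escalation event. With
#' no doctors available the event degrades to `alert_generated` with a
#' warning.
#'
#' @param world A `vw_world`.
#' @param patient_id Cohort patient identifier (e.g. `"P0001"`).
#' @return A one-row event tibble (`tick`, `patient_id`, `severity`,
#'   `action`, `responder_id`).
#' @export
call_doctor <- function(world, patient_id) {
  stopifnot(inherits(world, "vw_world"))
  agent <- world$patient_map$agent_id[world$patient_map$patient_id == patient_id]
  if (length(agent) != 1) abort(sprintf("unknown patient `%s`", patient_id))
  pat <- world$agents[world$agents$agent_id == agent, ]
  doctors <- world$agents[world$agents$is_doctor, ]
  if (nrow(doctors) == 0) {
    warn(sprintf("no doctors available for %s; generating alert instead",
                 patient_id))
    return(tibble::tibble(tick = world$tick, patient_id = patient_id,
                          severity = "critical", action = "alert_generated",
                          responder_id = NA_integer_))
  }
  dist <- sqrt((doctors$x - pat$x)^2 + (doctors$y - pat$y)^2)
  nearest <- doctors$agent_id[order(dist, doctors$agent_id)][1]
  tibble::tibble(tick = world$tick, patient_id = patient_id,
                 severity = "critical", action = "doctor_notified",
                 responder_id = as.integer(nearest))
}

#' Advance the simulation by one tick
#'
#' Executes one cycle of the main loop, in order: random wander of mobile
#' agents (reflecting at the grid boundary), sensor reading of each
#' patient's current vital record through the threshold rules, the logistic
#' probability update with Gaussian drift and clipping to \[0, 1\],
#' critical-condition checks with escalation (one event per patient per
#' tick at its highest severity), and the tick increment with the
#' average-probability recomputation. Total on valid worlds: no errors.
#'
#' @param world A `vw_world`.
#' @return The advanced world.
#' @export
sim_step <- function(world) {
  stopifnot(inherits(world, "vw_world"))
  cfg <- world$config
  agents <- world$agents
  mobile <- agents$kind %in% c("patient", "doctor")

  if (any(mobile)) {
    theta <- world$streams$movement$draw(runif(sum(mobile), 0, 2 * pi))
    nx <- agents$x[mobile] + cos(theta)
    ny <- agents$y[mobile] + sin(theta)
    g <- cfg$grid_size
    reflect <- function(v) abs((v %% (2 * g)) - g) * -1 + g  # reflect into [0, g]
    agents$x[mobile] <- reflect(nx)
    agents$y[mobile] <- reflect(ny)
  }

  np <- cfg$n_patients
  if (np > 0) {
    rec_tick <- world$tick %% cfg$records_per_patient
    recs <- world$cohort[world$cohort$tick == rec_tick, , drop = FALSE]
    statuses <- evaluate_vitals(recs, world$thresholds)
    n_abn <- dplyr::count(
      dplyr::filter(statuses, .data$level != "Normal"), .data$patient_id)
    abn <- stats::setNames(rep(0L, np), world$patient_map$patient_id)
    abn[n_abn$patient_id] <- n_abn$n
    drift <- world$streams$drift$draw(rnorm(np, 0, cfg$drift_sd))
    p <- plogis(cfg$intercept + cfg$abnormal_weight * abn) + drift
    p <- pmin(pmax(p, 0), 1)
    agents$probability[seq_len(np)] <- p

    sev <- severity_of(p, cfg$cutoffs)
    world$agents <- agents  # call_doctor sees updated positions
    for (k in which(!is.na(sev))) {
      pid <- world$patient_map$patient_id[k]
      ev <- switch(sev[k],
        life_threatening = tibble::tibble(
          tick = world$tick, patient_id = pid, severity = sev[k],
          action = "ambulance_called", responder_id = NA_integer_),
        extremely_critical = tibble::tibble(
          tick = world$tick, patient_id = pid, severity = sev[k],
          action = "alert_generated", responder_id = NA_integer_),
        critical = {
          e <- suppressWarnings(call_doctor(world, pid))
          e$severity <- sev[k]
          e
        }
      )
      world$events <- dplyr::bind_rows(world$events, ev)
    }
  }
  world$agents <- agents
  world$tick <- world$tick + 1L
  world$average_probability <- average_probability_of(agents)
  world
}

#' Run a simulation for a number of ticks
#'
#' @param config A [sim_config()], or an already [sim_setup()] world.
#' @param n_ticks Number of ticks to advance.
#' @return A list with the final `world`, the escalation `events` tibble,
#'   and a per-tick `trajectory` tibble (`tick`, `average_probability`).
#' @export
sim_run <- function(config = sim_config(), n_ticks = 100) {
  world <- if (inherits(config, "vw_world")) config else sim_setup(config)
  n_ticks <- check_count(n_ticks, "n_ticks", min = 0)
  traj <- vector("list", n_ticks)
  for (t in seq_len(n_ticks)) {
    world <- sim_step(world)
    traj[[t]] <- tibble::tibble(tick = world$tick,
                                average_probability = world$average_probability)
  }
  list(world = world, events = world$events,
       trajectory = dplyr::bind_rows(traj))
}

#' Write an escalation event log as JSON lines
#'
#' One JSON object per line (`tick`, `patient_id`, `severity`, `action`,
#' `responder_id`), append-safe.
#'
#' @param events An event tibble.
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble::tibble(tick = integer(), patient_id = character(),
                          severity = character(), action = character(),
                          responder_id = integer()))
  }
  purrr::map_dfr(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble::tibble(tick = as.integer(obj$tick),
                   patient_id = as.character(obj$patient_id),
                   severity = as.character(obj$severity),
                   action = as.character(obj$action),
                   responder_id = if (is.null(obj$responder_id))
                     NA_integer_ else as.integer(obj$responder_id))
  })
}
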