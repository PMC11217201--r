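# Packaged study tables: flow-meter readings, injected activities and
# modelled Qin/Qout values from the two-system, twelve-setting test-retest
# flow-phantom study, plus the acquisition protocol constants. Shipping the
# tables lets every published summary statistic be recomputed offline.

MEASUREMENT_IDS <- c("150-20", "150-40", "150-60", "150-80",
                     "200-20", "200-40", "200-60", "200-80",
                     "250-20", "250-40", "250-60", "250-80")

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "flowphantom")
  stop_if(path == "", "packaged fixture ", file, " not found")
  path
}

fixture_checksum <- function(df) {
  num <- unlist(df[vapply(df, is.numeric, logical(1L))])
  round(sum(num), 4)
}

#' Load the packaged study measurement tables
#'
#' Returns the measured data of the flow-phantom test-retest study: the
#' flow-meter readings for all 12 pump/constriction settings on both PET/CT
#' systems (`flowmeter`), the dispensed activities with the printed signed
#' test-retest differences (`activities`), the modelled Qin/Qout flow
#' values (`flows`), and the acquisition protocol constants (`protocol`).
#' Row counts and numeric checksums are validated against a manifest, and
#' basic schema invariants (the 12 canonical measurement ids, positive
#' activities, complete pairing between tables) are enforced; failures are
#' reported naming the offending field.
#'
#' @return An object of class `study_tables`.
#' @examples
#' tables <- load_study_tables()
#' subset(tables$activities, measurement_id == "150-20" & system == "DMI-20")
#' @export
load_study_tables <- function() {
  manifest <- utils::read.csv(fixture_path("manifest.csv"), stringsAsFactors = FALSE)
  read_checked <- function(file) {
    df <- utils::read.csv(fixture_path(file), stringsAsFactors = FALSE)
    entry <- manifest[manifest$file == file, ]
    stop_if(nrow(entry) != 1L, "fixture ", file, " missing from manifest")
    stop_if(nrow(df) != entry$n_rows,
            "fixture ", file, ": expected ", entry$n_rows, " rows, found ", nrow(df))
    stop_if(abs(fixture_checksum(df) - entry$numeric_checksum) > 1e-6,
            "fixture ", file, ": numeric checksum mismatch")
    df
  }
  flowmeter <- read_checked("flowmeter_readings.csv")
  activities <- read_checked("injected_activities.csv")
  flows <- read_checked("modelled_flows.csv")
  protocol <- yaml::read_yaml(fixture_path("protocol.yaml"))

  check_ids <- function(df, name) {
    stop_if(!setequal(unique(df$measurement_id), MEASUREMENT_IDS),
            name, ": measurement_id must be exactly the 12 canonical settings")
  }
  check_ids(flowmeter, "flowmeter"); check_ids(activities, "activities")
  check_ids(flows, "flows")
  stop_if(!setequal(unique(flows$system), c("DMI-20", "Vision-600")),
          "flows: system must be DMI-20 / Vision-600")
  stop_if(any(activities$test_MBq <= 0) || any(activities$retest_MBq <= 0),
          "activities: injected activities must be positive")
  stop_if(any(flowmeter$qcyl_measured_ml_min <= 0) ||
            any(flowmeter$qtube_measured_ml_min <= 0),
          "flowmeter: measured flows must be positive")
  # every modelled-flow record must pair with a flow-meter record
  key <- function(df) paste(df$measurement_id, df$system)
  stop_if(!all(key(flows) %in% key(flowmeter)),
          "flows: unmatched (measurement_id, system) pair")
  stop_if(length(protocol$frame_counts) != length(protocol$frame_durations_s),
          "protocol: frame_counts and frame_durations_s lengths differ")

  structure(list(flowmeter = flowmeter, activities = activities,
                 flows = flows, protocol = protocol),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> %d flow-meter rows, %d activity rows, %d modelled-flow rows\n",
              nrow(x$flowmeter), nrow(x$activities), nrow(x$flows)))
  cat(sprintf("  protocol: %g MBq requested, Vcyl %g ml, Vin %g ml, half-life %g s\n",
              x$protocol$requested_activity_MBq, x$protocol$vcyl_ml,
              x$protocol$v_input_ml, x$protocol$half_life_s))
  invisible(x)
}

#' Frame schedule defined by the packaged protocol
#'
#' @param tables A `study_tables` object from [load_study_tables()].
#' @return A [frame_schedule()] (24 frames, 280 s for the study protocol).
#' @export
protocol_schedule <- function(tables = load_study_tables()) {
  build_frame_schedule(Map(c, tables$protocol$frame_counts,
                           tables$protocol$frame_durations_s))
}

#' Session reference flows from the packaged flow-meter readings
#'
#' `Qref = flowmeter_calibration x Qcyl reading` per session. The study's
#' flow-meter calibration look-up is not published, so the default factor
#' is 1 and the derived values serve relative analyses, not absolute ones.
#'
#' @param tables A `study_tables` object.
#' @param flowmeter_calibration Multiplicative calibration factor.
#' @return The `flowmeter` table with a `qref_ml_min` column appended.
#' @export
session_qref <- function(tables = load_study_tables(), flowmeter_calibration = 1) {
  fm <- tables$flowmeter
  fm$qref_ml_min <- flowmeter_calibration * fm$qcyl_measured_ml_min
  fm
}
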