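# File formats: the TAC CSV dialect and the run configuration file.
#
# TAC CSV dialect: UTF-8, a required header row
#   frame_start_s,frame_duration_s,value_kBq_ml
# one row per frame, frames contiguous. Lines starting with '#' are
# metadata comments; the writer records the decay-correction state as
#   # decay_corrected: TRUE|FALSE
#   # reference_time_s: <t0>

#' Write a sampled TAC to CSV
#'
#' @param tac A [sampled_tac()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tac, path) {
  stop_if(!inherits(tac, "sampled_tac"), "tac must be a sampled_tac")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# decay_corrected: %s", tac$decay_corrected),
               sprintf("# reference_time_s: %.17g", tac$reference_time)), con)
  utils::write.csv(as.data.frame(tac), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sampled TAC from CSV
#'
#' Parses the package's TAC dialect (see [write_tac_csv()]); malformed rows
#' are rejected with their line numbers, and the frame grid is validated
#' (contiguous, positive durations).
#'
#' @param path Input file path.
#' @return A [sampled_tac()].
#' @export
read_tac_csv <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  stop_if(length(lines) == 0L, path, ": empty file")
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body_lineno <- setdiff(seq_along(lines), meta_idx)
  stop_if(length(body) == 0L, path, ": no header row")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  required <- c("frame_start_s", "frame_duration_s", "value_kBq_ml")
  missing <- setdiff(required, trimws(header))
  stop_if(length(missing) > 0L, path, ": missing column(s) ",
          paste(missing, collapse = ", "))
  stop_if(length(body) == 1L, path, ": no data rows")

  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  linenos <- body_lineno[-1L]
  cols <- match(required, trimws(header))
  parsed <- lapply(seq_along(rows), function(i) {
    fields <- rows[[i]]
    stop_if(length(fields) < length(header),
            path, ": line ", linenos[i], ": expected ", length(header),
            " fields, found ", length(fields))
    vals <- suppressWarnings(as.numeric(fields[cols]))
    stop_if(any(is.na(vals)), path, ": line ", linenos[i], ": non-numeric cell")
    vals
  })
  mat <- do.call(rbind, parsed)
  schedule <- tryCatch(frame_schedule(mat[, 1L], mat[, 2L]),
                       error = function(e) stop(path, ": ", conditionMessage(e),
                                                call. = FALSE))
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[length(hit)]))
  }
  sampled_tac(schedule, mat[, 3L],
              decay_corrected = isTRUE(as.logical(get_meta("decay_corrected", "FALSE"))),
              reference_time = as.numeric(get_meta("reference_time_s", "0")))
}

run_config_defaults <- function() {
  list(seed = 1L,
       noise_scale = 0.5,
       qpump_ml_min = 200,
       constriction_fraction = 0.4,
       vcyl_ml = 160,
       v_input_ml = 15.7,
       flowmeter_calibration = 1,
       requested_activity_MBq = 500,
       dispense_error_fraction = 0.15,
       isf = 0.1,
       delay_s = 5,
       qin_min = NA_real_,          # NA: derive from Qref/Vcyl (ideal phantom)
       qout_min = NA_real_,
       half_life_s = O15_HALF_LIFE_S,
       isf_scaling = "none",
       out_dir = ".",
       rounding_digits = 2L)
}

#' Load a run configuration file
#'
#' Flat YAML-style `key: value` file mirroring the simulation and fitting
#' parameters; absent keys take package defaults, unknown keys are an error
#' (guarding against silent typos), and a duplicated key keeps the last
#' occurrence with a warning.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    stop_if(!file.exists(path), "config file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    key_lines <- grep("^[A-Za-z_][A-Za-z0-9_]*\\s*:", lines)
    keys <- sub(":.*$", "", lines[key_lines])
    dup <- unique(keys[duplicated(keys)])
    if (length(dup) > 0L) {
      warning("duplicated config key(s): ", paste(dup, collapse = ", "),
              "; last occurrence wins", call. = FALSE)
      drop <- key_lines[duplicated(keys, fromLast = TRUE)]
      lines <- lines[setdiff(seq_along(lines), drop)]
    }
    user <- yaml::yaml.load(paste(lines, collapse = "\n"))
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    stop_if(length(unknown) > 0L,
            "unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  stop_if(!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed),
          "seed must be an integer")
  structure(cfg, class = "run_config")
}
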