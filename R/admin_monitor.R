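# File-management rules, trigger events (reminders, survey, administrator
# notifications) and daily quality/compliance logs over a file-backed store
# of delimited-text tables standing in for the relational database.

#' Create an empty participant store
#'
#' The store is a set of plain data.frames (days, files, sessions, events)
#' emulating the relational schema; [write_store()] / [read_store()] persist
#' it as headered delimited text. The `days` table is pre-populated with one
#' row per intervention date: `resting_value` is `NA` ("null") exactly when
#' no resting file passed QC for that date, `activity_min` is 0 when no
#' activity was recorded.
#'
#' @param profile a [participant_profile()].
#' @param config a [run_config()].
#' @return object of class `pa_store`.
#' @export
new_store <- function(profile, config = run_config()) {
  n_days <- nrow(config$framework) * 7L
  dates <- profile$start_date + seq_len(n_days) - 1L
  structure(list(
    profile = profile,
    config = config,
    days = data.frame(
      date = dates,
      resting_value = NA_real_,
      activity_min = 0,
      endurance_min = 0,
      uploads = 0L,
      rx_downloaded = FALSE,
      stringsAsFactors = FALSE
    ),
    files = data.frame(
      filename = character(0), date = as.Date(character(0)),
      mode = character(0), accepted = logical(0), reason = character(0),
      fraction_filtered = numeric(0), mean_hr = numeric(0),
      digest = character(0), upload_date = as.Date(character(0)),
      stringsAsFactors = FALSE
    ),
    sessions = data.frame(
      date = as.Date(character(0)), total_min = numeric(0),
      endurance_min = numeric(0), mean_hr = numeric(0),
      excluded = logical(0), digest = character(0),
      stringsAsFactors = FALSE
    ),
    events = data.frame(
      date = as.Date(character(0)), kind = character(0),
      detail = character(0), stringsAsFactors = FALSE
    )
  ), class = "pa_store")
}

#' @export
print.pa_store <- function(x, ...) {
  cat(sprintf(
    "<pa_store> %s: %d days, %d files, %d sessions, %d events\n",
    x$profile$user_id, nrow(x$days), nrow(x$files), nrow(x$sessions),
    nrow(x$events)))
  invisible(x)
}

day_row <- function(store, date) {
  i <- match(as.Date(date), store$days$date)
  fl_assert(!is.na(i), "fitloop_window_error",
            "date %s outside the intervention window", format(date))
  i
}

# End date of the calendar week containing `date`.
week_end_date <- function(store, date) {
  d <- as.integer(as.Date(date) - store$profile$start_date) + 1L
  store$profile$start_date + (((d - 1L) %/% 7L) + 1L) * 7L - 1L
}

#' Ingest uploaded monitor files into the store
#'
#' Applies the file-management rules: empty and repeated files (by content
#' fingerprint) are dropped; each file is allocated to its filename date, not
#' the upload date; for resting files the first upload of a date that passes
#' quality control wins; multiple activity files on one date are concatenated
#' so the participant is credited for every session; and activity data
#' arriving after its intervention week has rolled over is stored but flagged
#' excluded from the adherence check.
#'
#' @param store a `pa_store`.
#' @param files list of `am_file` objects (already parsed).
#' @param upload_date the date the upload happened.
#' @return the updated `pa_store`.
#' @export
ingest_uploads <- function(store, files, upload_date) {
  upload_date <- as.Date(upload_date)
  config <- store$config
  for (f in files) {
    fp <- file_fingerprint(f)
    if (fp$empty) next
    if (fp$digest %in% store$files$digest) next
    i <- day_row(store, f$file_date)
    store$days$uploads[match(upload_date, store$days$date)] <-
      store$days$uploads[match(upload_date, store$days$date)] + 1L
    if (f$mode == "resting") {
      qc <- resting_file_qc(f, config)
      if (qc$accepted && is.na(store$days$resting_value[i])) {
        store$days$resting_value[i] <- daily_hrrest(f, config)
      }
    } else {
      qc <- activity_file_qc(f, config)
      if (qc$accepted) {
        s <- segment_and_summarize(f, config = config)
        excluded <- upload_date > week_end_date(store, f$file_date)
        store$sessions <- rbind(store$sessions, data.frame(
          date = f$file_date, total_min = s$total_min,
          endurance_min = s$endurance_min, mean_hr = s$endurance_mean_hr,
          excluded = excluded, digest = fp$digest, stringsAsFactors = FALSE
        ))
        store$days$activity_min[i] <- store$days$activity_min[i] + s$total_min
        if (!excluded) {
          store$days$endurance_min[i] <-
            store$days$endurance_min[i] + s$endurance_min
        }
      }
    }
    store$files <- rbind(store$files, data.frame(
      filename = f$source_name, date = f$file_date, mode = f$mode,
      accepted = qc$accepted, reason = qc$reason,
      fraction_filtered = qc$fraction_filtered, mean_hr = qc$mean_hr,
      digest = fp$digest, upload_date = upload_date, stringsAsFactors = FALSE
    ))
  }
  store
}

#' Mark a prescription as downloaded for a date
#'
#' @param store a `pa_store`.
#' @param date prescription date.
#' @param downloaded logical.
#' @return the updated store.
#' @export
mark_prescription_downloaded <- function(store, date, downloaded = TRUE) {
  store$days$rx_downloaded[day_row(store, date)] <- downloaded
  store
}

# Length of the TRUE streak in `mask` ending exactly at position `i`.
streak_ending_at <- function(mask, i) {
  if (!mask[i]) return(0L)
  j <- i
  while (j > 1L && mask[j - 1L]) j <- j - 1L
  i - j + 1L
}

#' Scan for administrative trigger events on a date
#'
#' Pure function of the store contents: `reminder_3day_hr` fires on the 3rd
#' consecutive date with a null resting value (the counter resets on any
#' accepted resting upload), `survey_7day` fires on the 7th consecutive date
#' with no uploads of any kind (any upload resets), and `admin_no_download`
#' fires when prescriptions go undownloaded for (by default) 3 consecutive
#' days. Each trigger fires once per streak and re-arms only after the
#' condition clears; at most one event of each kind per date.
#'
#' @param store a `pa_store` current through `date`.
#' @param date the date being scanned.
#' @return data.frame of `TriggerEvent` rows (`date`, `kind`, `detail`);
#'   zero rows when nothing fires.
#' @export
scan_triggers <- function(store, date) {
  config <- store$config
  i <- day_row(store, date)
  upto <- store$days[seq_len(i), ]
  events <- list()
  s_rest <- streak_ending_at(is.na(upto$resting_value), i)
  if (s_rest == config$reminder_days) {
    events <- c(events, list(data.frame(
      date = as.Date(date), kind = "reminder_3day_hr",
      detail = sprintf("no resting heart-rate data for %d consecutive days",
                       s_rest), stringsAsFactors = FALSE)))
  }
  s_up <- streak_ending_at(upto$uploads == 0L, i)
  if (s_up == config$survey_days) {
    events <- c(events, list(data.frame(
      date = as.Date(date), kind = "survey_7day",
      detail = sprintf("no file uploads for %d consecutive days", s_up),
      stringsAsFactors = FALSE)))
  }
  s_dl <- streak_ending_at(!upto$rx_downloaded, i)
  if (s_dl == config$no_download_days) {
    events <- c(events, list(data.frame(
      date = as.Date(date), kind = "admin_no_download",
      detail = sprintf("prescription not downloaded for %d consecutive days",
                       s_dl), stringsAsFactors = FALSE)))
  }
  if (!length(events)) {
    return(store$events[0, ])
  }
  do.call(rbind, events)
}

#' Milestone notification events
#'
#' Four fixed administrative notifications: following account creation, at
#' the start of the intervention, one day prior to the exercise field test
#' (the first activity day of the final calendar week), and at the
#' conclusion of the intervention.
#'
#' @param profile a [participant_profile()].
#' @param config a [run_config()].
#' @return data.frame of four `milestone_email` events.
#' @export
milestone_emails <- function(profile, config = run_config()) {
  n_weeks <- nrow(config$framework)
  eft_date <- profile$start_date + (n_weeks - 1L) * 7L
  data.frame(
    date = c(profile$account_date, profile$start_date, eft_date - 1L,
             profile$start_date + n_weeks * 7L - 1L),
    kind = "milestone_email",
    detail = c("account created", "intervention start",
               "exercise field test tomorrow", "intervention concluded"),
    stringsAsFactors = FALSE
  )
}

#' Append trigger events to the store, one per kind per date
#'
#' @param store a `pa_store`.
#' @param events data.frame of events.
#' @return the updated store.
#' @export
append_events <- function(store, events) {
  if (!nrow(events)) return(store)
  key_new <- paste(events$date, events$kind)
  key_old <- paste(store$events$date, store$events$kind)
  store$events <- rbind(store$events, events[!(key_new %in% key_old), ])
  store
}

#' Daily quality/compliance log
#'
#' One pipe-delimited line per file processed for the date (QC outcome and
#' reason) followed by a summary line (resting value or null, activity
#' minutes, prescription download flag). Deterministic: re-running over the
#' same store reproduces identical lines.
#'
#' @param store a `pa_store`.
#' @param date the date to log.
#' @return character vector of log lines.
#' @export
daily_log <- function(store, date) {
  date <- as.Date(date)
  i <- day_row(store, date)
  fi <- store$files[store$files$date == date, , drop = FALSE]
  lines <- character(0)
  if (nrow(fi)) {
    lines <- sprintf(
      "%s | file | %s | %s | %s | %s | frac=%s | mean_hr=%s",
      format(date), fi$filename, fi$mode,
      ifelse(fi$accepted, "accepted", "rejected"), fi$reason,
      ifelse(is.na(fi$fraction_filtered), "-",
             sprintf("%.3f", fi$fraction_filtered)),
      ifelse(is.na(fi$mean_hr), "-", sprintf("%.1f", fi$mean_hr))
    )
  }
  d <- store$days[i, ]
  c(lines, sprintf(
    "%s | summary | resting=%s | activity_min=%s | rx_downloaded=%s",
    format(date),
    if (is.na(d$resting_value)) "null" else sprintf("%.1f", d$resting_value),
    format(d$activity_min), d$rx_downloaded
  ))
}

#' Persist / load a store as delimited text
#'
#' @param store a `pa_store`.
#' @param dir directory to write the tables into (created if needed).
#' @return `write_store()`: `dir`, invisibly. `read_store()`: a `pa_store`.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
  }
  wt(store$days, "days")
  wt(store$files, "files")
  wt(store$sessions, "sessions")
  wt(store$events, "events")
  wt(store$config$framework, "framework")
  p <- store$profile
  writeLines(c(
    paste0("user_id: ", p$user_id),
    paste0("sex: ", p$sex),
    paste0("baseline_hrrest: ", p$baseline_hrrest),
    paste0("hrmax: ", p$hrmax),
    paste0("start_date: ", format(p$start_date)),
    paste0("account_date: ", format(p$account_date))
  ), file.path(dir, "profile.dcf"))
  invisible(dir)
}

#' @rdname write_store
#' @param config a [run_config()] to attach on load; its framework is
#'   replaced by the one stored with the data.
#' @export
read_store <- function(dir, config = run_config()) {
  fl_assert(dir.exists(dir), "fitloop_config_error",
            "store directory '%s' does not exist", dir)
  rd <- function(name, dates = "date") {
    df <- utils::read.delim(file.path(dir, paste0(name, ".tsv")), sep = "\t",
                            stringsAsFactors = FALSE)
    for (col in intersect(dates, names(df))) {
      df[[col]] <- as.Date(as.character(df[[col]]))
    }
    df
  }
  dcf <- read.dcf(file.path(dir, "profile.dcf"))
  profile <- participant_profile(
    user_id = unname(dcf[1, "user_id"]),
    sex = unname(dcf[1, "sex"]),
    baseline_hrrest = suppressWarnings(as.numeric(dcf[1, "baseline_hrrest"])),
    hrmax = as.numeric(dcf[1, "hrmax"]),
    start_date = as.Date(unname(dcf[1, "start_date"])),
    account_date = as.Date(unname(dcf[1, "account_date"]))
  )
  config$framework <- read_framework(file.path(dir, "framework.tsv"))
  store <- new_store(profile, config)
  days <- rd("days")
  days$resting_value <- as.numeric(days$resting_value)
  days$activity_min <- as.numeric(days$activity_min)
  days$endurance_min <- as.numeric(days$endurance_min)
  days$uploads <- as.integer(days$uploads)
  days$rx_downloaded <- as.logical(days$rx_downloaded)
  store$days <- days
  files <- rd("files", c("date", "upload_date"))
  files$filename <- as.character(files$filename)
  files$fraction_filtered <- as.numeric(files$fraction_filtered)
  files$mean_hr <- as.numeric(files$mean_hr)
  store$files <- files
  sessions <- rd("sessions")
  sessions$mean_hr <- as.numeric(sessions$mean_hr)
  store$sessions <- sessions
  events <- rd("events")
  events$kind <- as.character(events$kind)
  events$detail <- as.character(events$detail)
  store$events <- events
  store
}
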