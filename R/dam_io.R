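# Reading, validating and annotating Trikinetics DAM2 monitor files.
#
# The DAM2 text dialect accepted here is the common 42-column layout:
# reading index, date ("d mmm yy"), time ("HH:MM:SS"), status code, a fixed
# number of auxiliary columns (6 by default), then 32 beam-break counts, one
# per channel. Files are plain tab-separated text with no header.

.DAM_N_CHANNELS <- 32L

# locale-independent "d mmm yy" / "dd mmm yy" parser
.parse_dam_datetime <- function(date_str, time_str) {
  parts <- strsplit(trimws(date_str), "[[:space:]]+")
  day <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  mon <- match(vapply(parts, `[`, "", 2L), month.abb)
  yr <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  yr <- ifelse(!is.na(yr) & yr < 100L, 2000L + yr, yr)
  bad <- is.na(day) | is.na(mon) | is.na(yr)
  iso <- sprintf("%04d-%02d-%02d %s", yr, mon, day, time_str)
  out <- as.POSIXct(iso, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out[bad] <- NA
  out
}

.format_dam_date <- function(datetime) {
  lt <- as.POSIXlt(datetime, tz = "UTC")
  sprintf("%02d %s %02d", lt$mday, month.abb[lt$mon + 1L], lt$year %% 100L)
}

#' Read a DAM2 monitor file
#'
#' Parses a tab-separated Drosophila Activity Monitor (DAM2) file into a
#' table of per-reading timestamps, status codes and 32 channel counts.
#' Readings whose status code differs from 1 are retained but flagged
#' invalid; downstream binning treats the minutes they fall in as missing.
#'
#' @param path Path to the monitor text file.
#' @param n_aux Number of auxiliary columns between the status code and the
#'   first channel count (DAM2 writes 6).
#' @return A `data.table` with columns `line` (file line number), `datetime`
#'   (POSIXct, UTC), `status`, `valid` (logical, `status == 1`) and `ch01`
#'   ... `ch32` (integer counts).
#' @export
read_dam_monitor <- function(path, n_aux = 6L) {
  if (!file.exists(path)) {
    stop("monitor file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("monitor file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  expected <- 4L + n_aux + .DAM_N_CHANNELS
  nf <- lengths(fields)
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1L]
    stop(sprintf(
      "malformed monitor row at line %d of %s: %d columns, expected %d",
      bad, basename(path), nf[bad], expected
    ), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = expected, byrow = TRUE)
  datetime <- .parse_dam_datetime(m[, 2L], m[, 3L])
  if (anyNA(datetime)) {
    bad <- which(is.na(datetime))[1L]
    stop(sprintf("unparseable timestamp at line %d of %s", bad, basename(path)),
         call. = FALSE)
  }
  if (is.unsorted(datetime, strictly = TRUE)) {
    bad <- which(diff(as.numeric(datetime)) <= 0)[1L] + 1L
    stop(sprintf(
      "timestamps not strictly increasing at line %d of %s", bad, basename(path)
    ), call. = FALSE)
  }
  counts <- matrix(suppressWarnings(as.integer(m[, (4L + n_aux + 1L):expected])),
                   nrow = nrow(m))
  if (anyNA(counts) || any(counts < 0L)) {
    bad <- which(apply(is.na(counts) | counts < 0L, 1L, any))[1L]
    stop(sprintf("invalid channel count at line %d of %s", bad, basename(path)),
         call. = FALSE)
  }
  status <- suppressWarnings(as.integer(m[, 4L]))
  out <- data.table(
    line = seq_len(nrow(m)),
    datetime = datetime,
    status = status,
    valid = status == 1L
  )
  colnames(counts) <- sprintf("ch%02d", seq_len(.DAM_N_CHANNELS))
  out <- cbind(out, as.data.table(counts))
  setattr(out, "dam_path", path)
  out[]
}

#' Write readings back to the canonical DAM2 dialect
#'
#' Writes the table produced by [read_dam_monitor()] (or by the simulator)
#' as tab-separated DAM2 text with six zero auxiliary columns. Files written
#' here re-read byte-identically.
#'
#' @param readings Table in the layout of [read_dam_monitor()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(readings, path) {
  stopifnot(all(c("datetime", "status") %in% names(readings)))
  chcols <- sprintf("ch%02d", seq_len(.DAM_N_CHANNELS))
  stopifnot(all(chcols %in% names(readings)))
  lt <- as.POSIXlt(readings$datetime, tz = "UTC")
  time_str <- sprintf("%02d:%02d:%02d", lt$hour, lt$min, floor(lt$sec))
  counts <- as.matrix(readings[, chcols, with = FALSE])
  body <- apply(counts, 1L, paste, collapse = "\t")
  aux <- paste(rep("0", 6L), collapse = "\t")
  out <- paste(seq_len(nrow(readings)), .format_dam_date(readings$datetime),
               time_str, readings$status, aux, body, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Bin one channel's counts to 1-minute resolution
#'
#' Sub-minute readings are summed into the containing minute. Minutes with
#' no reading, and minutes containing any reading flagged invalid
#' (status code != 1), are marked missing (`NA`), never zero: imputing zero
#' would fabricate inactivity, i.e. sleep.
#'
#' @param readings Table from [read_dam_monitor()].
#' @param channel Channel number, 1-32.
#' @return A `data.table` with columns `minute` (POSIXct, one row per minute
#'   from the first to the last observed minute) and `count` (integer or
#'   `NA` for missing minutes).
#' @export
bin_to_minutes <- function(readings, channel) {
  if (!is.numeric(channel) || length(channel) != 1L ||
      channel < 1L || channel > .DAM_N_CHANNELS) {
    stop("channel must be a single integer in 1..32", call. = FALSE)
  }
  col <- sprintf("ch%02d", as.integer(channel))
  dt <- data.table(
    minute = as.POSIXct(floor(as.numeric(readings$datetime) / 60) * 60,
                        tz = "UTC", origin = "1970-01-01"),
    count = readings[[col]],
    valid = readings$valid
  )
  agg <- dt[, .(count = sum(count), all_valid = all(valid)), by = minute]
  agg[all_valid == FALSE, count := NA_integer_]
  full <- data.table(minute = seq(min(agg$minute), max(agg$minute), by = 60))
  out <- agg[full, on = "minute"][, .(minute, count)]
  out[]
}

#' Construct an experiment design
#'
#' Describes the 3-day thermogenetic protocol: one baseline day (21 deg C),
#' one neural-activation day (30 deg C) and one recovery day (21 deg C)
#' under a light/dark cycle. Zeitgeber time (ZT) 0 is lights-on; minutes
#' with ZT in `[0, photoperiod)` are light phase (LP), the rest dark phase
#' (DP). Day role is assigned by the calendar date of the minute.
#'
#' @param baseline,activation,recovery Calendar dates (`Date` or
#'   "YYYY-MM-DD") of the three experiment days.
#' @param lights_on Clock time of lights-on, "HH:MM".
#' @param photoperiod_minutes Length of the light phase in minutes
#'   (default 720, i.e. 12 h:12 h).
#' @return A list of class `dam_design`.
#' @export
experiment_design <- function(baseline, activation, recovery,
                              lights_on = "08:00", photoperiod_minutes = 720L) {
  days <- c(baseline = as.Date(baseline), activation = as.Date(activation),
            recovery = as.Date(recovery))
  if (anyNA(days) || length(unique(days)) != 3L) {
    stop("design needs three distinct dates: baseline, activation, recovery",
         call. = FALSE)
  }
  hm <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1L]])
  if (length(hm) != 2L || anyNA(hm)) stop("lights_on must be 'HH:MM'", call. = FALSE)
  if (photoperiod_minutes <= 0 || photoperiod_minutes >= 1440) {
    stop("photoperiod_minutes must lie in (0, 1440)", call. = FALSE)
  }
  structure(list(
    days = days,
    lights_on_minute = hm[1L] * 60L + hm[2L],
    photoperiod_minutes = as.integer(photoperiod_minutes)
  ), class = "dam_design")
}

#' Annotate binned minutes with day role, phase and ZT
#'
#' Labels every minute of a binned series with its experiment-day role
#' (baseline / activation / recovery, by calendar date), zeitgeber minute
#' (0-1439, lights-on = 0) and light/dark phase. Minutes on dates outside
#' the design are dropped.
#'
#' @param binned Output of [bin_to_minutes()].
#' @param design A [experiment_design()].
#' @param fly_id,genotype,driver,genotype_role Metadata attached to every
#'   row; `genotype_role` is one of `"experimental"`, `"gal4_control"`,
#'   `"uas_control"`.
#' @return A `data.table` (one row per minute): `fly_id`, `genotype`,
#'   `driver`, `genotype_role`, `minute` (POSIXct), `date`, `day_role`,
#'   `zt_minute`, `phase` (`"LP"`/`"DP"`), `count` (`NA` = missing minute).
#' @export
annotate_minutes <- function(binned, design, fly_id, genotype = fly_id,
                             driver = NA_character_,
                             genotype_role = "experimental") {
  stopifnot(inherits(design, "dam_design"))
  genotype_role <- match.arg(genotype_role,
                             c("experimental", "gal4_control", "uas_control"))
  lt <- as.POSIXlt(binned$minute, tz = "UTC")
  date <- as.Date(binned$minute, tz = "UTC")
  role_idx <- match(date, design$days)
  keep <- !is.na(role_idx)
  clock_min <- lt$hour * 60L + lt$min
  zt <- (clock_min - design$lights_on_minute) %% 1440L
  out <- data.table(
    fly_id = fly_id, genotype = genotype, driver = driver,
    genotype_role = genotype_role,
    minute = binned$minute,
    date = date,
    day_role = names(design$days)[role_idx],
    zt_minute = zt,
    phase = ifelse(zt < design$photoperiod_minutes, "LP", "DP"),
    count = binned$count
  )[keep]
  missing_roles <- setdiff(c("baseline", "activation", "recovery"),
                           unique(out$day_role))
  if (length(missing_roles)) {
    warning("annotated series has no minutes on day(s): ",
            paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  out[]
}

#' Flag flies that died during recording
#'
#' Standard DAM hygiene: a fly is dropped when its number of active minutes
#' (count > 0) on the recovery (last) day falls below a threshold. Missing
#' minutes never count as active.
#'
#' @param activity Annotated per-minute table ([annotate_minutes()] rows,
#'   possibly many flies).
#' @param min_active_minutes_last_day Threshold; 0 keeps every fly.
#' @return A `data.table` per fly: `fly_id`, `active_minutes`, `keep`,
#'   `reason`.
#' @export
filter_dead_flies <- function(activity, min_active_minutes_last_day = 1L) {
  dec <- activity[day_role == "recovery",
                  .(active_minutes = sum(count > 0, na.rm = TRUE)),
                  by = fly_id]
  missing <- setdiff(unique(activity$fly_id), dec$fly_id)
  if (length(missing)) {
    dec <- rbind(dec, data.table(fly_id = missing, active_minutes = 0L))
  }
  dec[, keep := active_minutes >= min_active_minutes_last_day]
  dec[, reason := ifelse(keep, "alive",
                         sprintf("dead: %d active minutes on recovery day (< %d)",
                                 active_minutes, as.integer(min_active_minutes_last_day)))]
  dec[]
}

#' Read a channel map CSV
#'
#' Maps monitor file / channel pairs to flies. Columns: `monitor` (file
#' name or label), `channel` (1-32), `fly_id`, `genotype`, `driver`,
#' `genotype_role` (experimental | gal4_control | uas_control).
#'
#' @param path CSV path.
#' @return A validated `data.table`.
#' @export
read_channel_map <- function(path) {
  cm <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  need <- c("monitor", "channel", "fly_id", "genotype", "driver", "genotype_role")
  miss <- setdiff(need, names(cm))
  if (length(miss)) stop("channel map lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(cm$channel < 1L | cm$channel > .DAM_N_CHANNELS)) {
    stop("channel map has channels outside 1..32", call. = FALSE)
  }
  bad <- setdiff(unique(cm$genotype_role),
                 c("experimental", "gal4_control", "uas_control"))
  if (length(bad)) stop("unknown genotype_role: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(cm$fly_id)) stop("duplicate fly_id in channel map", call. = FALSE)
  cm[]
}

#' Load a full screen: monitors + channel map + design
#'
#' Reads every monitor file, bins each mapped channel to minutes, annotates
#' with the design, and stacks the result into one long per-minute table.
#'
#' @param monitor_paths Named character vector: names are the `monitor`
#'   labels used in the channel map, values are file paths.
#' @param channel_map Table from [read_channel_map()] (or equivalent).
#' @param design A [experiment_design()].
#' @return Long annotated activity `data.table` (all flies).
#' @export
load_dam_screen <- function(monitor_paths, channel_map, design) {
  channel_map <- as.data.table(channel_map)
  unknown <- setdiff(unique(channel_map$monitor), names(monitor_paths))
  if (length(unknown)) {
    stop("channel map references monitors without files: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pieces <- vector("list", nrow(channel_map))
  for (mon in unique(channel_map$monitor)) {
    readings <- read_dam_monitor(monitor_paths[[mon]])
    rows <- which(channel_map$monitor == mon)
    for (i in rows) {
      binned <- bin_to_minutes(readings, channel_map$channel[i])
      pieces[[i]] <- annotate_minutes(
        binned, design,
        fly_id = channel_map$fly_id[i], genotype = channel_map$genotype[i],
        driver = channel_map$driver[i],
        genotype_role = channel_map$genotype_role[i]
      )
    }
  }
  rbindlist(pieces)
}
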