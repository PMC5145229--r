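# Per-trial trace files: UTF-8 CSV with a commented metadata header
# followed by one data row per sample. The dialect is defined by this
# package (readers of other repositories' layouts are out of scope):
#
#   # subject_id: s01
#   # age: 30
#   # height_cm: 175.0
#   # weight_kg: 70.0
#   # gender: M
#   # activity_category: FALL
#   # activity_subtype: lateral
#   # trial_index: 1
#   # device: phone-01,thigh_pocket,generic,200,2
#   t_s,device_id,ax,ay,az,gx,gy,gz,mx,my,mz
#   0.000000,phone-01,0.000000,0.000000,-9.806650,,,,,,
#
# Decimal point, comma separator, LF endings. Gyro/magnetometer cells are
# empty when the modality is absent. Data rows are sorted by (device, t).
# Floats are written with 6 decimals; round-tripping is exact to 1e-6.

knownMetaKeys <- c("subject_id", "age", "height_cm", "weight_kg", "gender",
                   "activity_category", "activity_subtype", "trial_index")

traceHeaderCols <- c("t_s", "device_id", "ax", "ay", "az",
                     "gx", "gy", "gz", "mx", "my", "mz")

fmtNum <- function(x) {
  out <- sprintf("%.6f", x)
  out[!is.finite(x)] <- ""
  out
}

#' Write a trial recording as a trace CSV
#'
#' Serialises one [TrialRecording-class] in the package's trace dialect:
#' `# key: value` metadata lines (subject, activity, trial index, then one
#' `# device:` line per stream), a fixed data header row, and one row per
#' sample sorted by (device, t). Preserved unknown metadata (the trial's
#' `extra` slot) is written back as additional `# key: value` lines.
#'
#' @param trial a valid [TrialRecording-class].
#' @param path file path or connection to write to.
#' @return Invisibly, the path.
#' @seealso [readTrialCsv()]
#' @export
writeTrialCsv <- function(trial, path) {
  stopifnot(is(trial, "TrialRecording"))
  validObject(trial)
  s <- trial@subject
  lines <- c(
    sprintf("# subject_id: %s", s@subjectId),
    sprintf("# age: %d", s@age),
    sprintf("# height_cm: %s", fmtNum(s@height)),
    sprintf("# weight_kg: %s", fmtNum(s@weight)),
    sprintf("# gender: %s", s@gender),
    sprintf("# activity_category: %s", trial@activityCategory),
    sprintf("# activity_subtype: %s", trial@activitySubtype),
    sprintf("# trial_index: %d", trial@trialIndex))
  if (length(trial@extra))
    lines <- c(lines, sprintf("# %s: %s", names(trial@extra), trial@extra))
  for (st in trial@streams) {
    validObject(st)
    lines <- c(lines, sprintf("# device: %s,%s,%s,%g,%g",
                              st@spec@deviceId, st@position, st@spec@vendor,
                              st@spec@samplingRate, st@spec@accelRange))
  }
  lines <- c(lines, paste(traceHeaderCols, collapse = ","))
  for (st in trial@streams) {
    n <- nSamples(st)
    opt <- function(v) if (length(v)) fmtNum(v) else rep("", n)
    lines <- c(lines, paste(
      fmtNum(st@t), st@spec@deviceId,
      fmtNum(st@ax), fmtNum(st@ay), fmtNum(st@az),
      opt(st@gx), opt(st@gy), opt(st@gz),
      opt(st@mx), opt(st@my), opt(st@mz), sep = ","))
  }
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, open = "wb"); on.exit(close(f)); f
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trace CSV into a trial recording
#'
#' Parses a file written in the package's trace dialect (see
#' [writeTrialCsv()]) and returns a validated [TrialRecording-class].
#' Unknown `# key: value` metadata lines are preserved in the trial's
#' `extra` slot. Sample rows that arrive out of time order within a device
#' are re-sorted by timestamp with a warning; duplicate timestamps within a
#' device, acceleration components exceeding the device range by more than
#' 1%, and malformed headers are errors.
#'
#' @param path file path or connection.
#' @return A [TrialRecording-class].
#' @export
readTrialCsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  metaIdx <- grep("^#", lines)
  if (!length(metaIdx) || metaIdx[1L] != 1L ||
      any(diff(metaIdx) != 1L))
    stop("malformed trace file: metadata block must be a leading run of '# ' lines")
  meta <- list(); devices <- list(); extra <- character(0)
  for (i in metaIdx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed metadata at line %d: %s", i, lines[i]))
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (key == "device") {
      f <- strsplit(val, ",", fixed = TRUE)[[1L]]
      if (length(f) != 5L)
        stop(sprintf("malformed device line %d: expected 5 fields", i))
      devices[[f[1L]]] <- list(id = f[1L], position = f[2L], vendor = f[3L],
                               rate = as.numeric(f[4L]),
                               range = as.numeric(f[5L]))
    } else if (key %in% knownMetaKeys) {
      meta[[key]] <- val
    } else {
      extra[key] <- val
    }
  }
  missingKeys <- setdiff(knownMetaKeys, names(meta))
  if (length(missingKeys))
    stop("missing metadata key(s): ", paste(missingKeys, collapse = ", "))
  if (!length(devices)) stop("no '# device:' metadata line")

  hdrLine <- length(metaIdx) + 1L
  if (hdrLine > length(lines) ||
      !identical(trimws(lines[hdrLine]), paste(traceHeaderCols, collapse = ",")))
    stop(sprintf("malformed data header at line %d", hdrLine))
  body <- lines[seq.int(hdrLine + 1L, length(lines))]
  body <- body[nzchar(body)]
  if (!length(body)) stop("trace file contains no sample rows")
  df <- utils::read.csv(text = c(lines[hdrLine], body),
                        colClasses = c(t_s = "numeric", device_id = "character",
                                       ax = "numeric", ay = "numeric",
                                       az = "numeric", gx = "numeric",
                                       gy = "numeric", gz = "numeric",
                                       mx = "numeric", my = "numeric",
                                       mz = "numeric"))
  unknownDev <- setdiff(unique(df$device_id), names(devices))
  if (length(unknownDev))
    stop("sample rows for undeclared device(s): ",
         paste(unknownDev, collapse = ", "))

  subj <- SubjectMeta(meta$subject_id, as.integer(meta$age),
                      as.numeric(meta$height_cm), as.numeric(meta$weight_kg),
                      meta$gender)
  streamList <- list()
  for (dev in devices) {
    rows <- df[df$device_id == dev$id, , drop = FALSE]
    if (!nrow(rows))
      stop("declared device has no sample rows: ", dev$id)
    if (is.unsorted(rows$t_s, strictly = FALSE)) {
      warning(sprintf("re-sorting out-of-order samples for device %s", dev$id))
      rows <- rows[order(rows$t_s), , drop = FALSE]
    }
    if (anyDuplicated(rows$t_s))
      stop("duplicate timestamps for device ", dev$id)
    lim <- dev$range * STANDARD_GRAVITY * 1.01
    if (any(abs(c(rows$ax, rows$ay, rows$az)) > lim, na.rm = TRUE))
      stop(sprintf("acceleration exceeds +/-%g g by more than 1%% for device %s",
                   dev$range, dev$id))
    optCol <- function(v) if (all(is.na(v))) numeric(0) else as.numeric(v)
    streamList[[dev$position]] <- SensorStream(
      position = dev$position,
      spec = SensorSpec(dev$id, dev$vendor, dev$rate, dev$range),
      t = rows$t_s, ax = rows$ax, ay = rows$ay, az = rows$az,
      gx = optCol(rows$gx), gy = optCol(rows$gy), gz = optCol(rows$gz),
      mx = optCol(rows$mx), my = optCol(rows$my), mz = optCol(rows$mz))
  }
  TrialRecording(subject = subj,
                 activityCategory = meta$activity_category,
                 activitySubtype = meta$activity_subtype,
                 trialIndex = as.integer(meta$trial_index),
                 streams = streamList, extra = extra)
}

#' Write or read a whole dataset as a directory of trace files
#'
#' `writeDataset()` writes one trace CSV per trial (named
#' `trial_<subject>_<subtype>_<index>.csv`) plus a `manifest.csv` listing
#' file, subject, category, subtype and trial index. `readDataset()` loads
#' every file named in a directory's manifest back into a
#' [FallDataset-class].
#'
#' @param dataset a [FallDataset-class].
#' @param dir directory (created if needed).
#' @return `writeDataset()`: invisibly, the manifest data.frame;
#'   `readDataset()`: a [FallDataset-class].
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trs <- trials(dataset)
  manifest <- data.frame(
    file = vapply(trs, function(tr) sprintf("trial_%s_%s_%02d.csv",
                                            tr@subject@subjectId,
                                            tr@activitySubtype,
                                            tr@trialIndex), character(1)),
    subject_id = vapply(trs, function(tr) tr@subject@subjectId, character(1)),
    activity_category = vapply(trs, activityCategory, character(1)),
    activity_subtype = vapply(trs, activitySubtype, character(1)),
    trial_index = vapply(trs, function(tr) tr@trialIndex, integer(1)))
  if (anyDuplicated(manifest$file))
    stop("duplicate trial identities produce colliding file names")
  for (i in seq_along(trs))
    writeTrialCsv(trs[[i]], file.path(dir, manifest$file[i]))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname writeDataset
#' @param dir directory containing `manifest.csv` and the trace files.
#' @export
readDataset <- function(dir) {
  manifestPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manifestPath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(manifestPath)
  FallDataset(lapply(file.path(dir, manifest$file), readTrialCsv))
}
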