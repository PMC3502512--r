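# Delimited-text session writer/reader.
#
# One file per channel per recording: a small commented header (subject, arm,
# condition, channel, role, sampling rate, segment geometry) followed by one
# sample per line; segment matrices are stored column-major. A YAML manifest
# ties the files to the plan. Everything is plain text so sessions round-trip
# across languages.

channel_filename <- function(subject, arm, condition, channel) {
  sprintf("s%02d_%s_%s_%s.txt", subject, arm, condition,
          gsub("[^A-Za-z0-9]", "", channel))
}

#' Write a session to a directory of delimited text files
#'
#' @param session A `tremor_session` from [generate_session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "tremor_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plan <- attr(session, "plan")
  files <- character(nrow(session))
  for (i in seq_len(nrow(session))) {
    fn <- channel_filename(session$subject[i], session$arm[i],
                           session$condition[i], session$channel[i])
    dat <- session$data[[i]]
    hdr <- c(
      sprintf("# subject: %d", session$subject[i]),
      sprintf("# arm: %s", session$arm[i]),
      sprintf("# condition: %s", session$condition[i]),
      sprintf("# channel: %s", session$channel[i]),
      sprintf("# role: %s", session$role[i]),
      sprintf("# sampling_rate: %.10g", plan$sampling_rate),
      sprintf("# n_rows: %d", if (is.matrix(dat)) nrow(dat) else length(dat)),
      sprintf("# n_segments: %d", if (is.matrix(dat)) ncol(dat) else 1L))
    path <- file.path(dir, fn)
    writeLines(hdr, path)
    con <- file(path, open = "a")
    writeLines(format(as.vector(dat), digits = 17, scientific = TRUE,
                      trim = TRUE), con)
    close(con)
    files[i] <- fn
  }
  manifest <- list(
    plan = list(
      n_subjects = plan$n_subjects, muscles = plan$muscles,
      n_trials = plan$n_trials, sections_per_trial = plan$sections_per_trial,
      sampling_rate = plan$sampling_rate,
      segment_length = plan$segment_length,
      accel_duration = plan$accel_duration,
      subject_spread = plan$subject_spread, seed = plan$seed,
      arms = lapply(plan$arms, unclass)),
    files = files)
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

read_channel_file <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  vals <- as.numeric(lines[-hdr_idx])
  n_rows <- as.integer(get("n_rows"))
  n_seg <- as.integer(get("n_segments"))
  dat <- if (n_seg > 1) matrix(vals, n_rows, n_seg) else vals
  tibble(subject = as.integer(get("subject")), arm = get("arm"),
         condition = get("condition"), channel = get("channel"),
         role = get("role"), data = list(dat))
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the channel files and `manifest.yaml`.
#' @return A `tremor_session` tibble.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath)) abort("no manifest.yaml in `dir`.")
  manifest <- yaml::read_yaml(mpath)
  p <- manifest$plan
  plan <- session_plan(
    n_subjects = p$n_subjects, muscles = unlist(p$muscles),
    n_trials = p$n_trials, sections_per_trial = p$sections_per_trial,
    sampling_rate = p$sampling_rate, segment_length = p$segment_length,
    accel_duration = p$accel_duration,
    arms = lapply(p$arms, function(a) do.call(drug_effect, a)),
    subject_spread = p$subject_spread, seed = p$seed)
  out <- bind_rows(lapply(file.path(dir, unlist(manifest$files)),
                          read_channel_file))
  attr(out, "plan") <- plan
  class(out) <- c("tremor_session", class(out))
  out
}
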