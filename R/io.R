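# Plain-text interchange: gait profiles, afferent rate series and spike
# rasters travel as CSV so runs can be archived and re-fed.

#' Write / read a gait profile as CSV
#'
#' Columns `t, stretch, stretch_velocity, emg_env`; muscle, cycle duration
#' and stance fraction are stored in a `# key: value` comment header.
#'
#' @param profile a `gait_profile`.
#' @param path file path.
#' @return `read_gait_csv` returns a `gait_profile`.
#' @export
write_gait_csv <- function(profile, path) {
  hdr <- c(
    sprintf("# muscle: %s", attr(profile, "muscle")),
    sprintf("# cycle_duration: %s", attr(profile, "cycle_duration")),
    sprintf("# stance_fraction: %s", attr(profile, "stance_fraction"))
  )
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(profile)[c("t", "stretch", "stretch_velocity", "emg_env")],
    path, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_gait_csv
#' @export
read_gait_csv <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(key, hdr, value = TRUE)[1])
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(out, "muscle") <- get("muscle")
  attr(out, "cycle_duration") <- as.numeric(get("cycle_duration"))
  attr(out, "stance_fraction") <- as.numeric(get("stance_fraction"))
  attr(out, "fs") <- GAIT_FS
  class(out) <- c("gait_profile", class(out))
  out
}

#' Write / read a spike raster as a two-column-per-population event table
#'
#' @param raster a `spike_raster`.
#' @param path file path.
#' @return `read_raster_csv` returns a `spike_raster`.
#' @export
write_raster_csv <- function(raster, path) {
  sizes <- attr(raster, "pop_sizes")
  hdr <- sprintf("# pop_sizes: %s",
                 paste(sprintf("%s=%d", names(sizes), sizes), collapse = ";"))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(raster), path, sep = ",", row.names = FALSE,
    append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- grep("^# pop_sizes", readLines(path, n = 2), value = TRUE)
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  if (length(hdr)) {
    kv <- strsplit(sub("^# pop_sizes: ", "", hdr), ";")[[1]]
    parts <- strsplit(kv, "=")
    attr(out, "pop_sizes") <- setNames(
      as.integer(vapply(parts, `[`, "", 2)),
      vapply(parts, `[`, "", 1))
  }
  class(out) <- c("spike_raster", class(out))
  out
}
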