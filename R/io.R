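# Delimited-table interchange formats for marker, force, and respirometry
# traces: a CSV body plus a JSON header sidecar.

#' Write and read marker trajectory sets
#'
#' The table holds `t` plus three columns (`<marker>_x/_y/_z`) per marker;
#' the JSON sidecar records the sampling rate, marker roles, and standing
#' reference heights.
#'
#' @param ms a [marker_set()]
#' @param path output CSV path; the sidecar is written to `<path>.json`
#' @return `path`, invisibly
#' @export
write_markers <- function(ms, path) {
  cols <- do.call(cbind, lapply(ms$markers, function(m) m[, 1:3]))
  colnames(cols) <- as.vector(vapply(
    names(ms$markers), function(nm) paste(nm, c("x", "y", "z"), sep = "_"),
    character(3L)
  ))
  data.table::fwrite(data.frame(t = ms$t, cols, check.names = FALSE), path)
  jsonlite::write_json(
    list(rate = ms$rate, markers = names(ms$markers),
         standing_heights = as.list(ms$standing_heights), units = "m"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_markers
#' @export
load_markers <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(path)
  markers <- lapply(meta$markers, function(nm) {
    m <- as.matrix(dt[, paste(nm, c("x", "y", "z"), sep = "_"), with = FALSE])
    colnames(m) <- c("x", "y", "z")
    m
  })
  names(markers) <- meta$markers
  marker_set(dt$t, markers, meta$rate, unlist(meta$standing_heights))
}

#' Write and read force-plate traces
#'
#' @param trace a [force_trace()]
#' @param path output CSV path; the sidecar is written to `<path>.json`
#' @return `path`, invisibly
#' @export
write_forces <- function(trace, path) {
  data.table::fwrite(
    data.frame(t = trace$t, Fx = trace$Fx, Fy = trace$Fy, Fz = trace$Fz),
    path
  )
  jsonlite::write_json(
    list(rate = trace$rate, baseline_idx = range(trace$baseline_idx),
         units = "N"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_forces
#' @export
load_forces <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(path)
  force_trace(dt$t, dt$Fx, dt$Fy, dt$Fz, meta$rate,
              seq(meta$baseline_idx[1L], meta$baseline_idx[2L]))
}
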