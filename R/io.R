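#' Write a recording (and optional ground truth) to a container file
#'
#' The container is a versioned RDS schema holding the voltage matrix
#' (microvolts), sampling metadata, geometry, condition labels and — when
#' present — the simulator's ground truth. Round-trips are lossless and
#' bit-exact.
#'
#' @param x a `vh_segment`, or a list with elements `segment` and (optional)
#'   `truth` as returned by [render_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  if (inherits(x, "vh_segment")) x <- list(segment = x, truth = NULL)
  if (!inherits(x$segment, "vh_segment"))
    stop("format error: no vh_segment to write")
  saveRDS(list(schema = "vhmea-recording/1", segment = x$segment,
               truth = x$truth), path)
  invisible(path)
}

#' Read a recording container
#'
#' @param path file written by [write_recording()].
#' @return List with `segment` and `truth` (`NULL` when the file carries no
#'   ground truth).
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("format error: not a vhmea recording container"))
  if (!is.list(obj) || !identical(obj$schema, "vhmea-recording/1"))
    stop("format error: missing or unsupported schema field")
  seg <- obj$segment
  if (is.null(seg$samples)) stop("format error: missing field 'samples'")
  if (is.null(seg$fs) || !is.finite(seg$fs) || seg$fs <= 0)
    stop("format error: invalid field 'fs'")
  list(segment = seg, truth = obj$truth)
}

#' Write a spike-event table as CSV
#'
#' Columns: electrode, t_s, amp_uv, polarity.
#'
#' @param events event data.frame (e.g. `detect_segment(...)$events`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write the planted-unit manifest of a ground truth as CSV
#'
#' Columns: electrode, unit_id, rate_hz, n_spikes.
#'
#' @param truth a `vh_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_manifest <- function(truth, path) {
  rows <- list()
  for (e in seq_along(truth$units)) {
    ul <- truth$units[[e]]
    if (is.null(ul)) next
    for (u in ul) {
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = e, unit_id = u$unit_id, rate_hz = u$rate_hz,
        n_spikes = length(u$spike_times))
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
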