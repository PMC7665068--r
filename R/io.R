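#' Write traces to a long-format CSV
#'
#' Columns `trace_id,frame,intensity` plus `state` when ground truth is
#' present; `frame` is 0-based. Intensities are written in raw units.
#'
#' @param data a `trace_dataset` or list of numeric traces.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(data, path) {
  recs <- if (inherits(data, "trace_dataset")) data$records
          else lapply(data, function(x) list(intensities = as.numeric(x),
                                             states = NULL))
  has_states <- all(vapply(recs, function(r) !is.null(r$states), TRUE))
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    d <- data.frame(trace_id = i, frame = seq_along(r$intensities) - 1L,
                    intensity = r$intensities)
    if (has_states) d$state <- as.integer(r$states)
    d
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' Accepts the long format written by [write_traces()] (`trace_id` column)
#' or a single-trace file with `frame,intensity[,state]`.
#'
#' @param path CSV path.
#' @param frame_interval seconds per frame to attach to the dataset.
#' @return A `trace_dataset` (splits unassigned, mode `"unknown"` unless a
#'   manifest supplies one).
#' @export
read_traces <- function(path, frame_interval = 0.1) {
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(raw) == 0L) stop("empty trace file: ", path)
  need <- c("frame", "intensity")
  if (!all(need %in% names(raw)))
    stop("malformed header in ", path,
         ": need columns frame,intensity[,state][,trace_id]")
  for (col in intersect(c("frame", "intensity", "state"), names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", col, "' near line ", bad + 1L,
           " of ", path)
    }
  }
  ids <- if ("trace_id" %in% names(raw)) raw$trace_id else 1L
  recs <- lapply(split(raw, ids), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    list(intensities = d$intensity,
         states = if ("state" %in% names(d)) as.integer(d$state) else NULL,
         split = NA_character_)
  })
  names(recs) <- NULL
  s_max <- if ("state" %in% names(raw)) max(raw$state) else NA_integer_
  structure(list(records = recs, mode = "unknown", s_max = s_max,
                 frame_interval = frame_interval, unit_intensity = NA_real_,
                 noise = NULL, target_asnr = NA_real_,
                 achieved_asnr = NA_real_, seed = NA_integer_,
                 split_fractions = NULL),
            class = "trace_dataset")
}

#' Write or read a dataset bundle (traces CSV + JSON manifest)
#'
#' The manifest records mode, state cardinality, frame interval, noise
#' parameters, seed, achieved aSNR and the per-record split tags, so a
#' bundle round-trips to an identical dataset.
#'
#' @param data a `trace_dataset`.
#' @param dir directory for `traces.csv` and `manifest.json`.
#' @return `read_dataset` returns the `trace_dataset`; `write_dataset` the
#'   directory, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "trace_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traces(data, file.path(dir, "traces.csv"))
  manifest <- list(
    mode = data$mode, s_max = data$s_max,
    frame_interval = data$frame_interval,
    unit_intensity = data$unit_intensity, noise = data$noise,
    target_asnr = data$target_asnr, achieved_asnr = data$achieved_asnr,
    seed = data$seed, split_fractions = data$split_fractions,
    splits = vapply(data$records, `[[`, "", "split"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  data <- read_traces(file.path(dir, "traces.csv"),
                      frame_interval = mf$frame_interval)
  for (i in seq_along(data$records)) data$records[[i]]$split <- mf$splits[i]
  data$mode <- mf$mode
  data$s_max <- as.integer(mf$s_max)
  data$unit_intensity <- mf$unit_intensity
  data$noise <- mf$noise
  data$target_asnr <- mf$target_asnr
  data$achieved_asnr <- mf$achieved_asnr
  data$seed <- mf$seed
  data$split_fractions <- mf$split_fractions
  data
}
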