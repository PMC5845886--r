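#' @title Video and result input/output
#' @description Reading and writing [video_tensor]s as npy arrays with a JSON
#' metadata sidecar (`<file>.json` holding `dt` and `t0`), writing retina
#' outputs one npy per stage, and spike-event CSV lists.
#' @name video-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Write a video tensor to an npy file plus JSON metadata sidecar
#'
#' @param video a [video_tensor].
#' @param path output `.npy` path; `dt`/`t0` go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_tensor"))
  write_npy(video$values, path)
  jsonlite::write_json(list(dt = video$dt, t0 = video$t0), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a video tensor from an npy file
#'
#' 3-D arrays are wrapped via [wrap_video()]; 5-D arrays are taken as-is.
#' `dt` comes from the JSON sidecar when present, else from the argument.
#'
#' @param path path to a `.npy` file.
#' @param dt frame duration in seconds; required when no sidecar exists.
#' @return a [video_tensor].
#' @export
read_video <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- read_npy(path)
  r <- length(dim(vals))
  if (!(r %in% c(3L, 5L))) {
    stop("expected a 3-D or 5-D array, found shape (",
         paste(dim(vals), collapse = ","), ")")
  }
  t0 <- 0
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(dt)) dt <- meta$dt
    if (!is.null(meta$t0)) t0 <- meta$t0
  }
  if (is.null(dt)) {
    stop("no dt available for ", path,
         ": pass dt= or provide a ", basename(sc), " sidecar")
  }
  video_tensor(vals, dt = dt, t0 = t0)
}

#' Write retina outputs (or one video tensor) to disk
#'
#' Each stage becomes `<prefix>_<stage>.npy` with its metadata sidecar; spike
#' rasters are additionally written as CSV event lists
#' (`unit_x, unit_y, channel, time_s`).
#'
#' @param outputs a `retina_outputs` object or a single [video_tensor].
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(outputs, prefix) {
  files <- character(0)
  if (inherits(outputs, "video_tensor")) {
    p <- paste0(prefix, ".npy")
    write_video(outputs, p)
    return(invisible(p))
  }
  for (nm in names(outputs)) {
    p <- paste0(prefix, "_", nm, ".npy")
    write_video(outputs[[nm]], p)
    files <- c(files, p)
    if (startsWith(nm, "spikes")) {
      pc <- paste0(prefix, "_", nm, ".csv")
      utils::write.csv(spike_events(outputs[[nm]]), pc, row.names = FALSE)
      files <- c(files, pc)
    }
  }
  invisible(files)
}
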