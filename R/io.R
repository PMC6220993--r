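#' Persist an epoch collection to a JSON container
#'
#' Single-file plain-text container holding the data array (row-major
#' nested lists), labels, condition, time axis, sampling rate, channel
#' metadata and event times. Intended for small fixtures and pipeline
#' hand-off, not bulk storage.
#'
#' @param x An `epoch_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_collection"))
  payload <- list(
    container = "tgdecode-epochs-v1",
    dims = dim(x$data),
    data = as.vector(x$data),
    labels = x$labels,
    condition = x$condition,
    times = x$times,
    sfreq = x$sfreq,
    channel_types = x$channel_types,
    event_times = x$event_times,
    positive_label = x$positive_label)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch collection from a JSON container
#'
#' @param path File written by [write_epochs()].
#' @return An `epoch_collection`.
#' @export
read_epochs <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "tgdecode-epochs-v1")) {
    stop("not a tgdecode epochs container", call. = FALSE)
  }
  pos <- p$positive_label
  if (length(pos) == 0L) pos <- NULL     # JSON null round-trips as empty
  epoch_collection(array(p$data, dim = p$dims), p$labels, p$condition,
                   p$times, p$sfreq, p$channel_types, p$event_times, pos)
}
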