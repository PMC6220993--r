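#' Physical unit scale per channel type
#'
#' Sensor signals are simulated at realistic native magnitudes so that the
#' absolute-amplitude rejection thresholds (12,000 fT / 4,000 fT/cm / 150 uV)
#' are meaningful: magnetometers in fT, planar gradiometers in fT/cm, EEG in
#' uV. The values are the sensor-space magnitude produced by a unit source
#' amplitude.
#'
#' @return Named numeric vector with elements `mag`, `grad`, `eeg`.
#' @export
channel_type_scales <- function() {
  c(mag = 300, grad = 100, eeg = 10)
}

default_channel_types <- function(n_channels) {
  rep_len(c("mag", "grad", "eeg"), n_channels)
}

#' Synthetic forward model (lead field)
#'
#' Generates a channels x sources gain matrix standing in for a boundary
#' element forward solution. Within each channel-type block the source
#' columns are orthonormalized (when the block has at least `n_sources`
#' channels) and then scaled to the native unit magnitude of that type, so
#' each column has unit norm after per-type rescaling. Source positions lie
#' on a unit-hemisphere grid (z >= 0), which supports localization tests
#' without any anatomy. Two auxiliary "tangential" gain columns per source
#' (orthogonal within the source triplet) are stored for the loose
#' orientation constraint of the dSPM-style inverse.
#'
#' @param n_channels Number of sensors (>= `n_sources`).
#' @param n_sources Number of sources (>= 1).
#' @param seed Integer seed; the model is bit-reproducible in it.
#' @param channel_types Optional character vector of per-channel types in
#'   `c("mag","grad","eeg")`; defaults to a cyclic mix of all three.
#' @return An object of class `forward_model` with fields `gain`
#'   (channels x sources), `aux_gain` (channels x sources x 2),
#'   `channel_types`, `source_positions` (sources x 3), `seed`.
#' @export
make_forward_model <- function(n_channels, n_sources, seed,
                               channel_types = NULL) {
  if (!is.numeric(n_channels) || !is.numeric(n_sources) ||
      n_sources < 1 || n_channels < n_sources) {
    stop("invalid dimensions: need n_channels >= n_sources >= 1",
         call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  n_sources <- as.integer(n_sources)
  if (is.null(channel_types)) channel_types <- default_channel_types(n_channels)
  if (length(channel_types) != n_channels ||
      !all(channel_types %in% c("mag", "grad", "eeg"))) {
    stop("`channel_types` must be length n_channels with values mag/grad/eeg",
         call. = FALSE)
  }
  scales <- channel_type_scales()

  with_seed(seed, {
    # 3 orientation columns per source: column 1 is the "normal" gain used by
    # the generative model, columns 2-3 are auxiliary tangential directions.
    raw <- array(stats::rnorm(n_channels * n_sources * 3L),
                 dim = c(n_channels, n_sources, 3L))
    types_present <- unique(channel_types)
    n_blocks <- length(types_present)
    for (ty in types_present) {
      rows <- which(channel_types == ty)
      for (k in 1:3) {
        block <- raw[rows, , k, drop = FALSE]
        dim(block) <- c(length(rows), n_sources)
        if (length(rows) >= n_sources) {
          block <- qr.Q(qr(block))[, seq_len(n_sources), drop = FALSE]
        } else {
          block <- sweep(block, 2L, sqrt(colSums(block^2)), "/")
        }
        # each column: norm 1/sqrt(n_blocks) per block -> unit norm overall
        raw[rows, , k] <- block / sqrt(n_blocks) * scales[[ty]]
      }
    }
    # hemisphere grid positions (z >= 0), deterministic Fibonacci-style layout
    i <- seq_len(n_sources)
    golden <- (1 + sqrt(5)) / 2
    z <- (i - 0.5) / n_sources            # heights in (0, 1)
    phi <- 2 * pi * i / golden
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)

    structure(
      list(gain = raw[, , 1L, drop = TRUE],
           aux_gain = raw[, , 2:3, drop = FALSE],
           channel_types = channel_types,
           source_positions = pos,
           seed = as.integer(seed)),
      class = "forward_model")
  })
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d channels x %d sources (%s)\n",
              nrow(x$gain), ncol(x$gain),
              paste(sprintf("%d %s", table(x$channel_types),
                            names(table(x$channel_types))), collapse = ", ")))
  invisible(x)
}

#' Transient evoked source component
#'
#' Describes one class-sensitive evoked generator: a Gaussian temporal
#' envelope at a fixed source, with per-class amplitude. Sharing
#' `source_index` across conditions (possibly at different latencies) is how
#' cross-condition source overlap is controlled.
#'
#' @param source_index 1-based index into the forward model's sources.
#' @param latency Peak time in seconds.
#' @param width SD of the Gaussian temporal envelope, seconds (> 0).
#' @param amplitude_by_class Named numeric vector mapping class label to
#'   source amplitude (in unit source amplitude, see
#'   [channel_type_scales()]).
#' @param conditions Character vector of condition tags in which the
#'   component is active; `NULL` means active in every condition.
#' @return A `source_component` object.
#' @export
source_component <- function(source_index, latency, width,
                             amplitude_by_class, conditions = NULL) {
  stopifnot_scalar_num(width, "width", lower = 0, strict_lower = TRUE)
  if (is.null(names(amplitude_by_class)) || !is.numeric(amplitude_by_class)) {
    stop("`amplitude_by_class` must be a named numeric vector", call. = FALSE)
  }
  structure(list(source_index = as.integer(source_index),
                 latency = latency, width = width,
                 amplitude_by_class = amplitude_by_class,
                 conditions = conditions),
            class = "source_component")
}

#' Structured sensor-noise specification
#'
#' Noise is spatially mixed AR(1) Gaussian (rank-limited random mixing)
#' plus an optional 10-Hz background sinusoid with random phase per trial —
#' the minimal model with both temporal and spatial correlation.
#'
#' @param sensor_sd_by_type Named numeric vector of per-type noise SD in
#'   native units (fT, fT/cm, uV).
#' @param ar_coefficient AR(1) coefficient in [0, 1).
#' @param spatial_mixing_rank Rank of the spatial mixing matrix.
#' @param alpha_amplitude Amplitude of the 10-Hz background in unit source
#'   amplitude (>= 0).
#' @param seed Integer seed for the mixing matrix.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sensor_sd_by_type = c(mag = 300, grad = 100, eeg = 10),
                       ar_coefficient = 0.5, spatial_mixing_rank = 8,
                       alpha_amplitude = 0, seed = 1) {
  if (any(sensor_sd_by_type < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  stopifnot_scalar_num(ar_coefficient, "ar_coefficient", 0, 1,
                       strict_upper = TRUE)
  stopifnot_scalar_num(alpha_amplitude, "alpha_amplitude", 0)
  structure(list(sensor_sd_by_type = sensor_sd_by_type,
                 ar_coefficient = ar_coefficient,
                 spatial_mixing_rank = as.integer(spatial_mixing_rank),
                 alpha_amplitude = alpha_amplitude,
                 seed = as.integer(seed)),
            class = "noise_spec")
}
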