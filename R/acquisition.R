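#' Acquisition template for a time-gated FLIM stack
#'
#' Describes the temporal and spatial geometry of one field-of-view (FOV)
#' acquisition: the excitation repetition period, the gate width, the ordered
#' gate delays, the role of each temporal frame, and the frame geometry.
#'
#' A frame's role is either `"prebleach"` (frames acquired before the FLIM
#' series to photobleach cellular autofluorescence; they contribute to the
#' integrated intensity image but are never used for lifetime fitting) or
#' `"flim"` (the gate-delay series the decay is fitted to). All prebleach
#' frames are acquired at delay 0, i.e. with the gate on the decay peak.
#'
#' @param period_ns Excitation repetition period in ns (default 12.5 ns,
#'   i.e. an 80 MHz pulsed source).
#' @param gate_width_ns Gate duration in ns (default 4 ns).
#' @param delays_ns Ordered gate delays (ns) of the FLIM frames; must be
#'   strictly increasing and contain at least 3 values (the minimum to fit
#'   amplitude and lifetime and still check residuals).
#' @param n_prebleach Number of prebleach frames preceding the FLIM series
#'   (default 5).
#' @param frame_shape Integer vector `c(rows, cols)` (default `c(336, 256)`).
#' @param pixel_size_nm Projected pixel pitch in nm (default 615).
#'
#' @return An object of class `acq_template` with fields `period_ns`,
#'   `gate_width_ns`, `delays_ns`, `frame_roles`, `frame_delays_ns`,
#'   `frame_shape`, `pixel_size_nm`, `n_frames`.
#' @export
#' @examples
#' tpl <- acq_template()
#' tpl$n_frames                     # 12 = 5 prebleach + 7 flim
#' tpl$delays_ns                    # the 7 FLIM gate delays
acq_template <- function(period_ns = 12.5,
                         gate_width_ns = 4,
                         delays_ns = c(0, 1, 2, 3, 4, 6, 8),
                         n_prebleach = 5,
                         frame_shape = c(336L, 256L),
                         pixel_size_nm = 615) {
  stopifnot(is.numeric(period_ns), length(period_ns) == 1L, period_ns > 0)
  if (!(gate_width_ns > 0 && gate_width_ns <= period_ns)) {
    stop("gate_width_ns must lie in (0, period_ns]")
  }
  delays_ns <- as.numeric(delays_ns)
  if (length(delays_ns) < 3L) {
    stop("at least 3 FLIM gate delays are required to fit amplitude and ",
         "lifetime with a residual check")
  }
  if (any(diff(delays_ns) <= 0)) {
    stop("delays_ns must be strictly increasing")
  }
  if (any(delays_ns < 0) || any(delays_ns >= period_ns)) {
    stop("delays_ns must lie in [0, period_ns)")
  }
  n_prebleach <- as.integer(n_prebleach)
  stopifnot(n_prebleach >= 0L)
  frame_shape <- as.integer(frame_shape)
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 1L))

  roles <- c(rep("prebleach", n_prebleach), rep("flim", length(delays_ns)))
  frame_delays <- c(rep(0, n_prebleach), delays_ns)
  structure(
    list(
      period_ns = period_ns,
      gate_width_ns = gate_width_ns,
      delays_ns = delays_ns,
      frame_roles = roles,
      frame_delays_ns = frame_delays,
      frame_shape = frame_shape,
      pixel_size_nm = pixel_size_nm,
      n_frames = length(roles)
    ),
    class = "acq_template"
  )
}

#' @export
print.acq_template <- function(x, ...) {
  cat("<acq_template>", x$n_frames, "frames (",
      sum(x$frame_roles == "prebleach"), "prebleach +",
      sum(x$frame_roles == "flim"), "flim ), period",
      x$period_ns, "ns, gate", x$gate_width_ns, "ns\n")
  cat("  delays (ns):", paste(x$delays_ns, collapse = ", "), "\n")
  cat("  frame shape:", x$frame_shape[1], "x", x$frame_shape[2],
      " pixel", x$pixel_size_nm, "nm\n")
  invisible(x)
}

is_acq_template <- function(x) inherits(x, "acq_template")

#' Indices of FLIM frames in a template
#' @param template An `acq_template`.
#' @return Integer indices (1-based, acquisition order) of the FLIM frames.
#' @export
flim_frames <- function(template) {
  which(template$frame_roles == "flim")
}

#' Read or write an acquisition template as YAML
#'
#' @param path File path.
#' @param template An `acq_template` (for writing).
#' @return `read_acq_template` returns an `acq_template`;
#'   `write_acq_template` returns `path` invisibly.
#' @export
read_acq_template <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("period_ns", "gate_width_ns", "delays_ns")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("acquisition template ", path, " is missing fields: ",
         paste(miss, collapse = ", "))
  }
  acq_template(
    period_ns = cfg$period_ns,
    gate_width_ns = cfg$gate_width_ns,
    delays_ns = unlist(cfg$delays_ns),
    n_prebleach = cfg$n_prebleach %||% 0L,
    frame_shape = unlist(cfg$frame_shape %||% c(336L, 256L)),
    pixel_size_nm = cfg$pixel_size_nm %||% 615
  )
}

#' @rdname read_acq_template
#' @export
write_acq_template <- function(template, path) {
  stopifnot(is_acq_template(template))
  yaml::write_yaml(
    list(
      period_ns = template$period_ns,
      gate_width_ns = template$gate_width_ns,
      delays_ns = template$delays_ns,
      n_prebleach = sum(template$frame_roles == "prebleach"),
      frame_shape = as.integer(template$frame_shape),
      pixel_size_nm = template$pixel_size_nm
    ),
    path
  )
  invisible(path)
}
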