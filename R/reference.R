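#' Reference-dye decay
#'
#' A finely sampled gated decay of a dye of known monoexponential lifetime,
#' the carrier of the instrument-response information used by reference
#' reconvolution. The canonical acquisition samples the whole excitation
#' period at 25 ps intervals (e.g. Coumarin 6 in ethanol as the primary
#' reference; heavily iodide-quenched fluorescein, lifetime ~0.1 ns, as the
#' short-lifetime reference used for time-origin QC).
#'
#' @param times_ns Uniform sample grid in ns spanning `[0, period_ns)`.
#' @param values Decay samples (DN), nonnegative.
#' @param tau_ref_ns Known reference lifetime in ns (> 0).
#' @param period_ns Excitation period (ns), default 12.5.
#' @return An object of class `reference_decay`.
#' @export
reference_decay <- function(times_ns, values, tau_ref_ns, period_ns = 12.5) {
  times_ns <- as.numeric(times_ns)
  values <- as.numeric(values)
  stopifnot(length(times_ns) == length(values), length(times_ns) >= 4L)
  dts <- diff(times_ns)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1]) {
    stop("reference grid must be uniform")
  }
  if (abs(times_ns[1]) > 1e-12 || times_ns[length(times_ns)] >= period_ns) {
    stop("reference grid must span [0, period_ns)")
  }
  if (abs(length(times_ns) * dts[1] - period_ns) > 1e-6 * period_ns) {
    stop("reference grid must tile the period exactly")
  }
  if (any(values < 0)) stop("reference values must be nonnegative")
  if (!(tau_ref_ns > 0)) stop("tau_ref_ns must be positive")
  structure(
    list(times_ns = times_ns, values = values, tau_ref_ns = tau_ref_ns,
         period_ns = period_ns, dt_ns = dts[1]),
    class = "reference_decay"
  )
}

is_reference_decay <- function(x) inherits(x, "reference_decay")

#' @export
print.reference_decay <- function(x, ...) {
  cat("<reference_decay> tau_ref =", x$tau_ref_ns, "ns,",
      length(x$values), "samples at", x$dt_ns * 1000, "ps over",
      x$period_ns, "ns\n")
  invisible(x)
}

#' Read or write a reference decay as two-column text
#'
#' The format is plain text: comment header lines `# tau_ref_ns: <x>` and
#' `# period_ns: <x>`, then two whitespace-separated columns
#' `time_ns value_dn`.
#'
#' @param path File path.
#' @param ref A `reference_decay` (for writing).
#' @return `read_reference_decay` returns a `reference_decay`;
#'   `write_reference_decay` returns `path` invisibly.
#' @export
read_reference_decay <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("reference file ", path, " lacks '# ", key, ":' header")
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1]))
  }
  tau_ref <- get_num("tau_ref_ns")
  period <- get_num("period_ns")
  tab <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("time_ns", "value_dn"))
  reference_decay(tab$time_ns, tab$value_dn, tau_ref, period)
}

#' @rdname read_reference_decay
#' @export
write_reference_decay <- function(ref, path) {
  stopifnot(is_reference_decay(ref))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# tau_ref_ns: ", format(ref$tau_ref_ns, digits = 15)),
    paste0("# period_ns: ", format(ref$period_ns, digits = 15))
  ), con)
  utils::write.table(
    data.frame(time_ns = ref$times_ns, value_dn = ref$values),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
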