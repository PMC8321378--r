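# Classed conditions so callers can distinguish bad inputs from bad geometry.

abort_spagen <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "spagen_error"), call = call))
}

abort_io <- function(msg) abort_spagen(msg, "spagen_io_error")
abort_degenerate <- function(msg) abort_spagen(msg, "spagen_degenerate_mask_error")
abort_geometry <- function(msg) abort_spagen(msg, "spagen_geometry_error")
abort_input <- function(msg) abort_spagen(msg, "spagen_input_error")
abort_numeric <- function(msg) abort_spagen(msg, "spagen_numeric_error")

warn_spagen <- function(msg, class = "spagen_warning") {
  warning(warningCondition(msg, class = c(class, "spagen_warning")))
}
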