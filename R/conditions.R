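## Categorized error conditions. Every domain error raised by the package
## carries one of these classes so callers (and the CLI) can map failures to
## an error category without parsing messages.

pmrStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pmr_error")))
}

pmrFormatError     <- function(msg) pmrStop("pmr_format_error", msg)
pmrBoundsError     <- function(msg) pmrStop("pmr_bounds_error", msg)
pmrCountError      <- function(msg) pmrStop("pmr_count_error", msg)
pmrGeometryError   <- function(msg) pmrStop("pmr_geometry_error", msg)
pmrShapeError      <- function(msg) pmrStop("pmr_shape_error", msg)
pmrInputError      <- function(msg) pmrStop("pmr_input_error", msg)
pmrDegenerateError <- function(msg) pmrStop("pmr_degenerate_error", msg)
pmrMetricError     <- function(msg) pmrStop("pmr_metric_error", msg)
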