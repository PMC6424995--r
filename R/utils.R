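#' @importFrom rlang abort warn inform .data :=
#' @importFrom dplyr %>%
#' @importFrom generics tidy glance
NULL

# internal: error for a bad user-supplied field, naming it
config_abort <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "hopperqtl_config_error")
}

data_abort <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hopperqtl_data_error")
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
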