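# re-exported generics so cellsig objects work with the broom verbs
# and ggplot2::autoplot without attaching those packages explicitly

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot
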