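#' Re-exported generics
#'
#' `tidy()` and `glance()` from the generics package and `autoplot()` from
#' ggplot2, so the package's methods are usable without attaching those
#' packages.
#'
#' @name reexports
#' @keywords internal
NULL

#' @rdname reexports
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname reexports
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname reexports
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
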