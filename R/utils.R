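#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Path to the packaged literature parameter table
#'
#' The same table as [source_table()], shipped as a CSV fixture
#' (columns `source`, `parameter`, `value`).
#'
#' @return File path of the CSV.
#' @export
source_table_path <- function() {
  system.file("extdata", "table1_sources.csv", package = "tcellkpr",
              mustWork = TRUE)
}
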