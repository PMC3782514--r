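#' Bundled reference tables for the wheat Rht-1 homologous regions
#'
#' Published summary tables for the Rht-1 homologous BAC regions of diploid,
#' tetraploid and hexaploid wheat and related grasses, bundled as plain-text
#' TSVs. They serve as worked-example inputs: conservation sizes
#' (`"conservation"`), per-gene substitution rates (`"gene_rates"`), the
#' two-gene clock inputs with printed divergence times (`"clock_rates"`), and
#' colinear LTR retroelement substitution rates with printed ages
#' (`"ltr_rates"`).
#'
#' @param name One of `"conservation"`, `"gene_rates"`, `"clock_rates"`,
#'   `"ltr_rates"`.
#' @return A data.frame.
#' @export
reference_table <- function(name = c("conservation", "gene_rates",
                                     "clock_rates", "ltr_rates")) {
  name <- match.arg(name)
  path <- system.file("extdata", sprintf("wheat_rht1_%s.tsv", name),
                      package = "syntevol", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
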