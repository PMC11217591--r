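#' @keywords internal
#' @import data.table
#' @importFrom stats aov kruskal.test p.adjust cmdscale cor.test wilcox.test
#'   rbeta rnorm runif rpois rlnorm pnorm setNames as.formula complete.cases
#'   median var dist as.dist
#' @importFrom utils read.table write.table
"_PACKAGE"

.datatable.aware <- TRUE
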