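#' @importFrom stats sd chisq.test wilcox.test kruskal.test rnorm
#' @importFrom utils head read.csv
NULL
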