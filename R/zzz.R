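#' @importFrom stats dist median rank runif rnorm sd setNames uniroot
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom methods new is validObject
NULL
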