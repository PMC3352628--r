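#' @importFrom jsonlite read_json write_json
#' @importFrom stats approx filter rnorm
#' @importFrom utils packageVersion write.csv write.table
NULL
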