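#' Build the zero-shot prompt bank
#'
#' One sentence per class for every categorical (and multi-label) feature via
#' the template `"This nodule {feature} is {class}."`, and for every binary
#' feature a positive sentence `"There is {feature}."` paired with the shared
#' negative sentence `"No findings."`.
#'
#' @param schema A `semantic_schema`.
#' @return Object of class `prompt_bank`: named list, one entry per feature,
#'   each a named character vector of prompts (names = class labels, or
#'   `present`/`absent` for binaries).
#' @export
build_prompts <- function(schema = default_schema()) {
  bank <- lapply(schema$features, function(ft) {
    if (ft$type == "binary") {
      c(present = paste0("There is ", ft$display, "."),
        absent = "No findings.")
    } else {
      stats::setNames(
        paste0("This nodule ", ft$display, " is ", ft$classes, "."),
        ft$classes
      )
    }
  })
  structure(bank, class = "prompt_bank")
}
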