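#' Reference separability statistics for three CNN backbones
#'
#' Per-crop (apple, corn, grape, rice) in-category distance, between-
#' categories distance, feature-extraction performance and ensemble weight
#' reported for pooling-layer embeddings of VGG11, ResNet18 and
#' MobileNet_v3 trained on leaf-disease images. Useful as a desk-check of
#' the FEP and weight arithmetic: `bcD / icD` reproduces the `FEP` column
#' and [ensemble_weights()] on each crop's FEP triple reproduces
#' `weight_pct`, both to the printed precision.
#'
#' @return Data frame with columns `crop`, `model`, `icD`, `bcD`, `FEP`,
#'   `weight_pct`.
#' @examples
#' ref <- separability_reference()
#' apple <- ref[ref$crop == "apple", ]
#' 100 * ensemble_weights(apple$FEP, apple$model)
#' @export
separability_reference <- function() {
  utils::read.csv(system.file("extdata", "cnn_separability_reference.csv",
                              package = "elcdr"), stringsAsFactors = FALSE)
}
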