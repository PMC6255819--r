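#' Read or write a network configuration as YAML
#'
#' One YAML document per network: `input_channels`, `weight_seed`,
#' `padding`, `gram_layers` (1-based layer indices) and a `layers` sequence
#' of `{kind: conv|pool|dense, ...}` mappings. A reference VGG-19-style
#' architecture (16 conv + 3 dense weight-bearing layers) ships with the
#' package under `configs/vgg19.yaml`; it exists for layer-count parity with
#' the full-scale network and is never required for computation.
#'
#' @param path YAML file path.
#' @return `read_network_config()` returns a [network_config()];
#'   `write_network_config()` returns `path` invisibly.
#' @export
#' @examples
#' cfg <- read_network_config(reference_vgg19_path())
#' count_weight_layers(cfg)
read_network_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s': no such file", path))
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort_io(sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$layers)) abort_param("config file has no `layers` section")
  layers <- lapply(doc$layers, function(sp) {
    kind <- sp$kind %||% abort_param("layer entry is missing `kind`")
    switch(kind,
      conv = conv_layer(sp$out_channels, sp$kernel %||% 3L,
                        sp$activation %||% "relu"),
      pool = pool_layer(sp$mode %||% "avg", sp$size %||% 2L),
      dense = dense_layer(sp$out_channels, sp$activation %||% "relu"),
      abort_param(sprintf("unknown layer kind '%s'", kind)))
  })
  network_config(layers,
                 input_channels = doc$input_channels %||% 1L,
                 weight_seed = doc$weight_seed %||% 1L,
                 gram_layers = unlist(doc$gram_layers) %||% integer(),
                 padding = doc$padding %||% "zero")
}

#' @rdname read_network_config
#' @param config A [network_config()].
#' @export
write_network_config <- function(config, path) {
  if (!inherits(config, "network_config")) abort_param("`config` must be a network_config")
  doc <- list(
    input_channels = config$input_channels,
    weight_seed = config$weight_seed,
    padding = config$padding,
    gram_layers = as.list(config$gram_layers),
    layers = lapply(config$layers, unclass))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to the shipped VGG-19-style reference configuration
#' @export
reference_vgg19_path <- function() {
  system.file("configs", "vgg19.yaml", package = "mammetamer", mustWork = TRUE)
}
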