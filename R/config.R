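#' Read and write simulation configurations and trait architectures
#'
#' JSON serialization for [sim_config()] and [trait_architecture()], plus
#' the packaged demonstration configuration (a ~300-accession,
#' 1000-SNP panel with one planted architecture) used by the examples
#' and the integration tests.
#'
#' @param path JSON file path.
#' @return `read_sim_config` returns a `sim_config`;
#'   `read_trait_architecture` a `trait_architecture`;
#'   `demo_config` the packaged configuration as a list with elements
#'   `sim`, `architecture` and `pipeline`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config a `sim_config` or `trait_architecture`.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname read_sim_config
#' @export
read_trait_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch_from_list(x)
}

arch_from_list <- function(x) {
  trait_architecture(
    mu = x$mu %||% 0,
    main = if (!is.null(x$main)) as.data.frame(x$main),
    epistasis = if (!is.null(x$epistasis)) as.data.frame(x$epistasis),
    env_sd = x$env_sd %||% 0,
    gxe_sds = if (!is.null(x$gxe_sds)) unlist(x$gxe_sds),
    residual_sd = x$residual_sd %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_sim_config
#' @export
demo_config <- function() {
  x <- jsonlite::read_json(system.file("extdata", "synthetic_demo.json",
                                       package = "qtsmap"),
                           simplifyVector = TRUE)
  list(sim = do.call(sim_config, x$sim),
       architecture = arch_from_list(x$architecture),
       pipeline = x$pipeline)
}
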