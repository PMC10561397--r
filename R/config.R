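#' Read a flat experiment configuration
#'
#' Reads a YAML or JSON file of flat keys mirroring the package's field
#' names (`strategy`, `alpha1`, `alpha2`, `delta1`, `delta2`, `eta`,
#' `gamma`, `gamma12`, `sigma0_sq`, `rho`, `N`, `N_theory`, `seeds`, ...).
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @param defaults named list of fall-back values.
#' @return Named list.
#' @export
read_config <- function(path, defaults = list()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  utils::modifyList(defaults, as.list(cfg))
}
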