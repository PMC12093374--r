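#' Locate a bundled registry file
#'
#' @param name File name under `inst/extdata`.
#' @return Absolute path to the installed file.
#' @keywords internal
registry_file <- function(name) {
  path <- system.file("extdata", name, package = "bioswing")
  if (!nzchar(path)) stop("registry file not found: ", name)
  path
}

#' Load the parameter registry
#'
#' Reads the YAML parameter registry shipped with the package (equilibrium
#' constants, Henry constants, activity-model settings, organism kinetic
#' blocks, seed settings, and the k_L.a correlation constants). Individual
#' entries can be overridden with a nested list.
#'
#' @param file Path to a registry YAML file; defaults to the bundled registry.
#' @param overrides Nested list merged over the file contents (e.g.
#'   `list(organisms = list(oxidizer = list(mu_max = 0.05)))`).
#' @return A nested list with the registry contents.
#' @export
#' @examples
#' reg <- load_registry()
#' reg$equilibria$K1_carbonate
load_registry <- function(file = registry_file("parameters.yaml"),
                          overrides = NULL) {
  reg <- yaml::read_yaml(file)
  if (!is.null(overrides)) reg <- modify_list_deep(reg, overrides)
  reg
}

#' Recursively merge two lists
#' @keywords internal
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
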