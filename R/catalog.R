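# Component catalog: named specs loaded from a human-editable YAML file.

#' Load the component catalog
#'
#' Reads a catalog of syringes, tubing, mixing points and catheters from a
#' YAML file and returns typed component specs. The packaged default catalog
#' (`inst/extdata/component_catalog.yaml`) lists materials typical of a
#' neonatal/paediatric multi-infusion setup; lumen diameters and compliances
#' are documented estimates and every value can be overridden by pointing
#' `path` at an edited copy.
#'
#' @param path path to a catalog YAML file; default is the packaged catalog.
#' @return A named list with elements `syringes`, `tubing`, `mixing_points`,
#'   `catheters`, each a named list of spec objects.
#' @examples
#' cat <- component_catalog()
#' names(cat$catheters)
#' @export
component_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "component_catalog.yaml", package = "infusim")
  }
  raw <- yaml::read_yaml(path)
  out <- list(
    syringes = purrr::imap(raw$syringes, function(x, nm) {
      syringe_spec(nm, x$nominal_volume_ml, x$compliance_ml_mbar)
    }),
    tubing = purrr::imap(raw$tubing, function(x, nm) {
      tube_geometry(x$length_m, x$inner_diameter_mm)
    }),
    mixing_points = purrr::imap(raw$mixing_points, function(x, nm) {
      mixing_point_spec(nm, x$dead_volume_ml)
    }),
    catheters = purrr::imap(raw$catheters, function(x, nm) {
      catheter_spec(nm, x$french_size,
                    tube_geometry(x$length_m, x$inner_diameter_mm),
                    resistance_mbar_h_ml = x$resistance_mbar_h_ml)
    })
  )
  structure(out, class = "infusim_catalog")
}

#' Look up a component by name
#'
#' Searches all sections of the catalog for an entry with the given name and
#' returns its spec. Unknown names raise an error listing the available
#' entries.
#'
#' @param name component label, e.g. `"Premicath 1Fr"`.
#' @param catalog a catalog from [component_catalog()].
#' @return The matching spec object.
#' @examples
#' catalog_lookup("Careflow 7Fr")$french_size
#' @export
catalog_lookup <- function(name, catalog = component_catalog()) {
  for (section in catalog) {
    if (name %in% names(section)) return(section[[name]])
  }
  available <- unlist(lapply(catalog, names), use.names = FALSE)
  abort(
    sprintf("Unknown component \"%s\". Available: %s.",
            name, paste(available, collapse = ", ")),
    class = "infusim_lookup_error"
  )
}

#' @export
print.infusim_catalog <- function(x, ...) {
  cat("<infusim component catalog>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(names(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
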