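#' Read / write a section specification as YAML
#'
#' Serializes the generator parameters of a [section_spec()] so a synthetic
#' dataset's provenance can live beside its images.
#'
#' @param spec a `section_spec`.
#' @param path YAML file path.
#' @return `write_section_spec` returns `path` invisibly;
#'   `read_section_spec` returns a `section_spec`.
#' @export
write_section_spec <- function(spec, path) {
  stopifnot(inherits(spec, "section_spec"))
  keep <- c("pixel_area_um2", "implant_length_mm", "implant_thickness_mm",
            "defect_diameter_mm", "defect_depth_mm", "margin_mm",
            "image_width_px", "image_height_px", "growth_steps",
            "conduction_bias", "accept_prob", "noise_level", "seed")
  yaml::write_yaml(spec[keep], path)
  invisible(path)
}

#' @rdname write_section_spec
#' @export
read_section_spec <- function(path) {
  do.call(section_spec, yaml::yaml.load_file(path))
}
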