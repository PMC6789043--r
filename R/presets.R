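# Literature-derived presets for the synthetic generators.
#
# Each preset stores only numbers printed in the source report (group means
# from figure captions or methods text), with units and a source string per
# parameter, so every simulated ground truth is traceable. Nothing is
# interpolated from figures.

preset_param <- function(value, units, source) {
  list(value = value, units = units, source = source)
}

.cp_preset_db <- function() {
  list(
    WT_12D_GlcFA = list(
      ca_fold       = preset_param(2.03, "F/F0",            "Fig. 4e caption"),
      ca_tau        = preset_param(0.63, "s",               "Fig. 4f caption"),
      apd90         = preset_param(541,  "ms",              "Fig. 4h caption"),
      max_ocr       = preset_param(359,  "pmoles/min/cell", "Fig. 6g caption"),
      atp_production= preset_param(93,   "pmoles/min/cell", "Fig. 6h caption"),
      proton_leak   = preset_param(3.64, "pmoles/min/cell", "Fig. 6i caption")
    ),
    Mut_12D_GlcFA = list(
      ca_fold       = preset_param(1.55, "F/F0",            "Fig. 4e caption"),
      ca_tau        = preset_param(0.76, "s",               "Fig. 4f caption"),
      apd90         = preset_param(1068, "ms",              "Fig. 4h caption"),
      max_ocr       = preset_param(190,  "pmoles/min/cell", "Fig. 6g caption"),
      atp_production= preset_param(51,   "pmoles/min/cell", "Fig. 6h caption"),
      proton_leak   = preset_param(7.66, "pmoles/min/cell", "Fig. 6i caption")
    ),
    KO_12D_GlcFA = list(
      max_ocr       = preset_param(125,  "pmoles/min/cell", "Fig. 6g caption"),
      atp_production= preset_param(43,   "pmoles/min/cell", "Fig. 6h caption"),
      proton_leak   = preset_param(10.52,"pmoles/min/cell", "Fig. 6i caption")
    ),
    Mut_Glc = list(
      poincare_ratio= preset_param(4.36, "",                "Results, beat-rate variability")
    ),
    Mut_GlcFA = list(
      poincare_ratio= preset_param(3.12, "",                "Results, beat-rate variability")
    ),
    EV = list(
      twitch_force  = preset_param(24,   "nN",              "Fig. 3b caption"),
      power         = preset_param(22,   "fW",              "Fig. 3d caption"),
      cell_area     = preset_param(2389, "um^2",            "Fig. 3e caption")
    ),
    MiMaC = list(
      twitch_force  = preset_param(36,   "nN",              "Fig. 3b caption"),
      power         = preset_param(38,   "fW",              "Fig. 3d caption"),
      cell_area     = preset_param(3022, "um^2",            "Fig. 3e caption")
    )
  )
}

#' List all built-in experimental-group presets
#'
#' Presets encode published group means (calcium fold change and tau, APD90,
#' mitostress respiration metrics, Poincare ellipse axis ratios, micropost
#' twitch force and power, cell area) used as ground truth by the synthetic
#' generators. Every parameter carries units and a source citation string.
#'
#' @return A named list of `cp_preset` objects.
#' @seealso [cp_preset()], [gen_imaging()], [gen_electro()], [gen_micropost()],
#'   [gen_ocr()]
#' @export
cp_presets <- function() {
  db <- .cp_preset_db()
  out <- lapply(names(db), function(nm)
    structure(list(name = nm, parameters = db[[nm]]), class = "cp_preset"))
  names(out) <- names(db)
  out
}

#' Fetch a single preset by name
#'
#' @param name Preset name, e.g. `"WT_12D_GlcFA"`, `"Mut_12D_GlcFA"`,
#'   `"KO_12D_GlcFA"`, `"Mut_Glc"`, `"Mut_GlcFA"`, `"EV"`, `"MiMaC"`.
#' @return A `cp_preset` object with fields `name` and `parameters` (a named
#'   list of `value`/`units`/`source` triplets).
#' @export
cp_preset <- function(name) {
  if (inherits(name, "cp_preset")) return(name)
  db <- cp_presets()
  if (!name %in% names(db))
    stop(sprintf("unknown preset '%s'; see cp_presets()", name))
  db[[name]]
}

#' Look up one parameter of a preset
#'
#' @param preset A `cp_preset` object or preset name.
#' @param key Parameter name (e.g. `"ca_tau"`).
#' @return The numeric value.
#' @export
preset_value <- function(preset, key) {
  preset <- cp_preset(preset)
  p <- preset$parameters[[key]]
  if (is.null(p))
    stop(sprintf("preset '%s' has no parameter '%s'", preset$name, key))
  p$value
}

#' @export
print.cp_preset <- function(x, ...) {
  cat(sprintf("<cp_preset> %s\n", x$name))
  for (nm in names(x$parameters)) {
    p <- x$parameters[[nm]]
    cat(sprintf("  %-15s %8g %-16s [%s]\n", nm, p$value, p$units, p$source))
  }
  invisible(x)
}

#' @export
as.data.frame.cp_preset <- function(x, ...) {
  data.frame(
    preset = x$name,
    parameter = names(x$parameters),
    value = vapply(x$parameters, function(p) p$value, numeric(1)),
    units = vapply(x$parameters, function(p) p$units, character(1)),
    source = vapply(x$parameters, function(p) p$source, character(1)),
    row.names = NULL
  )
}

#' Write / read presets as YAML
#'
#' Round-trips a `cp_preset` (name, parameter values, units, sources)
#' losslessly through a YAML file.
#' @param preset A `cp_preset` object.
#' @param path File path.
#' @return `write_preset_yaml` returns `path` invisibly; `read_preset_yaml`
#'   returns the `cp_preset`.
#' @export
write_preset_yaml <- function(preset, path) {
  preset <- cp_preset(preset)
  yaml::write_yaml(list(name = preset$name, parameters = preset$parameters),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @export
read_preset_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(name = x$name, parameters = x$parameters),
            class = "cp_preset")
}
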