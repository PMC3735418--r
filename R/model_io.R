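# Plain-text model persistence. A model file is a versioned R literal
# (deparsed list) holding the derived tables, profile, normalizers and
# weights, so a scoring run is exactly reproducible from the file alone.

MODEL_FILE_VERSION <- 1L

strip_model <- function(model) {
  # drop closures/caches; everything else is plain data
  p <- model$potentials
  list(version = MODEL_FILE_VERSION,
       structure_id = model$structure_id,
       burial = unclass(p$burial),
       ssm = unclass(p$ssm),
       contact_ca = unclass(p$contact_ca),
       contact_sc = unclass(p$contact_sc),
       class_map = p$class_map,
       freq = p$freq,
       profile = unclass(model$profile),
       weights = model$weights,
       normalizers = model$normalizers,
       window = model$cache$window)
}

#' Write an energy model (or bare potential set) to a text file
#'
#' The file is a versioned plain-text R literal; it round-trips every derived
#' table, the profile, the normalizers and the weights. Model files written
#' for one target can be re-attached to the same backbone with [read_model()].
#'
#' @param x an `energy_model` or a `potential_set`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_model <- function(x, path) {
  payload <- if (inherits(x, "energy_model")) {
    c(strip_model(x), list(kind = "energy_model"))
  } else if (inherits(x, "potential_set")) {
    list(version = MODEL_FILE_VERSION, kind = "potential_set",
         burial = unclass(x$burial), ssm = unclass(x$ssm),
         contact_ca = unclass(x$contact_ca), contact_sc = unclass(x$contact_sc),
         class_map = x$class_map, freq = x$freq)
  } else {
    stop_seqevolve("can only serialize energy_model or potential_set objects",
                   "seqevolve_usage_error")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(deparse(payload, control = c("keepNA", "keepInteger", "niceNames",
                                          "showAttributes", "digits17")),
             con, sep = "\n")
  invisible(path)
}

rebless <- function(payload) {
  pot <- structure(list(
    burial = structure(payload$burial, class = "burial_model"),
    ssm = structure(payload$ssm, class = "ss_model"),
    contact_ca = structure(payload$contact_ca, class = "contact_model"),
    contact_sc = structure(payload$contact_sc, class = "contact_model"),
    class_map = payload$class_map,
    freq = payload$freq
  ), class = "potential_set")
  pot
}

#' Read a model file
#'
#' Returns a `potential_set` for bare potential files. For full model files a
#' target `structure` must be supplied (the file stores no coordinates); the
#' stored profile, normalizers and weights are re-attached and the
#' structure-specific caches rebuilt.
#'
#' @param path model file written by [write_model()]
#' @param structure target `structure3d`, required for full model files
#' @return an `energy_model` or `potential_set`
#' @export
read_model <- function(path, structure = NULL) {
  payload <- tryCatch(dget(path), error = function(e) {
    stop_seqevolve(paste("cannot parse model file:", conditionMessage(e)),
                   "seqevolve_format_error")
  })
  if (is.null(payload$version) || payload$version > MODEL_FILE_VERSION) {
    stop_seqevolve("unsupported model file version", "seqevolve_format_error")
  }
  pot <- rebless(payload)
  if (identical(payload$kind, "potential_set")) return(pot)
  if (is.null(structure)) {
    stop_seqevolve("a target structure is required to load a full model file",
                   "seqevolve_usage_error")
  }
  profile <- base::structure(payload$profile, class = "seq_profile")
  model <- build_energy_model(structure, potentials = pot, profile = profile,
                              weights = payload$weights, calibrate = FALSE,
                              window = payload$window)
  model$normalizers <- payload$normalizers
  model$structure_id <- payload$structure_id
  model
}
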