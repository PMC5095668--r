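#' Read / write kinetic parameter files
#'
#' Flat key-value YAML with the fields of [kinetic_params()]; units are nM
#' and seconds. Bundled reference files for the two pore models live in
#' `inst/extdata/` (`params_model_I.yaml`, `params_model_II.yaml`) and
#' reproduce [reference_params()] exactly.
#'
#' @param path File path.
#' @return `read_kinetic_params` returns a validated [kinetic_params()].
#' @export
read_kinetic_params <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(kinetic_params))
  extra <- setdiff(names(vals), allowed)
  if (length(extra)) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  }
  do.call(kinetic_params, vals)
}

#' @rdname read_kinetic_params
#' @param params A [kinetic_params()].
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Export a trajectory as tidy delimited text
#'
#' Long format with columns `time_s`, `species`, `concentration_nM`.
#'
#' @param traj A `pore_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
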