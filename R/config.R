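#' Read a stimulus specification from YAML
#'
#' The YAML keys mirror the arguments of [stimulus_spec()]; unknown keys are
#' rejected. Lists of specs are supported with a top-level `stimuli:` array.
#'
#' @param path YAML file.
#' @return a `stimulus_spec` or a list of them.
#' @export
read_stimulus_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fields) {
    known <- names(formals(stimulus_spec))
    bad <- setdiff(names(fields), known)
    if (length(bad)) stop("unknown stimulus fields: ", paste(bad, collapse = ", "))
    if (!is.null(fields$center0)) fields$center0 <- as.numeric(fields$center0)
    if (!is.null(fields$lateral_velocity)) {
      fields$lateral_velocity <- as.numeric(fields$lateral_velocity)
    }
    do.call(stimulus_spec, fields)
  }
  if (!is.null(y$stimuli)) lapply(y$stimuli, build) else build(y)
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any of the blocks `frontend`, `lptc`, `contour`,
#' `decision`; each key overrides the corresponding parameter default, so an
#' empty file yields the published operating point.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return a [loom_config()].
#' @export
read_config_yaml <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  apply_block <- function(ctor, block) {
    fields <- y[[block]] %||% list()
    known <- names(formals(ctor))
    bad <- setdiff(names(fields), known)
    if (length(bad)) {
      stop("unknown ", block, " fields: ", paste(bad, collapse = ", "))
    }
    if (!is.null(fields$betas)) fields$betas <- as.numeric(fields$betas)
    do.call(ctor, fields)
  }
  loom_config(frontend = apply_block(frontend_params, "frontend"),
              lptc = apply_block(lptc_params, "lptc"),
              contour = apply_block(contour_params, "contour"),
              decision = apply_block(decision_params, "decision"))
}
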