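#' Model configuration files
#'
#' A model is serialised as one block per coefficient
#' (\code{form}, \code{mean}, and for sinusoids \code{amplitude},
#' \code{angularFrequency}, \code{phase}, \code{period}; for tabulated
#' profiles \code{times}, \code{values}, \code{period}) plus \code{omega}
#' and an optional \code{extension} block with \code{alphaS}/\code{gammaS}.
#' YAML or JSON is chosen by file extension
#' (\code{.yaml}/\code{.yml} vs \code{.json}).
#'
#' @param path file path.
#' @return \code{readModelConfig} returns an \code{ecoEpidemicModel};
#'   \code{writeModelConfig} returns \code{path} invisibly.
#' @name modelConfig
NULL

pfToList <- function(f) {
  switch(f$form,
    constant = list(form = "constant", mean = f$mean),
    sinusoid = list(form = "sinusoid", mean = f$mean,
                    amplitude = f$amplitude,
                    angularFrequency = f$angularFrequency, phase = f$phase,
                    period = f$period),
    tabulated = list(form = "tabulated", times = f$times, values = f$values,
                     period = f$period))
}

pfFromList <- function(x) {
  switch(x$form,
    constant = periodicConstant(x$mean),
    sinusoid = periodicSinusoid(x$mean, x$amplitude, x$angularFrequency,
                                x$phase %||% 0, x$period),
    tabulated = periodicTabulated(x$times, x$values, x$period),
    stop("unknown coefficient form in config: ", x$form))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modelToConfig <- function(model) {
  stopifnot(inherits(model, "ecoEpidemicModel"))
  main <- c(reactionCoefNames, diffusivityNames)
  cfg <- list(omega = model$omega,
              coefficients = lapply(model$coefs[main], pfToList))
  if (model$hasExtension)
    cfg$extension <- lapply(model$coefs[extensionNames], pfToList)
  cfg
}

modelFromConfig <- function(cfg) {
  stopifnot(!is.null(cfg$omega), !is.null(cfg$coefficients))
  args <- lapply(cfg$coefficients, pfFromList)
  names(args) <- names(cfg$coefficients)
  args$omega <- cfg$omega
  if (!is.null(cfg$extension)) {
    args$alphaS <- pfFromList(cfg$extension$alphaS)
    args$gammaS <- pfFromList(cfg$extension$gammaS)
  }
  do.call(ecoEpidemicModel, args)
}

#' @rdname modelConfig
#' @param model an \code{ecoEpidemicModel}.
#' @export
writeModelConfig <- function(model, path) {
  cfg <- modelToConfig(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' @rdname modelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  modelFromConfig(cfg)
}
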