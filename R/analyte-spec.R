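#' Define an analyte specification
#'
#' An analyte specification carries the per-analyte constants every stage of
#' the toolkit needs: the target (assigned) mean and SD of the in-control
#' distribution, the total allowable error (TEa), and the peer-group reference
#' value used for bias estimation.
#'
#' TEa can be stated either as a percentage of the target (`tea_mode =
#' "percent"`, e.g. CLIA '88 limits) or in absolute analyte units (`tea_mode =
#' "absolute"`, e.g. the +/- 10 x 10^9/L limit commonly used for platelets).
#' [tea_pct()] and [tea_units()] convert between the two at computation time.
#'
#' @param name Analyte identifier, e.g. `"Hb"`, `"WBC"`, `"RBC"`, `"HCT"`,
#'   `"PLT"`, or any custom string.
#' @param units Unit string (documentation only).
#' @param target_mean Target (in-control) mean, in analyte units.
#' @param target_sd Target (in-control) SD, in analyte units. Must be > 0.
#' @param tea Total allowable error, interpreted according to `tea_mode`.
#' @param tea_mode Either `"percent"` (percent of target) or `"absolute"`
#'   (analyte units).
#' @param reference_value Assigned peer-group (EQA median) value used for bias
#'   computation; defaults to `target_mean`. Must be > 0.
#'
#' @return An object of class `analyte_spec` (a named list).
#' @examples
#' plt <- analyte_spec("PLT", "10^9/L", 250, 7, tea = 10, tea_mode = "absolute")
#' tea_pct(plt)   # 4 percent of target
#' tea_units(plt) # 10 x 10^9/L
#' @export
analyte_spec <- function(name, units = "", target_mean, target_sd, tea,
                         tea_mode = c("percent", "absolute"),
                         reference_value = target_mean) {
  tea_mode <- match.arg(tea_mode)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(target_mean)) stop("`target_mean` must be finite", call. = FALSE)
  if (!is.finite(target_sd) || target_sd <= 0) {
    stop("`target_sd` must be > 0", call. = FALSE)
  }
  if (!is.finite(tea) || tea <= 0) stop("`tea` must be > 0", call. = FALSE)
  if (!is.finite(reference_value) || reference_value <= 0) {
    stop("`reference_value` must be > 0", call. = FALSE)
  }
  structure(
    list(
      name = name, units = units,
      target_mean = target_mean, target_sd = target_sd,
      tea = tea, tea_mode = tea_mode,
      reference_value = reference_value
    ),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf(
    "<analyte_spec> %s: target %g +/- %g %s, TEa %g%s, reference %g\n",
    x$name, x$target_mean, x$target_sd, x$units, x$tea,
    if (x$tea_mode == "percent") "%" else paste0(" ", x$units),
    x$reference_value
  ))
  invisible(x)
}

#' Total allowable error as a percentage of target
#' @param spec An [analyte_spec()].
#' @return TEa expressed as percent of the target mean.
#' @export
tea_pct <- function(spec) {
  stopifnot(inherits(spec, "analyte_spec"))
  if (spec$tea_mode == "percent") spec$tea else 100 * spec$tea / spec$target_mean
}

#' Total allowable error in analyte units
#' @param spec An [analyte_spec()].
#' @return TEa expressed in analyte units.
#' @export
tea_units <- function(spec) {
  stopifnot(inherits(spec, "analyte_spec"))
  if (spec$tea_mode == "absolute") spec$tea else spec$tea / 100 * spec$target_mean
}

#' Default hematology analyte specifications
#'
#' Ready-made specifications for the five routine hematology parameters.
#' TEa limits follow CLIA '88 percent limits except PLT, which uses the
#' absolute +/- 10 x 10^9/L limit customary at a normal platelet level. The
#' target means are typical mid-normal adult levels and the target SDs
#' correspond to the long-term imprecision (CV) of a modern hematology
#' analyzer on fresh samples; PLT uses CV 2.8% so that QC-vs-patient CV
#' experiments line up with the worked examples shipped with the package.
#'
#' @param analyte Optional single analyte name; when supplied, the matching
#'   [analyte_spec()] is returned instead of the full list.
#' @return A named list of `analyte_spec` objects, or one spec.
#' @examples
#' default_analyte_specs("PLT")
#' @export
default_analyte_specs <- function(analyte = NULL) {
  specs <- list(
    Hb  = analyte_spec("Hb", "g/L", 150, 1.35, tea = 7, tea_mode = "percent"),
    WBC = analyte_spec("WBC", "10^9/L", 7, 0.14, tea = 15, tea_mode = "percent"),
    RBC = analyte_spec("RBC", "10^12/L", 4.5, 0.068, tea = 6, tea_mode = "percent"),
    HCT = analyte_spec("HCT", "%", 42, 0.63, tea = 6, tea_mode = "percent"),
    PLT = analyte_spec("PLT", "10^9/L", 250, 7, tea = 10, tea_mode = "absolute")
  )
  if (is.null(analyte)) {
    return(specs)
  }
  if (!analyte %in% names(specs)) {
    stop("no default spec for analyte '", analyte, "'", call. = FALSE)
  }
  specs[[analyte]]
}
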