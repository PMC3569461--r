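## Regional conductance table and chronic-AF remodeling modifications.
##
## The five electrophysiological variants (CT, PM, APG, AVR, AWM) differ only
## in the maximal conductances of I_t, I_CaL, I_Kr and I_K1; remodeling
## additionally slows the fast inactivation of I_CaL by 62% and shifts the
## I_t activation and I_Na inactivation curves by +16 mV and +1.6 mV.

.VARIANT_CONDUCTANCES <- list(
  control = data.frame(
    row.names = c("gt", "gCaL", "gKr", "gK1"),
    CT  = c(10.6, 10.3, 0.4, 4.2),
    PM  = c(8.3, 6.2, 0.4, 4.2),
    APG = c(4.2, 6.7, 2.3, 4.2),
    AVR = c(8.3, 4.2, 2.3, 4.2),
    AWM = c(7.5, 6.7, 0.5, 4.2)),
  remodeled = data.frame(
    row.names = c("gt", "gCaL", "gKr", "gK1"),
    CT  = c(1.6, 2.7, 0.4, 10.5),
    PM  = c(1.2, 1.6, 0.4, 10.5),
    APG = c(0.6, 1.7, 2.3, 10.5),
    AVR = c(1.2, 1.1, 2.3, 10.5),
    AWM = c(1.1, 1.7, 0.5, 10.5)))

.REMODEL_KINETICS <- c(tauFCaLScale = 1.62, itActShift = 16, iNaInactShift = 1.6)

#' Cell-model variant regions
#'
#' The five regions carrying distinct ionic parameter sets.
#' @return character vector of region names
#' @export
cellVariantRegions <- function() colnames(.VARIANT_CONDUCTANCES$control)

#' Build the ionic parameter set of a regional cell variant
#'
#' Returns the maximal conductances of I_t, I_CaL, I_Kr and I_K1 for the
#' requested atrial region and condition; under remodeling the kinetic
#' modifications of chronic AF (slowed fast I_CaL inactivation, shifted I_t
#' activation and I_Na inactivation curves) are applied as well.
#'
#' @param region one of \code{cellVariantRegions()}
#' @param condition "control" or "remodeled"
#' @return a \linkS4class{CellParams} object
#' @examples
#' makeCellParams("AWM", "control")
#' makeCellParams("CT", "remodeled")
#' @export
makeCellParams <- function(region, condition = c("control", "remodeled")) {
  condition <- match.arg(condition)
  if (length(region) != 1L || !region %in% cellVariantRegions())
    stop("unknown cell variant region: ", paste(region, collapse = ", "),
         " (expected one of ", paste(cellVariantRegions(), collapse = ", "), ")")
  g <- .VARIANT_CONDUCTANCES[[condition]][[region]]
  kin <- if (condition == "remodeled") .REMODEL_KINETICS else
    c(tauFCaLScale = 1, itActShift = 0, iNaInactShift = 0)
  new("CellParams", region = region, condition = condition,
      gt = g[1], gCaL = g[2], gKr = g[3], gK1 = g[4],
      tauFCaLScale = unname(kin[1]), itActShift = unname(kin[2]),
      iNaInactShift = unname(kin[3]), cm = 50)
}

#' @rdname makeCellParams
#' @param object a CellParams object
#' @return \code{conductances()}: named numeric vector of the four maximal
#'   conductances (nS)
#' @export
conductances <- function(object) {
  stopifnot(is(object, "CellParams"))
  c(gt = object@gt, gCaL = object@gCaL, gKr = object@gKr, gK1 = object@gK1)
}

# flat numeric parameter vector in the order the compiled core expects
.parVector <- function(params) {
  c(params@gt, params@gCaL, params@gKr, params@gK1,
    params@tauFCaLScale, params@itActShift, params@iNaInactShift)
}

.paramsKey <- function(params) paste(.parVector(params), collapse = "_")

#' Published resting state of the cell model
#'
#' The quiescent initial conditions of the original model publication, as a
#' named state vector (Vm, gates, concentrations, buffers).
#' @return named numeric vector of the full cell state
#' @export
restingState <- function() {
  s <- cpp_initial_state()
  names(s) <- cpp_state_names()
  s
}

#' Export / import cell parameter sets as plain text
#'
#' Tab-separated name/value pairs with region and condition headers, so a
#' variant can be archived or exchanged without R serialization.
#' @param params a CellParams object
#' @param file path to write to / read from
#' @return \code{importCellParams} returns a CellParams object
#' @export
exportCellParams <- function(params, file) {
  stopifnot(is(params, "CellParams"))
  df <- data.frame(
    name = c("region", "condition", "gt", "gCaL", "gKr", "gK1",
             "tauFCaLScale", "itActShift", "iNaInactShift", "cm"),
    value = c(params@region, params@condition, params@gt, params@gCaL,
              params@gKr, params@gK1, params@tauFCaLScale, params@itActShift,
              params@iNaInactShift, params@cm))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname exportCellParams
#' @export
importCellParams <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  v <- stats::setNames(df$value, df$name)
  new("CellParams", region = v[["region"]], condition = v[["condition"]],
      gt = as.numeric(v[["gt"]]), gCaL = as.numeric(v[["gCaL"]]),
      gKr = as.numeric(v[["gKr"]]), gK1 = as.numeric(v[["gK1"]]),
      tauFCaLScale = as.numeric(v[["tauFCaLScale"]]),
      itActShift = as.numeric(v[["itActShift"]]),
      iNaInactShift = as.numeric(v[["iNaInactShift"]]),
      cm = as.numeric(v[["cm"]]))
}
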