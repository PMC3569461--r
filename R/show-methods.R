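## show() methods for the S4 containers

setMethod("show", "CellParams", function(object) {
  cat("CellParams:", object@region, "/", object@condition, "\n")
  g <- conductances(object)
  cat(sprintf("  g_t = %.1f  g_CaL = %.1f  g_Kr = %.1f  g_K1 = %.1f nS\n",
              g[1], g[2], g[3], g[4]))
  if (object@condition == "remodeled")
    cat(sprintf("  tau_fCaL x%.2f, I_t act %+g mV, I_Na inact %+g mV\n",
                object@tauFCaLScale, object@itActShift, object@iNaInactShift))
})

setMethod("show", "TissueGrid", function(object) {
  d <- object@dims
  cat("TissueGrid:", object@topology, paste(d, collapse = " x "),
      "nodes @", object@dx, "um\n")
  cat("  extent:", paste(round(d * object@dx / 1e4, 2), collapse = " x "),
      "cm;  regions:", paste(unique(object@region), collapse = ", "), "\n")
})

setMethod("show", "StimulusProtocol", function(object) {
  cat("StimulusProtocol:", nrow(object@events), "events\n")
  if (nrow(object@events)) {
    ev <- object@events
    cat("  t =", paste(head(ev$start, 8), collapse = ", "),
        if (nrow(ev) > 8) "...", "ms\n")
  }
})

setMethod("show", "MonodomainModel", function(object) {
  cat("MonodomainModel:", object@condition, "\n")
  show(object@grid)
  cat(sprintf("  Sv = %.3g 1/m, cmArea = %g uF/cm^2, dt = %g ms\n",
              object@Sv, object@cmArea, object@dt))
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult:", length(object@times), "samples over",
      round(max(object@times)), "ms,", prod(object@grid@dims), "nodes\n")
  nact <- sum(vapply(object@activations, length, integer(1)))
  cat("  total activations:", nact, "\n")
})

setMethod("show", "VmTrace", function(object) {
  cat("VmTrace:", round(max(object@t)), "ms,",
      length(object@upstrokes), "beats (",
      object@params@region, "/", object@params@condition, ")\n")
})

setMethod("show", "EGMTrace", function(object) {
  cat("EGMTrace:", round(max(object@t) - min(object@t)), "ms @ 1 kHz,",
      "electrode at (", paste(round(object@electrode@position), collapse = ", "),
      ") um\n")
})

setMethod("show", "SpectralResult", function(object) {
  cat(sprintf("SpectralResult: DF = %.2f Hz, OI = %.2f (band %g-%g Hz)\n",
              object@df, object@oi, object@band[1], object@band[2]))
})

setMethod("show", "MorphologyCall", function(object) {
  cat("MorphologyCall:", object@morphology, "(", nrow(object@windows),
      "activation windows )\n")
})
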