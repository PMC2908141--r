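#' Condition presets: planted activity per genotype x drug state
#'
#' Each preset fixes, per simulated slice, the number of active electrodes,
#' the number of distinct units planted on each active electrode, and the
#' aggregate firing rate per active electrode (the units' rates sum to it).
#' The basal and serotonin presets carry the reported group statistics for
#' control and SMA (survival-motor-neuron-deficient) slices; the
#' acetylcholine, bicuculline and GABA presets carry the corresponding
#' drug-row summaries. Inactive tissue-covered electrodes receive one
#' sub-criterion background unit (`inactive_rate_hz` < 1 Hz), so the
#' 50-spikes-per-50-s activity criterion is realized by construction.
#'
#' Units-per-electrode is only reported for the basal and serotonin states;
#' the other drug presets reuse the genotype's basal value.
#'
#' @param genotype `"control"` or `"SMA"`.
#' @param drug one of `"basal"`, `"serotonin"`, `"acetylcholine"`,
#'   `"bicuculline"`, `"GABA"`.
#' @return An object of class `vh_preset` with fields `genotype`, `drug`,
#'   `n_active_electrodes`, `units_per_active_electrode`,
#'   `aggregate_rate_hz`, `inactive_rate_hz`.
#' @examples
#' build_preset("control", "basal")$n_active_electrodes     # 15
#' build_preset("SMA", "serotonin")$n_active_electrodes     # 11
#' @export
build_preset <- function(genotype = c("control", "SMA"),
                         drug = c("basal", "serotonin", "acetylcholine",
                                  "bicuculline", "GABA")) {
  if (!is.character(genotype) || !genotype[1] %in% c("control", "SMA"))
    stop("unknown condition: genotype must be 'control' or 'SMA'")
  genotype <- genotype[1]
  if (!is.character(drug) ||
      !drug[1] %in% c("basal", "serotonin", "acetylcholine", "bicuculline", "GABA"))
    stop("unknown condition: drug not recognized")
  drug <- drug[1]

  tab <- list(
    "control.basal"         = c(15, 5, 6.08),
    "SMA.basal"             = c(6, 4, 5.48),
    "control.serotonin"     = c(25, 7, 10.20),
    "SMA.serotonin"         = c(11, 5, 6.98),
    "control.acetylcholine" = c(14, 5, 5.88),
    "SMA.acetylcholine"     = c(6, 4, 5.39),
    "control.bicuculline"   = c(16, 5, 5.96),
    "SMA.bicuculline"       = c(7, 4, 6.18),
    "control.GABA"          = c(14, 5, 5.74),
    "SMA.GABA"              = c(6, 4, 5.14)
  )
  v <- tab[[paste(genotype, drug, sep = ".")]]
  if (is.null(v)) stop("unknown condition: ", genotype, "/", drug)
  structure(
    list(genotype = genotype, drug = drug,
         n_active_electrodes = as.integer(v[1]),
         units_per_active_electrode = as.integer(v[2]),
         aggregate_rate_hz = v[3],
         inactive_rate_hz = 0.3),
    class = "vh_preset"
  )
}

#' @export
print.vh_preset <- function(x, ...) {
  cat(sprintf("<vh_preset> %s/%s: %d active electrodes, %d units/electrode, %.2f Hz aggregate\n",
              x$genotype, x$drug, x$n_active_electrodes,
              x$units_per_active_electrode, x$aggregate_rate_hz))
  invisible(x)
}
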