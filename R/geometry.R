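#' Default ventral-horn electrode mask
#'
#' Slices are positioned so that only the ventral horn lies over the array,
#' covering just over half of the 8x8 grid. The default tissue mask is the
#' 6x6 corner sub-grid (36 electrodes); any mask of at least 25 sites
#' accommodates every condition preset.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param horn_rows,horn_cols extent of the sub-grid covered by tissue.
#' @return Integer vector of 1-based electrode indices (row-major order).
#' @export
default_ventral_mask <- function(n_rows = 8, n_cols = 8,
                                 horn_rows = 6, horn_cols = 6) {
  idx <- outer(seq_len(horn_rows) - 1L, seq_len(horn_cols),
               function(r, c) r * n_cols + c)
  sort(as.integer(idx))
}

#' Multi-electrode array geometry
#'
#' Describes the MED64-style probe: an 8x8 grid of 64 electrodes with 75 um
#' inter-electrode spacing, plus the set of electrodes considered covered by
#' ventral-horn tissue.
#'
#' @param n_rows,n_cols grid dimensions (default 8x8).
#' @param spacing_um inter-electrode spacing in micrometres.
#' @param ventral_horn_mask 1-based indices of tissue-covered electrodes.
#' @return An object of class `vh_geometry`.
#' @examples
#' g <- array_geometry()
#' g$n_electrodes      # 64
#' length(g$ventral_horn_mask)  # 36
#' @export
array_geometry <- function(n_rows = 8, n_cols = 8, spacing_um = 75,
                           ventral_horn_mask = default_ventral_mask(n_rows, n_cols)) {
  n_el <- n_rows * n_cols
  mask <- sort(unique(as.integer(ventral_horn_mask)))
  if (length(mask) == 0)
    stop("ventral_horn_mask must be non-empty")
  if (any(mask < 1L) || any(mask > n_el))
    stop("ventral_horn_mask indices must lie in 1..", n_el)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_electrodes = as.integer(n_el), spacing_um = spacing_um,
         ventral_horn_mask = mask),
    class = "vh_geometry"
  )
}

#' @export
print.vh_geometry <- function(x, ...) {
  cat(sprintf("<vh_geometry> %dx%d grid, %g um spacing, %d/%d electrodes under tissue\n",
              x$n_rows, x$n_cols, x$spacing_um,
              length(x$ventral_horn_mask), x$n_electrodes))
  invisible(x)
}
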