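# Frozen scenario presets.
#
# The three correlation scenarios are defined relative to the lattice's
# nearest-neighbour spacing (= 1 coordinate unit) and were fixed by a
# one-time calibration against the documented type I error pattern (see the
# methods vignette for the procedure and the structural constraints it
# uncovered): latent variances sigma2 of 0.25 / 0.5 / 4 with decay lengths
# kappa of 0.5 / 0.75 / 0.4, plus an "independent" preset (sigma2 = 0) for
# parameter-free calibration checks. beta0 = -2.5 puts the per-spot zero
# fraction above 0.9 under the null of the weak preset, the zero-inflation
# regime typical of spot-level counts. These values are frozen; the
# benchmark harness treats them as the study conditions.
scenario_presets <- list(
  independent = list(sigma2 = 0, kappa = 1),
  weak = list(sigma2 = 0.25, kappa = 0.5),
  moderate = list(sigma2 = 0.5, kappa = 0.75),
  strong = list(sigma2 = 4, kappa = 0.4)
)

#' Frozen simulation scenario presets
#'
#' Returns one of the package's frozen correlation scenarios on a Visium-like
#' hex lattice: `"independent"` (`sigma2 = 0`), `"weak"`
#' (`sigma2 = 0.25, kappa = 0.5`), `"moderate"` (`sigma2 = 0.5, kappa = 0.75`)
#' or `"strong"` (`sigma2 = 4, kappa = 0.4`), with `kappa` in nearest-neighbour
#' spot units and zero-inflating intercept `beta0 = -2.5`. The default
#' 59 x 59 lattice has 3,481 spots, split into two contiguous grade regions.
#' See the package vignette for how these presets were chosen and what they
#' emulate.
#'
#' @param name Preset name.
#' @param n_rows,n_cols Lattice dimensions.
#' @param beta1 Grade effect (0 for type I error studies).
#' @param grade_scheme,seed Passed to [st_scenario()].
#' @return A [st_scenario()] object.
#' @examples
#' scenario_preset("weak", n_rows = 10, n_cols = 10)
#' @export
scenario_preset <- function(name = c("independent", "weak", "moderate", "strong"),
                            n_rows = 59, n_cols = 59, beta1 = 0,
                            grade_scheme = "spatial-half-split", seed = 1L) {
  name <- match.arg(name)
  p <- scenario_presets[[name]]
  st_scenario(
    sigma2 = p$sigma2, kappa = p$kappa, beta0 = -2.5, beta1 = beta1,
    lattice = generate_visium_lattice(n_rows, n_cols),
    grade_scheme = grade_scheme, seed = seed
  )
}
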