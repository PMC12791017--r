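#' Sulfur-cycle flux bookkeeping
#'
#' Steady-state arithmetic linking pyrite burial to the marine sulfate
#' budget and atmospheric oxygen:
#'
#' * `net_sulfur_loss()`: marine sulfate loss = pyrite burial flux minus
#'   riverine sulfate delivery (mol S yr^-1).
#' * `o2_release()`: net O2 release from sulfur cycling. Burial and
#'   oxidative weathering transfer 15 mol electrons per mol FeS2; 4 mol
#'   electrons reduce one O2. The oxidation flux is the pyrite-derived
#'   fraction of riverine sulfate (mol S yr^-1, divided by 2 to count FeS2).
#'
#' @param burial Pyrite burial flux, mol S yr^-1.
#' @param riverine Riverine sulfate delivery, mol S yr^-1.
#' @param pyrite_fraction Fraction of riverine sulfate derived from pyrite
#'   weathering (default 0.5).
#' @return mol S yr^-1 (`net_sulfur_loss`) or mol O2 yr^-1 (`o2_release`).
#' @examples
#' net_sulfur_loss(7.0e12, 2.8e12) # 4.2e12
#' o2_release(7.0e12, 2.8e12)      # ~1.05e13
#' @export
net_sulfur_loss <- function(burial, riverine) {
  burial - riverine
}

#' @rdname net_sulfur_loss
#' @export
o2_release <- function(burial, riverine, pyrite_fraction = 0.5) {
  net_fes2 <- (burial - pyrite_fraction * riverine) / 2
  net_fes2 * 15 / 4
}
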