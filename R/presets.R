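#' Analysis presets for the Ubc9-SUMO-RanBP2 sumoylation system
#'
#' The parameter values used in the published trajectory analyses of the E2
#' (Ubc9) - SUMO conjugate with and without the E3 ligase fragment RanBP2.
#' These numbers are simulation-specific configuration, shipped here as a
#' documented preset for users re-running comparable simulations; nothing in
#' the package hard-wires them.
#'
#' @return list with:
#' \describe{
#'   \item{equilibration_end}{equilibration periods excluded from averages,
#'     ns: 2.5 (unbound Ubc9), 5 (unbound SUMO), 0.5 (Ubc9-SUMO), 0.4
#'     (Ubc9-SUMO-RanBP2).}
#'   \item{sumo_tail_resno}{flexible N-terminal SUMO tail (residues -1..19)
#'     excluded from fluctuation fits.}
#'   \item{delay_grid}{bond-autocorrelation delays, ns: 0, 0.4, 1, 5, 30;
#'     the largest delay is chosen slightly longer than half the simulation
#'     time.}
#'   \item{cluster_radius}{k-means RMSD radius, A: 1.7 (Ubc9-SUMO and the
#'     joined Ubc9 ensemble), 2.0 (Ubc9-SUMO-RanBP2).}
#'   \item{radius_grid}{radii explored when choosing the cutoff: 1.5, 1.7,
#'     2 A (cluster count decreases as the radius grows).}
#'   \item{joined_trim}{initial time discarded from each trajectory before
#'     joining ensembles, ns.}
#' }
#' @export
sumoylation_presets <- function() {
  list(
    equilibration_end = c(ubc9 = 2.5, sumo = 5, ubc9_sumo = 0.5,
                          ubc9_sumo_ranbp2 = 0.4),
    sumo_tail_resno = -1:19,
    delay_grid = c(0, 0.4, 1, 5, 30),
    cluster_radius = c(ubc9_sumo = 1.7, ubc9_sumo_ranbp2 = 2.0,
                       joined_ubc9 = 1.7),
    radius_grid = c(1.5, 1.7, 2.0),
    joined_trim = 10
  )
}
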