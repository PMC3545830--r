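#' Canonical developmental stage labels
#'
#' The four sampled points of the modified Eichhorn-Lorenz (E-L) scale used
#' throughout the package: young berries (E-L 31), early veraison (E-L 35),
#' late veraison (E-L 36) and harvest-ripe berries (E-L 38).
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' berryStages()
berryStages <- function() c("EL31", "EL35", "EL36", "EL38")

#' Expression archetype templates
#'
#' Ten named four-stage expression shapes used both to plant ground-truth
#' patterns in synthetic catalogs and to label k-means centroids. Each
#' template is a nonnegative 4-vector over the stages EL31, EL35, EL36,
#' EL38; only the shape matters (clustering operates on scale-and-centred
#' profiles, which are invariant to the template's overall amplitude).
#'
#' The shapes cover the regulation classes seen in berry development:
#' transcripts specific to a single stage, monotone decreasing/increasing
#' trajectories, joint up-regulation at both veraison points, and the
#' complementary dip at veraison.
#'
#' @return Named list of ten numeric 4-vectors.
#' @export
#' @examples
#' names(berryArchetypes())
berryArchetypes <- function() {
  list(
    decreasing              = c(1.00, 0.70, 0.40, 0.10),
    early_veraison_specific = c(0.05, 1.00, 0.15, 0.05),
    increasing              = c(0.10, 0.40, 0.70, 1.00),
    late_increase           = c(0.08, 0.10, 0.45, 1.00),
    late_veraison_specific  = c(0.05, 0.15, 1.00, 0.05),
    low_at_veraison         = c(1.00, 0.15, 0.15, 0.90),
    ripe_specific           = c(0.05, 0.05, 0.08, 1.00),
    veraison_up             = c(0.08, 1.00, 0.90, 0.15),
    young_shoulder          = c(1.00, 0.55, 0.10, 0.08),
    young_specific          = c(1.00, 0.05, 0.05, 0.05)
  )
}
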