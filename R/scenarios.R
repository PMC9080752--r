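# Study-condition scenarios.
#
# Bundled parameterisations of the synthetic generators matching the
# conditions under which the Picasso triggerfish visual system was
# characterised: reference pigments with their
# characterised lambda-max values, group-mean expression profiles for
# field-caught and aquarium-held fish, the behavioural grating designs, and
# a ganglion-cell retina with a temporal peak on a horizontal streak.

#' Synthetic reference pigments for lambda-max prediction
#'
#' Characterised reference pigments used for lambda-max prediction: medaka
#' RH1 (502 nm) and Nile tilapia SWS2B (425 nm), RH2B (472 nm), RH2A-alpha
#' (528 nm) and LWS (560 nm). The true reference amino-acid sequences are
#' not shipped; each pigment carries a synthetic scaffold -- the bovine
#' rhodopsin sequence with the reference's documented tuning-site residues
#' planted -- which preserves bovine-site numbering exactly and is
#' sufficient for substitution detection at tuning sites.
#'
#' @return Named list of [reference_pigment()] objects
#'   (`RH1`, `SWS2B`, `RH2B`, `RH2Aalpha`, `LWS`).
#' @export
study_reference_pigments <- function() {
  scaffold <- function(id, cls, lmax, plants) {
    base <- opsin_sequence(paste0(id, "_scaffold"), cls,
                           amino_acids = bovine_rhodopsin())
    v <- make_opsin_variant(base, plants, id = paste0(id, "_scaffold"))
    reference_pigment(id, cls, lmax, v$sequence)
  }
  list(
    RH1 = scaffold("O_latipes_RH1_synthetic", "RH1", 502,
                   data.frame(bovine_site = c(166, 299),
                              to = c("S", "S"))),
    SWS2B = scaffold("O_niloticus_SWS2B_synthetic", "SWS2", 425,
                     data.frame(bovine_site = c(46, 164),
                                to = c("F", "G"))),
    RH2B = scaffold("O_niloticus_RH2B_synthetic", "RH2", 472,
                    data.frame(bovine_site = c(88, 112, 266),
                               to = c("M", "I", "T"))),
    RH2Aalpha = scaffold("O_niloticus_RH2Aalpha_synthetic", "RH2", 528,
                         data.frame(bovine_site = c(88, 112, 266),
                                    to = c("C", "I", "T"))),
    LWS = scaffold("O_niloticus_LWS_synthetic", "LWS", 560,
                   data.frame(bovine_site = integer(), to = character()))
  )
}

#' Study opsin gene metadata
#'
#' Gene classes and coding-sequence lengths used by the expression
#' scenarios (lengths are typical teleost opsin CDS lengths; synthetic).
#'
#' @return Data frame with `gene_id`, `gene_class`, `cds_length_bp`.
#' @export
study_opsin_genes <- function() {
  data.frame(
    gene_id = c("RH1", "SWS2B", "RH2A", "RH2C-1", "RH2C-2", "LWS"),
    gene_class = c("rod", "single_cone", "double_cone", "double_cone",
                   "double_cone", "double_cone"),
    cds_length_bp = c(1062L, 1053L, 1065L, 1047L, 1047L, 1074L)
  )
}

study_true_proportions <- function(group = c("aquarium", "field"),
                                   p_rod = 0.689,
                                   single_cone_share = 1 / 3) {
  group <- match.arg(group)
  dc <- if (group == "aquarium")
    c("RH2A" = 0.6030, "RH2C-1" = 0.1214, "RH2C-2" = 0.2738,
      "LWS" = 0.0018)
  else
    c("RH2A" = 0.3504, "RH2C-1" = 0.1734, "RH2C-2" = 0.4589,
      "LWS" = 0.0170)
  dc <- dc / sum(dc)
  cone <- 1 - p_rod
  c("RH1" = p_rod, "SWS2B" = cone * single_cone_share,
    cone * (1 - single_cone_share) * dc)
}

#' Simulate a named study-condition scenario
#'
#' Scenario names and their planted truths:
#' \describe{
#'   \item{aquarium_expression / field_expression}{multinomial read counts
#'     with the group-mean double-cone proportions of aquarium-held or
#'     field-caught fish, a rod proportion of 68.9% and single cones taking
#'     one third of cone expression (the share implied by the 2:1
#'     double:single cone mosaic).}
#'   \item{achromatic_acuity}{logistic observer with a 62%-criterion
#'     threshold of 3.94 cpd, gratings 0.5--5 cpd in 0.5 steps.}
#'   \item{green_yellow_acuity}{threshold 1.71 cpd, gratings 0.5--3 cpd.}
#'   \item{pink_purple_acuity}{threshold 1.89 cpd, gratings 0.5--3 cpd.}
#'   \item{ganglion_streak}{retina with a horizontal streak and a temporal
#'     peak of 38,643 cells per mm^2 sampled at about 200 sites.}
#' }
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @return The corresponding generator's `list(data..., ledger)`.
#' @export
simulate_scenario <- function(scenario = c("aquarium_expression",
                                           "field_expression",
                                           "achromatic_acuity",
                                           "green_yellow_acuity",
                                           "pink_purple_acuity",
                                           "ganglion_streak"),
                              seed = 1) {
  scenario <- match.arg(scenario)
  genes <- study_opsin_genes()
  lens <- setNames(genes$cds_length_bp, genes$gene_id)
  cls <- setNames(genes$gene_class, genes$gene_id)
  switch(scenario,
    aquarium_expression = make_read_counts(
      study_true_proportions("aquarium"), lens, cls, seed = seed),
    field_expression = make_read_counts(
      study_true_proportions("field"), lens, cls, seed = seed),
    achromatic_acuity = make_trials(
      3.94, slope = 2, frequencies = seq(0.5, 5, 0.5),
      n_per_frequency = 110, seed = seed, treatment = "achromatic"),
    green_yellow_acuity = make_trials(
      1.71, slope = 2.5, frequencies = seq(0.5, 3, 0.5),
      n_per_frequency = 110, seed = seed, treatment = "green_yellow"),
    pink_purple_acuity = make_trials(
      1.89, slope = 2.5, frequencies = seq(0.5, 3, 0.5),
      n_per_frequency = 110, seed = seed, treatment = "pink_purple"),
    ganglion_streak = make_retina(seed = seed)
  )
}
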