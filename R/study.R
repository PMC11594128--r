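# Frozen desk-scale study presets: the configuration under which the
# package reproduces the emulated study's headline numbers.

#' Desk-scale study defaults
#'
#' The frozen configuration for desk-scale reproductions of the multi-breed
#' prediction study: a 10 x 0.25 Morgan genome with 10,000 markers
#' ([sim_genome()] defaults), an ancestral pool of 200 diploids, breed panels
#' of 21-26 individuals expanded to 1500 by block resampling, and GBLUP
#' references of 400 (+200) with 200-individual validation sets.
#'
#' `block_len = 40` markers (1 Mb, about 1 cM) rather than the 500 used on
#' the ~658k-marker HD chip: at desk marker spacing a 500-marker block would
#' span 12.5 cM and collapse the genotype space to ~20 blocks, an order of
#' magnitude fewer effective chromosome segments than HD data carry. A 1 cM
#' block reproduces the effective segment count (Me around 1100) implied by
#' the study's within-breed accuracies at a 400-individual reference, which
#' is the property that governs prediction accuracy. See the methods
#' vignette for the derivation.
#'
#' @return a named list of defaults.
#' @export
desk_defaults <- function() {
  list(
    block_len = 40L, n_sim = 1500L,
    n_pool_hap = 400L, ancestral_ne = 200L, n_founders = 70L,
    panel_sizes = c(24L, 26L),
    n_ref_a = 400L, n_ref_b = 200L, n_val = 200L,
    replicates = 10L, h2 = c(0.1, 0.3, 0.6), strategy = "II"
  )
}

#' Generate a calibrated two-breed study population
#'
#' Builds the desk-scale ancestral pool, calibrates the divergence
#' generations to the requested phase consistency with
#' [calibrate_divergence()], and derives the two breed panels. This is the
#' entry point the acceptance workflow uses for the "two breeds at
#' consistency about 0.5" condition.
#'
#' @param seed integer seed controlling the whole construction.
#' @param target_consistency calibration target (default 0.5).
#' @param map marker map (desk-scale by default).
#' @param tolerance calibration tolerance.
#' @param panel_sizes diploids per derived panel.
#' @return list with `panels` (named list, breeds `"A"` and `"B"`),
#'   `generations`, `calibrated_consistency`, and the ancestral `pool`.
#' @export
make_study_pair <- function(seed, target_consistency = 0.5,
                            map = sim_genome(), tolerance = 0.05,
                            panel_sizes = desk_defaults()$panel_sizes) {
  d <- desk_defaults()
  pool <- generate_ancestral_pool(d$n_pool_hap, map,
                                  ancestral_ne = d$ancestral_ne,
                                  seed = derive_seed(seed, "pool"))
  cal <- calibrate_divergence(pool, target_consistency,
                              tolerance = tolerance,
                              seed = derive_seed(seed, "calibrate"),
                              n_founders = d$n_founders)
  cfg <- breed_set_config(
    breed_ids = c("A", "B"), panel_sizes = panel_sizes,
    split_generations = rep(cal$generations, 2),
    n_founders = d$n_founders, ancestral_ne = d$ancestral_ne,
    map = map, seed = derive_seed(seed, "panels")
  )
  list(panels = make_breed_panels(cfg, ancestral = pool),
       generations = cal$generations,
       calibrated_consistency = cal$consistency,
       pool = pool)
}
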