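# Shared study configuration for the numbered analysis drivers.
# Every driver regenerates the same synthetic study from these seeds, so
# each can be run on its own:  Rscript analysis/0X_*.R
suppressPackageStartupMessages(library(memmodes))

STUDY_SEED <- 42L
dir.create("results", showWarnings = FALSE)

# Six independent binding runs with the start -> mode mapping of the study
# design: start 1 lands in mode 1, starts 2/4/5/6 in mode 2, start 3 in
# mode 3.
make_study <- function(seed = STUDY_SEED, n_frames = 200L) {
  protein <- make_toy_protein(134, seed = seed)
  bilayer <- make_bilayer_patch(15, 15, seed = seed + 1)
  specs <- default_mode_specs()
  start_modes <- list(specs$mode1, specs$mode2, specs$mode3,
                      specs$mode2, specs$mode2, specs$mode2)
  trajectories <- lapply(seq_along(start_modes), function(i)
    simulate_binding_trajectory(protein, bilayer, start_modes[[i]],
                                n_frames = n_frames, seed = seed + 100 + i))
  list(protein = protein, bilayer = bilayer, specs = specs,
       start_modes = vapply(start_modes, `[[`, integer(1), "label"),
       trajectories = trajectories, seed = seed)
}

make_afm_study <- function(seed = STUDY_SEED, n_fields = 8L,
                           particles_per_field = 75L) {
  spec <- default_mixture_spec()
  fields <- lapply(seq_len(n_fields), function(i)
    simulate_afm_field(spec, particles_per_field, field_nm = 110,
                       noise_sd_nm = 0.05, seed = seed + 200 + i))
  list(spec = spec, fields = fields, seed = seed)
}
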