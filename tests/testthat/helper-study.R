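# Study-scale objects for the acceptance suite: a 5-anatomy cohort with
# 500 paced + 60 VT beats per anatomy at 4 mm resolution. Built once per
# test run and shared by every acceptance block (simulation dominates the
# runtime; training is cheap).

study_cfg <- function() memo("study_cfg", function() {
  cohort <- make_cohort(5, geometry_params(target_edge_length = 4), 1L)
  library_config(cohort, n_paced_per_anatomy = 500, n_vt_per_anatomy = 60,
                 global_seed = 1L)
})

study_bundles <- function() memo("study_bundles", function() {
  build_bundles(study_cfg())
})

study_pacing <- function() memo("study_pacing", function() {
  build_pacing_library(study_cfg(), study_bundles())
})

study_vt <- function() memo("study_vt", function() {
  build_vt_library(study_cfg(), study_bundles())
})

study_base_tc <- function(seed) {
  train_config(epochs = 150, patience = 30, seed = seed)
}

study_transfer_tc <- function(seed) {
  train_config(epochs = 120, patience = 25, freeze_policy = "freeze_encoder",
               seed = seed)
}

study_s1 <- function(mode) memo(paste0("study_s1_", mode), function() {
  run_rotating_evaluation(study_pacing(), study_vt(),
                          "seen_pacing_unseen_vt", mode,
                          base_tc = study_base_tc(11L),
                          transfer_tc = study_transfer_tc(12L),
                          seed = 42L)
})

study_s2 <- function(mode) memo(paste0("study_s2_", mode), function() {
  run_rotating_evaluation(study_pacing(), study_vt(), "fully_unseen", mode,
                          base_tc = train_config(epochs = 120, patience = 25,
                                                 seed = 11L),
                          transfer_tc = study_transfer_tc(12L),
                          seed = 43L)
})
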