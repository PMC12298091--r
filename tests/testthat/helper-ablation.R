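# Heavier shared computation, built once: a full-scale ablation run (cohort
# of 800, tiny-preset backbone) and a longer-pretrained backbone for the
# attribution check, both on the same cohort and split.

fix_ablation <- function(seed = 1) {
  key <- sprintf("ablation_%d", seed)
  if (is.null(.fixtures[[key]])) {
    cohort <- phantom_cohort(phantom_config(), 800, seed = seed)
    res <- run_ablation(cohort, seed = seed)
    .fixtures[[key]] <- list(cohort = cohort, result = res)
  }
  .fixtures[[key]]
}

# attribution backbone: the pipeline's fully trained encoder — phantom
# pretraining (from the ablation run) followed by freeze-and-fine-tune on
# the real training split, checkpointed on validation loss
fix_gradcam_backbone <- function(seed = 1) {
  key <- sprintf("gradcam_%d", seed)
  if (is.null(.fixtures[[key]])) {
    fx <- fix_ablation(seed)
    ft <- finetune_backbone(fx$result$backbone_pretrained, fx$cohort,
                            fx$result$split,
                            seed = iopscreen:::child_seed(seed, 44L))
    .fixtures[[key]] <- ft$model
  }
  .fixtures[[key]]
}
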