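# CPU-scale capability study on synthetic data. The study conditions are
# fixed here in one place: a 200-scan, 4-class, 64x64 synthetic dataset
# (40 patients, 5 scans each) and the reduced architecture (8-channel stem,
# P = 4, D = 128, 4 heads, L = 4), trained with the standard recipe.

#' Synthetic-data capability study
#'
#' Two checks of the training pipeline on generated data:
#'
#' * capability - the full hybrid model is trained on a 200-scan synthetic
#'   4-class dataset (patient-level validation hold-out) and training stops
#'   as soon as training accuracy reaches `target_train_acc` (or at
#'   `capability_epochs`); the achieved training accuracy measures whether
#'   the implementation can fit the task at all;
#' * ablation direction - over `n_seeds` independent seeds, the full model
#'   and the pure-transformer `vit_only` ablation are trained for
#'   `comparison_epochs` epochs on the same split, and their
#'   best-checkpoint validation accuracies are compared.
#'
#' @param seed Base seed for data generation, splits and initialization.
#' @param n_seeds Seeds in the ablation comparison.
#' @param capability_epochs Epoch cap for the capability run.
#' @param comparison_epochs Epochs per ablation-comparison run.
#' @param target_train_acc Training accuracy at which the capability run
#'   stops early.
#' @param verbose Print per-epoch progress.
#' @return List with `train_accuracy`, `epochs_used`, `comparison` (data
#'   frame: seed, validation accuracy of the full model and of the
#'   `vit_only` ablation), and `full_wins` (count of seeds where the full
#'   model's validation accuracy is >= the ablation's).
#' @export
synthetic_benchmark <- function(seed = 1L, n_seeds = 5L,
                                capability_epochs = 30L,
                                comparison_epochs = 6L,
                                target_train_acc = 0.95,
                                verbose = FALSE) {
  d <- generate_oct_dataset(synth_spec(n_patients_per_class = 10L,
                                       scans_per_patient = 5L,
                                       image_size = 64L, seed = seed))
  y <- factor(d$records$label)
  cfg_full <- hctnet_config("reduced")
  cfg_vit <- hctnet_config("reduced", ablation_mode = "vit_only")

  # the capability run asks whether the optimizer can fit the training
  # set at all, so validation-loss early stopping is disabled for it
  cap <- hctnet_fit(d$images, y, config = cfg_full,
                    tcfg = train_config(max_epochs = capability_epochs,
                                        patience = capability_epochs,
                                        seed = seed,
                                        stop_at_train_acc =
                                          target_train_acc),
                    patient_id = d$records$patient_id, verbose = verbose)
  comparison <- data.frame(seed = integer(), full = numeric(),
                           vit_only = numeric())
  for (s in seq_len(n_seeds)) {
    run_seed <- seed + 1000L * s
    val_acc <- vapply(list(cfg_full, cfg_vit), function(cfg) {
      fit <- hctnet_fit(d$images, y, config = cfg,
                        tcfg = train_config(max_epochs = comparison_epochs,
                                            seed = run_seed),
                        patient_id = d$records$patient_id,
                        verbose = verbose)
      fit$log$val_acc[fit$log$epoch == fit$best_epoch]
    }, numeric(1))
    comparison <- rbind(comparison,
                        data.frame(seed = run_seed, full = val_acc[1],
                                   vit_only = val_acc[2]))
  }
  list(train_accuracy = max(cap$log$train_acc),
       epochs_used = nrow(cap$log),
       comparison = comparison,
       full_wins = sum(comparison$full >= comparison$vit_only))
}
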