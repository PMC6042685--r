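#' Recover a programmed nuclear pMad effect from synthetic cohorts
#'
#' End-to-end validation of the pMad quantification pipeline: generates
#' batches of synthetic soma images (control, plus an experimental group
#' whose true nuclear mean is elevated by `effect_pct`), runs maximum
#' projection, nuclear measurement with the ground-truth nucleus mask
#' (decoupling segmentation from quantification), four-corner background
#' subtraction and per-batch control normalization, and returns the
#' recovered percent change per batch.
#'
#' @param effect_pct programmed percent increase of the true nuclear mean.
#' @param n_batches number of independently generated staining batches.
#' @param n_control,n_experimental images per group per batch.
#' @param seed integer master seed; per-image sub-seeds are drawn from it.
#' @param control_truth a [soma_truth()] describing the control condition.
#' @return List with `per_batch` (percent change per batch), `mean`, `se`
#'   (simulation standard error of the mean, delta-method propagation of
#'   the per-specimen variances, pooled over batches), `se_batch` (the
#'   cruder SD of batch values / sqrt(n_batches)), and `effect_pct`.
#' @export
recover_pmad_effect <- function(effect_pct, n_batches = 3L,
                                n_control = 20L, n_experimental = 20L,
                                seed = 1L, control_truth = soma_truth()) {
  exp_truth <- control_truth
  exp_truth$true_nuclear_mean <-
    control_truth$true_nuclear_mean * (1 + effect_pct / 100)
  n_per_batch <- n_control + n_experimental
  sub_seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max, n_batches * n_per_batch),
           nrow = n_batches)
  })
  measure <- function(truth, img_seed, batch) {
    gen <- generate_soma_image(truth, seed = img_seed)
    proj <- max_project(gen$stack)
    roi <- segment_nucleus(mask = gen$truth$nucleus_mask)
    nuclear_pmad(get_channel(proj, "pMad"), roi, batch_id = batch)
  }
  per_batch <- numeric(n_batches)
  var_batch <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    ctrl <- do.call(rbind, lapply(seq_len(n_control), function(i) {
      measure(control_truth, sub_seeds[b, i], batch = b)
    }))
    expm <- do.call(rbind, lapply(seq_len(n_experimental), function(i) {
      measure(exp_truth, sub_seeds[b, n_control + i], batch = b)
    }))
    per_batch[b] <- normalize_to_control(expm, ctrl)$percent_change
    # delta-method variance of 100 * (me/mc - 1) for this batch
    mc <- mean(ctrl$corrected); me <- mean(expm$corrected)
    var_batch[b] <- (100 / mc)^2 *
      (var(expm$corrected) / n_experimental +
         (me / mc)^2 * var(ctrl$corrected) / n_control)
  }
  list(per_batch = per_batch, mean = mean(per_batch),
       se = sqrt(mean(var_batch) / n_batches),
       se_batch = sd(per_batch) / sqrt(n_batches),
       effect_pct = effect_pct)
}

#' Peak temperature bin of a synthetic calcium cohort
#'
#' Generates `n_animals` synthetic heat-ramp recordings, runs the full
#' calcium pipeline ([analyze_recording()]) on each, and returns the bin
#' label (degrees C, 1-degree bins anchored at integers) at which the
#' group-mean binned dF/F0 curve is maximal.
#'
#' @param n_animals animals in the cohort.
#' @param truth a [recording_truth()] (control profile by default).
#' @param seed integer master seed.
#' @param n_baseline baseline frames for F0.
#' @return List with `peak_bin` (degrees C), `curve` (the
#'   [group_binned_mean()] data.frame), and `binned` (per-animal results).
#' @export
calcium_cohort_peak <- function(n_animals = 17L,
                                truth = recording_truth(), seed = 1L,
                                n_baseline = 30L) {
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_animals))
  binned <- lapply(seq_len(n_animals), function(i) {
    rec <- generate_gcamp_recording(truth, seed = sub_seeds[i])$recording
    analyze_recording(rec, n_baseline = n_baseline, animal_id = i)
  })
  curve <- group_binned_mean(binned)
  list(peak_bin = curve$bin_temp[which.max(curve$mean_dff)],
       curve = curve, binned = binned)
}

#' Replicate the cohort peak-bin measurement
#'
#' Runs [calcium_cohort_peak()] under `n_replicates` independent master
#' seeds and returns the peak bin of each replicate.
#'
#' @param n_replicates seeded replicates.
#' @param n_animals animals per replicate.
#' @param truth a [recording_truth()].
#' @param seed integer master seed.
#' @return Numeric vector of peak bins (degrees C), length `n_replicates`.
#' @export
calcium_peak_replicates <- function(n_replicates = 20L, n_animals = 17L,
                                    truth = recording_truth(), seed = 1L) {
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                          n_replicates))
  vapply(rep_seeds, function(s) {
    calcium_cohort_peak(n_animals = n_animals, truth = truth,
                        seed = s)$peak_bin
  }, numeric(1))
}
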