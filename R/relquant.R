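#' Per-sample delta-Ct against a reference miRNA
#'
#' For every sample with a non-missing reference measurement,
#' `delta_ct = mean_ct(sample, target) - mean_ct(sample, reference)`.
#' Samples missing the reference are excluded with a message; a reference
#' absent from the panel altogether is an error. Because each sample is
#' normalized against itself, a global efficiency shift of all Ct values of
#' a sample leaves every delta-Ct unchanged.
#'
#' @param collapsed output of [collapse_replicates()].
#' @param reference name of the reference miRNA (e.g. `"miR-26a-5p"`).
#' @return data frame with columns `sample_id`, `target`, `delta_ct`.
#' @export
delta_ct <- function(collapsed, reference) {
  if (!reference %in% collapsed$target)
    stop("reference '", reference, "' absent from the panel")
  ref <- collapsed[collapsed$target == reference & !collapsed$missing, ,
                   drop = FALSE]
  excluded <- setdiff(unique(collapsed$sample_id), ref$sample_id)
  if (length(excluded) > 0)
    message("delta-Ct: excluded sample(s) missing the reference: ",
            paste(excluded, collapse = ", "))
  ref_ct <- stats::setNames(ref$mean_ct, ref$sample_id)
  sub <- collapsed[!collapsed$missing &
                     collapsed$sample_id %in% ref$sample_id, , drop = FALSE]
  out <- data.frame(sample_id = sub$sample_id, target = sub$target,
                    delta_ct = sub$mean_ct - ref_ct[sub$sample_id],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct fold changes against a calibrator group
#'
#' For each target, `delta_delta_ct` is the sample's delta-Ct minus the
#' arithmetic mean delta-Ct of the calibrator group (e.g. healthy donors),
#' and `fold_change = 2^-delta_delta_ct` (amplification efficiency fixed at
#' 2). Averaging calibrator delta-Ct arithmetically makes the geometric mean
#' of calibrator fold changes exactly 1.
#'
#' @param dct output of [delta_ct()].
#' @param sheet sample sheet with `group` labels covering every sample.
#' @param calibrator_group group used as calibrator (default `"HD"`).
#' @return data frame with columns `sample_id`, `target`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
ddct_fold_change <- function(dct, sheet, calibrator_group = "HD") {
  sheet <- validate_sample_sheet(sheet, unique(dct$sample_id))
  grp <- sheet$group[match(dct$sample_id, sheet$sample_id)]
  out <- dct
  out$group <- grp
  calib_mean <- tapply(out$delta_ct[grp == calibrator_group],
                       out$target[grp == calibrator_group], mean)
  missing <- setdiff(unique(out$target), names(calib_mean))
  if (length(missing) > 0 || all(grp != calibrator_group))
    stop("calibrator group '", calibrator_group,
         "' has no delta-Ct values for target(s): ",
         paste(if (length(missing) > 0) missing else unique(out$target),
               collapse = ", "))
  out$delta_delta_ct <- out$delta_ct - calib_mean[out$target]
  out$fold_change <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out[, c("sample_id", "target", "group", "delta_ct", "delta_delta_ct",
          "fold_change")]
}
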