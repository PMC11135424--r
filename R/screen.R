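#' Relative quantity from Ct values
#'
#' Standard reference-normalized relative quantification:
#' `RQ = 2^-(ct_target - ct_reference)`.
#'
#' @param ct_target,ct_reference cycle-threshold values (vectorized).
#' @return Numeric relative quantities; `NA` where either Ct is `NA`.
#' @examples
#' relativeQuantity(25, 20)  # 2^-5
#' @export
relativeQuantity <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference))
}

#' PSI fold change from inclusion and total relative quantities
#'
#' `fc = (rq_inclusion / rq_total) / (rq_inclusion_ctrl / rq_total_ctrl)`:
#' the exon-inclusion-to-total-mRNA ratio of a sample, normalized to the same
#' ratio in the control.
#'
#' @param rq_inclusion,rq_total sample relative quantities.
#' @param rq_inclusion_ctrl,rq_total_ctrl control relative quantities.
#' @return Numeric fold change(s).
#' @examples
#' psiFoldChange(0.5, 0.25, 1, 1)  # 2
#' @export
psiFoldChange <- function(rq_inclusion, rq_total, rq_inclusion_ctrl,
                          rq_total_ctrl) {
  if (any(c(rq_inclusion, rq_total, rq_inclusion_ctrl, rq_total_ctrl) <= 0,
          na.rm = TRUE))
    stop("relative quantities must be positive")
  if (any(is.na(c(rq_inclusion, rq_total, rq_inclusion_ctrl, rq_total_ctrl))))
    stop("all four relative quantities must be present")
  (rq_inclusion / rq_total) / (rq_inclusion_ctrl / rq_total_ctrl)
}

screenFoldChanges <- function(plate, neg_control = "GFP",
                              detection_ct = 35) {
  need <- c("factor_id", "amplicon", "replicate", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate lacks column(s): ", paste(miss, collapse = ", "))
  amps <- c("exon5", "exon21", "total", "reference")
  if (!all(amps %in% plate$amplicon))
    stop("plate must contain amplicons: ", paste(amps, collapse = ", "))
  if (!neg_control %in% plate$factor_id)
    stop("negative control '", neg_control, "' absent from plate")

  wide <- reshape(plate[plate$amplicon %in% amps, ],
                  idvar = c("factor_id", "replicate"),
                  timevar = "amplicon", direction = "wide")
  names(wide) <- sub("^ct\\.", "ct_", names(wide))
  detected_row <- wide$ct_exon5 < detection_ct &
    wide$ct_exon21 < detection_ct & wide$ct_total < detection_ct &
    wide$ct_reference < detection_ct

  rq <- function(ct) relativeQuantity(ct, wide$ct_reference)
  ratio5 <- rq(wide$ct_exon5) / rq(wide$ct_total)
  ratio21 <- rq(wide$ct_exon21) / rq(wide$ct_total)

  # per-replicate normalization to the negative control of that replicate
  for (r in unique(wide$replicate)) {
    sel <- wide$replicate == r
    ctrl <- sel & wide$factor_id == neg_control
    if (sum(ctrl) != 1L)
      stop("need exactly one negative-control row per replicate")
    ratio5[sel] <- ratio5[sel] / ratio5[ctrl]
    ratio21[sel] <- ratio21[sel] / ratio21[ctrl]
  }
  fc5 <- tapply(ratio5, wide$factor_id, mean)
  fc21 <- tapply(ratio21, wide$factor_id, mean)
  detected <- tapply(detected_row, wide$factor_id, all)
  ids <- names(fc5)
  data.frame(factor_id = ids,
             psi_fc_exon5 = as.numeric(fc5),
             psi_fc_exon21 = as.numeric(fc21),
             detected = as.logical(detected[ids]),
             stringsAsFactors = FALSE)
}

screenZ <- function(fc, in_reference) {
  ref <- fc[in_reference]
  if (length(ref) < 2L) stop("need >= 2 reference factors for z-scores")
  s <- sd(ref)
  if (is.na(s) || s == 0) stop("degenerate screen: zero fold-change variance")
  (fc - mean(ref)) / s
}

hitRule <- function(z5, z21, z5_ctrl, z21_ctrl, sum_threshold = 2) {
  z5 > z5_ctrl & z21 > z21_ctrl & (z5 + z21) > sum_threshold
}

#' Score a dual-readout screen and call hits
#'
#' Computes per-factor PSI fold changes for both exon readouts (relative
#' quantities against the reference gene, the inclusion/total ratio
#' normalized per replicate to the negative control, then averaged over
#' replicates), converts them to z-scores over the detected non-control
#' library factors (sample sd; `include_controls = TRUE` adds the controls to
#' that reference distribution), and calls hits: both z-scores above the
#' positive control's and their sum above `sum_threshold`. Factors with any
#' amplicon at or above `detection_ct` are flagged undetected and can never
#' be hits.
#'
#' @param plate long data.frame: `factor_id`, `amplicon`
#'   (`exon5`/`exon21`/`total`/`reference`), `replicate`, `ct`.
#' @param pos_control,neg_control factor ids of the controls.
#' @param detection_ct detection limit in cycles.
#' @param sum_threshold minimum z5 + z21 for a hit.
#' @param include_controls include controls in the z-score reference
#'   distribution (default excludes them).
#' @return data.frame, one row per factor: fold changes, `z5`, `z21`,
#'   `detected`, `is_hit`, `role`.
#' @export
callHits <- function(plate, pos_control = "SMCHD1", neg_control = "GFP",
                     detection_ct = 35, sum_threshold = 2,
                     include_controls = FALSE) {
  fc <- screenFoldChanges(plate, neg_control, detection_ct)
  if (!pos_control %in% fc$factor_id)
    stop("positive control '", pos_control, "' absent from plate")
  is_control <- fc$factor_id %in% c(pos_control, neg_control)
  if (!fc$detected[fc$factor_id == pos_control])
    stop("positive control is below the detection limit")
  in_ref <- fc$detected & (include_controls | !is_control)
  if (sum(in_ref) < 3L) stop("need >= 3 detected factors for z-scores")
  z5 <- screenZ(fc$psi_fc_exon5, in_ref)
  z21 <- screenZ(fc$psi_fc_exon21, in_ref)
  zc5 <- z5[fc$factor_id == pos_control]
  zc21 <- z21[fc$factor_id == pos_control]
  out <- fc
  out$z5 <- z5
  out$z21 <- z21
  out$role <- ifelse(out$factor_id == pos_control, "pos_control",
                     ifelse(out$factor_id == neg_control, "neg_control",
                            "library"))
  out$is_hit <- out$role == "library" & out$detected &
    hitRule(z5, z21, zc5, zc21, sum_threshold)
  ord <- order(out$role != "neg_control", out$role != "pos_control",
               out$factor_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
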