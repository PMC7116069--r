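# Evaluation of a detected-and-classified syllable table against the
# generator's ground truth: detection rate at a timing tolerance and
# per-type label agreement.

#' Score detections against ground-truth annotations
#'
#' Matches every ground-truth syllable to the nearest detection by onset
#' (within the same pup when both tables carry `pup_id`); a syllable
#' counts as detected when both onset and offset errors are below
#' `tol_ms`. Label agreement is evaluated over the detected syllables.
#'
#' @param ground_truth Data frame with `onset_s`, `offset_s`, `type`.
#' @param detections Data frame with `onset_s`, `offset_s` and optionally
#'   `label`.
#' @param tol_ms Timing tolerance in ms (default 5).
#' @return List with `n_truth`, `n_detected`, `detection_rate`,
#'   `confusion` (truth x predicted table over detected syllables, when
#'   labels are present) and `label_accuracy` (per-type named vector).
#' @export
evaluate_detection <- function(ground_truth, detections, tol_ms = 5) {
  by_pup <- "pup_id" %in% names(ground_truth) && "pup_id" %in% names(detections)
  gt_parts <- if (by_pup) split(ground_truth, ground_truth$pup_id)
  else list(ground_truth)
  truth <- character(0); pred <- character(0); hit <- logical(0)
  for (gt in gt_parts) {
    det <- if (by_pup) detections[detections$pup_id == gt$pup_id[1], ]
    else detections
    for (i in seq_len(nrow(gt))) {
      ok <- FALSE; lab <- NA_character_
      if (nrow(det) > 0) {
        j <- which.min(abs(det$onset_s - gt$onset_s[i]))
        ok <- abs(det$onset_s[j] - gt$onset_s[i]) * 1000 < tol_ms &&
          abs(det$offset_s[j] - gt$offset_s[i]) * 1000 < tol_ms
        if (ok && "label" %in% names(det)) lab <- det$label[j]
      }
      truth <- c(truth, gt$type[i]); pred <- c(pred, lab); hit <- c(hit, ok)
    }
  }
  out <- list(n_truth = length(truth), n_detected = sum(hit),
              detection_rate = mean(hit))
  keep <- hit & !is.na(pred)
  if (any(keep)) {
    out$confusion <- table(truth = truth[keep], predicted = pred[keep])
    out$label_accuracy <- vapply(split(seq_along(truth[keep]), truth[keep]),
                                 function(ix) mean(pred[keep][ix] == truth[keep][ix]),
                                 numeric(1))
  }
  out
}
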