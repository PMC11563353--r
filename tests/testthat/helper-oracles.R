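# Exhaustive reference for the constrained-ROC threshold rule, written as
# plain loops over the candidate thresholds (decision rule: score >= theta).
threshold_oracle <- function(scores, labels, max_fpr = 0.30) {
  cands <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (th in cands) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    fpr <- sum(pred == 1 & labels == 0) / sum(labels == 0)
    if (fpr > max_fpr + 1e-12) next
    if (is.null(best) ||
          sens > best$sensitivity + 1e-15 ||
          (sens == best$sensitivity && fpr < best$fpr - 1e-15) ||
          (sens == best$sensitivity && fpr == best$fpr && th > best$threshold))
      best <- list(threshold = th, sensitivity = sens, fpr = fpr)
  }
  best
}
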