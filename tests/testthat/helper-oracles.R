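# Independent oracles, kept free of the implementation paths they check.

# Exhaustive pairwise Mann-Whitney enumeration of the ROC area.
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
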