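# Independent reference implementations used to cross-check the package.

# exhaustive maximization of the quadrant-entropy sum over all 255
# candidate thresholds, written directly from the definition
brute_force_entropy_threshold <- function(g, mask = NULL) {
  C <- ropscreen:::.glcm(g, mask)
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:254) {
    i <- t + 1L
    bg <- C[1:i, 1:i]
    fg <- C[(i + 1L):256L, (i + 1L):256L]
    sb <- sum(bg); sf <- sum(fg)
    if (sb <= 0 || sf <= 0) next
    pb <- bg[bg > 0] / sb
    pf <- fg[fg > 0] / sf
    H <- -sum(pb * log2(pb)) - sum(pf * log2(pf))
    if (H > best) {
      best <- H
      bt <- t
    }
  }
  bt
}
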