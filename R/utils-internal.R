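# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# log(sum(exp(x))) without overflow; -Inf entries allowed.
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Two-sided normal p-value for an estimate/SE pair, floored at the
# smallest value kept representable so the (0,1] invariant always holds.
.z_pvalue <- function(b, se) pmax(2 * stats::pnorm(-abs(b / se)), 1e-300)

.complement <- function(allele) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[allele])
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# Append one (variant, reason) block to a drop log.
.log_drop <- function(log, ids, reason) {
  if (length(ids) == 0) return(log)
  rbind(log, data.frame(variant_id = ids, reason = reason))
}

.empty_drop_log <- function() {
  data.frame(variant_id = character(), reason = character())
}

# Subset a HarmonizedSet by index, keeping the drop log.
.h_subset <- function(h, idx) {
  HarmonizedSet(h@variantId[idx], h@betaX[idx], h@seX[idx],
                h@betaY[idx], h@seY[idx],
                if (length(h@betaM)) h@betaM[idx] else numeric(0),
                if (length(h@seM)) h@seM[idx] else numeric(0),
                dropped = h@dropped)
}
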