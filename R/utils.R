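# Internal weighted-moment helpers. All use the population convention
# (denominator = total weight), which is what makes the index identities
# C = 2 cov_w(h, R)/hbar and E = 8 cov_w(h, R)/(hmax - hmin) exact.

.wmean <- function(x, w) sum(w * x) / sum(w)

.wcov <- function(x, y, w) {
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sum(w * (x - mx) * (y - my)) / W
}

.wvar <- function(x, w) .wcov(x, x, w)

.check_weights <- function(weights, n, what = "weights") {
  if (length(weights) != n) {
    stop(sprintf("`%s` must have length %d, not %d", what, n, length(weights)),
         call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop(sprintf("`%s` must be finite and non-missing", what), call. = FALSE)
  }
  if (any(weights <= 0)) {
    stop(sprintf("`%s` must be strictly positive (row %d is not)",
                 what, which(weights <= 0)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.effective_n <- function(w) sum(w)^2 / sum(w^2)

# Two-sided significance stars, per the usual survey-table convention:
# * p < 0.1, ** p < 0.05, *** p < 0.01.
.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

# Small stable FNV-1a hash of a serialized R object, used to fingerprint
# study configurations in run logs.
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
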