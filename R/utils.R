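## Internal helpers shared across modules.

## round() in R rounds half to even; edge counts use the conventional
## round-half-away-from-zero so that e.g. 10% of 30135 -> 3014.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Upper-triangle index pairs (i < j) of an n x n matrix in column-major
## order; the canonical edge enumeration used for flattening z matrices.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

## Deterministic sub-seed derivation: keeps every stage independently
## seeded from one master seed while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563) + 1L
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y lengths differ (%d vs %d)",
              length(x), length(y))
  stop_if_not(length(x) >= 2L, "AUC is undefined on fewer than 2 grid points")
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}
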