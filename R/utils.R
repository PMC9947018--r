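# internal numerical helpers shared across modules

# thin-plate kernel phi(r) = r^2 log r, expressed in squared distances:
# phi = 0.5 * d2 * log(d2), with phi(0) = 0 by continuity
.tps_phi <- function(d2) {
  out <- 0.5 * d2 * log(d2)  # 0 * log(0) yields NaN, patched below
  out[!is.finite(out)] <- 0
  out
}

# squared Euclidean distances between the rows of A (m x k) and B (q x k)
.pairdist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  d2
}

.assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# 32-bit polynomial rolling hash over a character scalar, hex-encoded;
# used to stamp pipeline outputs with the configuration that produced them
.hash32 <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
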