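# Shared fixtures and independent oracles.
#
# The oracles re-derive thin-plate-spline quantities with deliberately
# naive code (explicit double loops, qr.solve) so that agreement with the
# package is a genuine cross-check, not a tautology.

pressure_factors <- function() {
  list(factor_spec("pressure_A", 400, 800),
       factor_spec("pressure_B", 350, 750))
}

standard_design <- function() make_ccd(pressure_factors())

standard_transforms <- function() {
  c(size_nm = "log10", pdi = "identity", le_pct = "identity")
}

standard_goals <- function() {
  c(size_nm = "minimize", pdi = "minimize", le_pct = "maximize")
}

# wrap an arbitrary coded matrix as a design object
design_from_coded <- function(X, factors = pressure_factors()) {
  nms <- vapply(factors, `[[`, character(1), "name")
  des <- data.frame(run_id = seq_len(nrow(X)), role = "manual",
                    stringsAsFactors = FALSE)
  for (j in seq_along(nms)) {
    f <- factors[[j]]
    des[[paste0(nms[j], "_coded")]] <- X[, j]
    des[[nms[j]]] <- f$low + (X[, j] + 1) / 2 * (f$high - f$low)
  }
  structure(des, factors = factors, alpha = NA_real_,
            class = c("ccd_design", "data.frame"))
}

# naive dense solve of the augmented thin-plate system
oracle_tps_solve <- function(X, y, lambda = 0) {
  q <- nrow(X)
  k <- ncol(X)
  M <- matrix(0, q + k + 1L, q + k + 1L)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      M[i, j] <- if (r > 0) r^2 * log(r) else 0
    }
    M[i, i] <- M[i, i] + lambda
    M[i, q + 1L] <- 1
    M[q + 1L, i] <- 1
    for (d in seq_len(k)) {
      M[i, q + 1L + d] <- X[i, d]
      M[q + 1L + d, i] <- X[i, d]
    }
  }
  z <- qr.solve(M, c(y, rep(0, k + 1L)))
  list(w = z[seq_len(q)], c = z[q + 1L + 0:k])
}

# naive pointwise evaluation of the radial sum + affine part
oracle_tps_predict <- function(nodes, w, cc, points) {
  vapply(seq_len(nrow(points)), function(m) {
    v <- cc[1] + sum(cc[-1] * points[m, ])
    for (i in seq_len(nrow(nodes))) {
      r <- sqrt(sum((points[m, ] - nodes[i, ])^2))
      if (r > 0) v <- v + w[i] * r^2 * log(r)
    }
    v
  }, numeric(1))
}

# random distinct coded node sets for property tests
random_nodes <- function(n, k = 2L) {
  repeat {
    X <- matrix(stats::runif(n * k, -1.4, 1.4), n, k)
    if (min(dist(X)) > 1e-3) return(X)
  }
}
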