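# Independent oracles used to check package routines.  These deliberately
# re-derive everything from first principles (closed forms, triple loops)
# and share no code path with the implementation.

# Closed-form ordinary least squares via the sum formulas.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r_squared = r^2)
}

# Minimum-image displacement, re-derived (floor convention, not round).
oracle_wrap <- function(d, edge) {
  if (is.na(edge)) return(d)
  d <- d - floor(d / edge) * edge     # into [0, L)
  ifelse(d > edge / 2, d - edge, d)   # into (-L/2, L/2]
}

oracle_dist <- function(p, q, edges) {
  d <- mapply(oracle_wrap, q - p, edges)
  sqrt(sum(d^2))
}

# Exhaustive O(N^3) hydrogen-bond enumeration over (donor, H, acceptor).
brute_hbonds <- function(frame, max_dist = 3.0, min_angle = 120,
                         covalent = 1.2) {
  at <- frame$atoms; X <- frame$coords
  edges <- if (frame$cell$periodic) frame$cell$edges else rep(NA_real_, 3)
  found <- list()
  for (h in which(at$element == "H")) {
    for (d in which(at$element == "O")) {
      if (oracle_dist(X[d, ], X[h, ], edges) > covalent) next
      for (a in which(at$element == "O")) {
        if (a == d) next
        r_ha <- oracle_dist(X[h, ], X[a, ], edges)
        if (r_ha > max_dist || r_ha == 0) next
        vhd <- mapply(oracle_wrap, X[d, ] - X[h, ], edges)
        vha <- mapply(oracle_wrap, X[a, ] - X[h, ], edges)
        cosang <- sum(vhd * vha) / sqrt(sum(vhd^2) * sum(vha^2))
        ang <- acos(max(-1, min(1, cosang))) * 180 / pi
        if (ang < min_angle) next
        found[[length(found) + 1L]] <-
          c(donor = at$index[d], hydrogen = at$index[h], acceptor = at$index[a])
      }
    }
  }
  if (!length(found))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  out <- as.data.frame(do.call(rbind, found))
  out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
}

# O(N^2) double-loop nonbonded energy.
brute_pair_energy <- function(frame, params, idx = seq_len(nrow(frame$atoms))) {
  at <- frame$atoms; X <- frame$coords
  edges <- if (frame$cell$periodic) frame$cell$edges else rep(NA_real_, 3)
  e <- 0
  for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
    if (jj <= ii) next
    i <- idx[ii]; j <- idx[jj]
    r <- oracle_dist(X[i, ], X[j, ], edges)
    if (r > params$cutoff) next
    sig <- (params$sigma[at$element[i]] + params$sigma[at$element[j]]) / 2
    eps <- sqrt(params$epsilon[at$element[i]] * params$epsilon[at$element[j]])
    e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6) +
      params$coulomb_k * at$charge[i] * at$charge[j] / r
  }
  unname(e)
}

# Full minimum-image distance matrix by double loop (periodic cubic box).
cross_dist_oracle <- function(pts, edge) {
  n <- nrow(pts)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) m[i, j] <- oracle_dist(pts[i, ], pts[j, ], rep(edge, 3))
  m
}

table1 <- function() utils::read.csv(study_table("calibration"))

table2 <- function(system = NULL) {
  df <- utils::read.csv(study_table("phase_solubility"))
  if (is.null(system)) df else df[df$system == system, ]
}
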