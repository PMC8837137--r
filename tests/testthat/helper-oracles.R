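# Shared fixtures and independent oracles, built in code at test time.

# Axis-aligned cube mesh (12 triangles), outward-wound.
cube_mesh <- function(side = 10, offset = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  v <- sweep(v, 2, offset, "+")
  f <- matrix(c(1, 3, 2, 2, 3, 4, 5, 6, 7, 6, 8, 7, 1, 2, 5, 2, 6, 5,
                3, 7, 4, 4, 7, 8, 1, 5, 3, 3, 5, 7, 2, 4, 6, 4, 8, 6),
              ncol = 3, byrow = TRUE)
  m <- triangle_mesh(v, f)
  if (mesh_volume(m) < 0) m <- triangle_mesh(v, f[, c(1, 3, 2)])
  m
}

sphere_mesh <- function(r = 10, detail = "fine") {
  make_bone_like_mesh("ellipsoid", c(r, r, r), detail = detail,
                      modulation_sd = 0)
}

# Brute-force point-to-triangle distance (independent of the compiled path):
# dense barycentric sampling refined by local optimization of the quadratic.
oracle_point_tri_dist <- function(p, a, b, c) {
  # distance to triangle == constrained quadratic in (u, v); solve by
  # checking the unconstrained optimum and all edges/vertices
  e1 <- b - a; e2 <- c - a; d <- a - p
  A <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- -c(sum(e1 * d), sum(e2 * d))
  cands <- list(c(0, 0), c(1, 0), c(0, 1))
  if (abs(det(A)) > 1e-300) {
    uv <- solve(A, rhs)
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) cands <- c(cands, list(uv))
  }
  seg <- function(t) pmin(pmax(t, 0), 1)
  # edge a-b (v = 0), edge a-c (u = 0), edge b-c (u + v = 1)
  cands <- c(cands,
             list(c(seg(rhs[1] / A[1, 1]), 0)),
             list(c(0, seg(rhs[2] / A[2, 2]))),
             list({
               e3 <- c - b; d3 <- b - p
               t <- seg(-sum(e3 * d3) / sum(e3 * e3))
               c(1 - t, t)
             }))
  min(vapply(cands, function(uv) {
    q <- a + uv[1] * e1 + uv[2] * e2
    sqrt(sum((p - q)^2))
  }, 0))
}

oracle_point_mesh_dist <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(j) {
    oracle_point_tri_dist(p, mesh$vertices[mesh$faces[j, 1], ],
                          mesh$vertices[mesh$faces[j, 2], ],
                          mesh$vertices[mesh$faces[j, 3], ])
  }, 0))
}

# Brute-force CPD responsibilities by direct per-element evaluation.
oracle_cpd_posteriors <- function(Y, X, sigma2, w) {
  M <- nrow(Y); N <- nrow(X)
  P <- matrix(0, M, N)
  for (n in seq_len(N)) {
    k <- numeric(M)
    for (m in seq_len(M))
      k[m] <- exp(-sum((X[n, ] - Y[m, ])^2) / (2 * sigma2))
    cc <- if (w > 0) (2 * pi * sigma2)^1.5 * (w / (1 - w)) * M / N else 0
    P[, n] <- k / (sum(k) + cc)
  }
  P
}

# Exact two-sided rank-sum p by full enumeration of rank assignments.
oracle_rank_sum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-sided signed-rank p by full enumeration of sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

max_transform_diff <- function(a, b) {
  max(max(abs(a$rotation - b$rotation)), max(abs(a$translation - b$translation)))
}
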