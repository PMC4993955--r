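# Independent oracles and small fixtures used across test files.

# random proper rotation matrix
randomRotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -pi, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Independent point-to-triangle distance: project the point onto the
# triangle's plane; if the projection's barycentric coordinates are inside,
# the distance is the plane distance; otherwise the minimum point-to-segment
# distance over the three edges. A different formulation from the package's
# Voronoi-region implementation.
pointSegDist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  sqrt(sum((a + t * ab - p)^2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

pointTriDistOracle <- function(p, a, b, c) {
  n <- cross3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-14) stop("degenerate triangle in oracle")
  n <- n / nn
  q <- p - sum((p - a) * n) * n  # projection onto plane
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((q - p)^2)))
  min(pointSegDist(p, a, b), pointSegDist(p, a, c), pointSegDist(p, b, c))
}

meshDistOracle <- function(points, mesh) {
  mean(vapply(seq_len(nrow(points)), function(i) {
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      v <- mesh$faces[f, ]
      pointTriDistOracle(points[i, ], mesh$vertices[v[1], ],
                         mesh$vertices[v[2], ], mesh$vertices[v[3], ])
    }, numeric(1)))
  }, numeric(1)))
}

# exhaustive optimal 1:1 assignment minimizing total |delta ps|
# (small instances only)
optimalMatchCost <- function(psCases, psControls) {
  nC <- length(psCases); nK <- length(psControls)
  stopifnot(nK >= nC, nC <= 8)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > nC) { best <<- cost; return() }
    for (j in seq_len(nK)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + abs(psCases[i] - psControls[j]))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nK), 0)
  best
}

# matched pairs with known conditional log-odds beta: covariates drawn for
# two pair members; which member is the case follows the conditional
# probability exp(x1 b) / (exp(x1 b) + exp(x2 b))
simulateClrPairs <- function(n, beta) {
  k <- length(beta)
  x1 <- matrix(rnorm(n * k), n, k)
  x2 <- matrix(rnorm(n * k), n, k)
  p1 <- plogis(drop((x1 - x2) %*% beta))
  firstIsCase <- runif(n) < p1
  xCase <- ifelse(matrix(firstIsCase, n, k), x1, x2)
  xControl <- ifelse(matrix(firstIsCase, n, k), x2, x1)
  list(xCase = xCase, xControl = xControl)
}

# small deterministic knee table for selection tests
kneeRow <- function(pid, side, pain = 5, kl = 2, tkr = FALSE, interval = NA,
                    indication = if (tkr) "OA" else NA_character_,
                    age = 60, bmi = 27, gender = "female", hasShape = TRUE) {
  data.frame(participant_id = pid,
             knee_id = paste0(pid, "_", ifelse(side == "left", "L", "R")),
             side = side, age = age, gender = gender, bmi = bmi,
             nrs_pain = pain, kl_grade = kl, severity = 0, shape_severity = 0,
             tkr = tkr, tkr_interval_years = interval, indication = indication,
             insurance = TRUE, has_shape = hasShape, stringsAsFactors = FALSE)
}
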