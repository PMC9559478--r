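# Independent oracles used to check the package implementations.
# These deliberately use the slowest, most literal formulation of each
# quantity and never share code with the functions they verify.

# AUC by explicit enumeration of all positive-negative pairs (ties = 1/2).
bf_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Ordinary least squares coefficients on centered/scaled predictors
# against the centered response, via the normal equations.
bf_ols <- function(X, y) {
  Xs <- scale(X)
  yc <- y - mean(y)
  drop(solve(crossprod(Xs), crossprod(Xs, yc)))
}

# Ward.D2 agglomeration by brute force: at every step the merge cost of
# each cluster pair is recomputed from scratch from the cluster members,
#   cost(A, B) = sqrt( 2 |A||B| / (|A|+|B|) * ||mean(A) - mean(B)||^2 ),
# and the cheapest pair merges. Returns the merge heights and the
# partition after each merge (list of sorted member vectors).
bf_ward_d2 <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        A <- clusters[[i]]
        B <- clusters[[j]]
        muA <- colMeans(m[A, , drop = FALSE])
        muB <- colMeans(m[B, , drop = FALSE])
        cost <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                       sum((muA - muB)^2))
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
    heights <- c(heights, best_cost)
    partitions[[length(partitions) + 1]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition given as a list of member index vectors.
canonical_partition <- function(clusters) {
  cl <- lapply(unname(clusters), function(g) as.integer(sort(g)))
  cl[order(vapply(cl, `[`, integer(1), 1))]
}

# Canonical form of a partition given as an assignment vector.
canonical_assignment <- function(assign) {
  canonical_partition(split(seq_along(assign), assign))
}

# Small modeling table: labeled subset + predictor matrix for one scheme.
sim_modeling_data <- function(n_farms = 20, n_years = 2, scheme = 1,
                              seed = 7, schema = default_trait_schema()) {
  d <- generate_dataset(n_farms, n_years, schema = schema, seed = seed)
  build_modeling_subset(label_records(d, scheme))
}

# Designs whose single-component PLS weight vector is exactly known.
# Columns are built from an orthonormal basis that is orthogonal to both
# the centered response and the ones vector, so centering and
# unit-variance scaling cannot disturb the construction:
#   X_e1:  col 1 = centered response, cols 2..4 orthogonal to it
#          -> weight vector exactly proportional to (1, 0, 0, 0);
#   X_sym: col j = centered response + 0.5 * basis_j (equal norms)
#          -> weight vector exactly proportional to (1, 1, 1, 1).
make_vip_designs <- function(seed = 42) {
  n <- 12
  y <- rep(c(0L, 1L), each = n / 2)
  yc <- y - mean(y)
  set.seed(seed)
  Q <- qr.Q(qr(cbind(yc, rep(1, n), matrix(rnorm(n * 4), n, 4))))
  E <- Q[, 3:6]
  X_e1 <- cbind(yc, E[, 1], E[, 2], E[, 3])
  X_sym <- vapply(1:4, function(j) yc + 0.5 * E[, j], numeric(n))
  colnames(X_e1) <- colnames(X_sym) <- paste0("x", 1:4)
  list(y = y, X_e1 = X_e1, X_sym = X_sym)
}
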