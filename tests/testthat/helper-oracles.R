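# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# exhaustive circular cross-correlation argmax over integer shifts; the
# returned value is the correction shift (negated content shift), matching
# phase_correlate()'s convention
oracle_shift <- function(frame, template, max_disp) {
  best <- c(0L, 0L); bv <- -Inf
  for (dy in -max_disp:max_disp) for (dx in -max_disp:max_disp) {
    v <- sum(frame * dendromap:::roll_matrix(template, dy, dx))
    if (v > bv) { bv <- v; best <- c(dy, dx) }
  }
  -best
}

# brute-force per-pixel Pearson correlation loop
oracle_corr_map <- function(stack, seed, radius) {
  d <- dim(stack$data)
  seed_ts <- stack$data[, seed[1], seed[2]]
  out <- matrix(0, d[2], d[3])
  for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if ((r - seed[1])^2 + (c - seed[2])^2 > radius^2) next
    ts <- stack$data[, r, c]
    if (stats::sd(ts) == 0) next
    out[r, c] <- stats::cor(seed_ts, ts)
  }
  out
}

# direct superposition of exponential kernels (vs the recursive filter)
oracle_superposition <- function(events, tau) {
  T_ <- length(events)
  out <- numeric(T_)
  for (t in which(events != 0))
    out[t:T_] <- out[t:T_] + events[t] * exp(-(0:(T_ - t)) / tau)
  out
}

# naive min distance from a point to a set of segments
oracle_point_polyline <- function(pt, path) {
  best <- Inf
  for (s in seq_len(nrow(path) - 1)) {
    a <- path[s, ]; b <- path[s + 1, ]
    for (t in seq(0, 1, length.out = 2001)) {
      p <- a + t * (b - a)
      best <- min(best, sqrt(sum((pt - p)^2)))
    }
  }
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# exhaustive optimal one-to-one matching under a distance cap:
# maximum cardinality first, then minimum total distance
oracle_matching <- function(c1, c2, max_disp) {
  n1 <- nrow(c1); n2 <- nrow(c2)
  d <- sqrt(outer(c1[, 1], c2[, 1], "-")^2 + outer(c1[, 2], c2[, 2], "-")^2)
  best <- list(k = -1L, cost = Inf, pairs = cbind(integer(0), integer(0)))
  ks <- seq(min(n1, n2), 0)
  for (k in ks) {
    if (k < best$k) break
    if (k == 0) {
      if (best$k < 0) best <- list(k = 0L, cost = 0,
                                   pairs = cbind(integer(0), integer(0)))
      break
    }
    rows_sets <- utils::combn(n1, k, simplify = FALSE)
    cols_sets <- utils::combn(n2, k, simplify = FALSE)
    for (rs in rows_sets) for (cs in cols_sets)
      for (p in all_permutations(seq_len(k))) {
        dd <- d[cbind(rs, cs[p])]
        if (any(dd > max_disp)) next
        cost <- sum(dd)
        if (k > best$k || (k == best$k && cost < best$cost))
          best <- list(k = k, cost = cost, pairs = cbind(rs, cs[p]))
      }
    if (best$k == k) break
  }
  best
}

# tiny feature map of point-like spines at given centroids
toy_map <- function(centroids, image_dim = c(64, 64), ids = NULL,
                    dendrite = NULL) {
  spines <- list()
  for (i in seq_len(nrow(centroids))) {
    m <- matrix(FALSE, image_dim[1], image_dim[2])
    r <- round(centroids[i, 1]); c <- round(centroids[i, 2])
    m[r, c] <- TRUE
    s <- dendromap:::spine_roi(if (is.null(ids)) i else ids[i], m,
                               seed = c(r, c))
    s$centroid <- as.numeric(centroids[i, ])  # keep sub-pixel positions
    if (!is.null(dendrite)) s$parent_dendrite <- dendrite$id
    spines[[i]] <- s
  }
  feature_map(spines = spines,
              dendrites = if (is.null(dendrite)) list() else list(dendrite),
              image_dim = image_dim)
}
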