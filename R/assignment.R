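# Jonker-Volgenant / Hungarian solver for the rectangular linear
# assignment problem (rows <= cols), O(n^2 m). Written here because no
# installed package exposes a linear-assignment routine; verified against
# brute-force enumeration in the test suite.
#
# cost: n x m numeric matrix, n <= m. Returns an integer vector a with
# a[i] = column assigned to row i (every row is assigned).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("solve_assignment needs nrow(cost) <= ncol(cost)")
  INF <- .Machine$double.xmax / 4
  # index offset: column j of `cost` is j + 1 here; index 1 is a virtual
  # column holding the row currently being inserted
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)       # p[j] = row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF; j1 <- 0L
      free_j <- which(!used)
      free_j <- free_j[free_j > 1L]
      if (length(free_j)) {
        cur <- cost[i0, free_j - 1L] - u[i0 + 1L] - v[free_j]
        upd <- cur < minv[free_j]
        if (any(upd)) {
          minv[free_j[upd]] <- cur[upd]
          way[free_j[upd]] <- j0
        }
        j1 <- free_j[which.min(minv[free_j])]
        delta <- minv[j1]
      }
      if (!is.finite(delta)) stop("assignment infeasible")
      iu <- which(used)
      u[p[iu] + 1L] <- u[p[iu] + 1L] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0) a[p[j]] <- j - 1L
  a
}
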