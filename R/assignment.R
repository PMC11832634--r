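# Linear assignment problem, shortest-augmenting-path (Jonker-Volgenant
# style) with dual potentials; O(n^3).  Costs must be finite; use a large
# finite sentinel for forbidden pairs.
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (n == 0) return(integer(0))
  if (!all(is.finite(cost))) stop("costs must be finite")
  u <- numeric(n)       # row potentials
  v <- numeric(n + 1)   # col potentials; index 1 is the virtual column
  p <- integer(n + 1)   # p[j]: row currently assigned to column j-1 (0 none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used)
      cur <- cost[i0, js - 1L] - u[i0] - v[js]
      upd <- cur < minv[js]
      if (any(upd)) {
        minv[js[upd]] <- cur[upd]
        way[js[upd]] <- j0
      }
      j1 <- js[which.min(minv[js])]
      delta <- minv[j1]
      ju <- which(used)
      u[p[ju]] <- u[p[ju]] + delta
      v[ju] <- v[ju] - delta
      minv[js] <- minv[js] - delta
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
  # p[j+1] = row assigned to column j; invert to row -> column
  assign_col <- integer(n)
  assign_col[p[2:(n + 1)]] <- seq_len(n)
  assign_col
}
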