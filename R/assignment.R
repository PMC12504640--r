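# Linear sum assignment (Jonker-Volgenant shortest augmenting path),
# minimizing total cost over an n x m cost matrix with n <= m.
# Returns for each row its assigned column. O(n^2 m); plenty for the
# domain-matching sizes used here (hundreds of domains).
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop2("cost matrix must have nrow <= ncol")
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j]: row currently assigned to column j (0 = none)
  way <- integer(m + 1) # predecessor column on the augmenting path
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) match[p[j]] <- j
  match
}
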