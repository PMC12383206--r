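# Independent oracles used across tests, kept deliberately naive so they
# never share code with the implementation under test.

# BFS flood-fill component count for pixels equal to `value`.
oracle_component_count <- function(mask, value, connectivity = 8) {
  m <- matrix(as.integer(mask), nrow(mask))
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 8)
    rbind(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  count <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (m[i, j] != value || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(offs))) {
        ii <- p[1] + offs[d, 1]; jj <- p[2] + offs[d, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            m[ii, jj] == value && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  count
}

# per-class pixel histogram
oracle_class_counts <- function(mask) {
  vapply(0:3, function(k) sum(mask == k), numeric(1))
}
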