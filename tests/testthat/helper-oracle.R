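# Independent oracle for the fitting-alignment optimum: exhaustive search
# over block decompositions by memoized recursion, written against the
# scoring definition (not the DP implementation).
oracleFitScore <- function(qf, rf, p = alignParams()) {
  m <- length(qf); n <- length(rf)
  Q <- c(0, cumsum(qf)); R <- c(0, cumsum(rf))
  sb <- function(x, y, interior, free) {
    s <- p@matchBonus - p@cutPenalty * interior
    if (!free) s <- s - (x - y)^2 /
        (2 * p@sizingVarPerBp * max(x, p@sizingFloor))
    s
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- -Inf
    for (a in seq_len(min(p@delta, i))) {
      y <- Q[i + 1] - Q[i - a + 1]
      for (b in seq_len(min(p@delta, j))) {
        x <- R[j + 1] - R[j - b + 1]
        qstart1 <- (i - a == 0); rstart1 <- (j - b == 0)
        qend <- (i == m); rend <- (j == n)
        freeL <- (qstart1 && y < x && b <= 2) || (rstart1 && x < y && a <= 2)
        freeR <- (qend && y < x && b <= 2) || (rend && x < y && a <= 2)
        interior <- a + b - 2
        if (qstart1 || rstart1)
          res <- max(res, sb(x, y, interior, freeL || freeR))
        if (i - a >= 1 && j - b >= 1) {
          prev <- f(i - a, j - b)
          if (is.finite(prev))
            res <- max(res, prev + sb(x, y, interior, freeR))
        }
      }
    }
    memo[[key]] <- res
    res
  }
  cand <- vapply(seq_len(n), function(j) f(m, j), numeric(1))
  if (m > 1)
    cand <- c(cand, vapply(seq_len(m - 1), function(i) f(i, n), numeric(1)))
  max(cand)
}

# best fitting-alignment score over both orientations via the compiled DP
dpFitScore <- function(qf, rf, p = alignParams()) {
  s1 <- omtk:::cpp_fit_align(qf, rf, as.integer(p@delta), p@matchBonus,
                             p@cutPenalty, p@sizingVarPerBp, p@sizingFloor)
  s1$score
}
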