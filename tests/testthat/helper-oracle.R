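## Independent oracles, coded literally and separately from the package
## implementation. Used on small inputs only.

## Literal four-phase nucleosome caller. Candidates are kept as a plain
## list of (start, end) pairs; every pass rescans from scratch and restarts
## after the first change, so the fixed point is reached by brute force.
oracle_nucleosomes <- function(m, L, n = 75, c = 100, e = 25) {
  cands <- list()
  ## phase 1: scan every maximal m6A-free run
  marked <- rep(FALSE, L)
  if (length(m)) marked[m + 1] <- TRUE
  i <- 0
  while (i < L) {
    if (!marked[i + 1]) {
      j <- i
      while (j < L && !marked[j + 1]) j <- j + 1
      if (j - i >= n) cands[[length(cands) + 1]] <- c(i, j)
      i <- j
    } else i <- i + 1
  }
  ## phase 2: for every mark, the region between its neighbouring marks
  ## (read ends as boundaries) with that one internal m6A
  for (t in seq_along(m)) {
    lo <- if (t == 1) -1 else m[t - 1]
    hi <- if (t == length(m)) L else m[t + 1]
    if (hi - lo - 1 >= c) cands[[length(cands) + 1]] <- c(lo + 1, hi)
  }
  merge_all <- function(cands) {
    if (length(cands) < 2) return(cands)
    o <- order(vapply(cands, `[`, 0, 1))
    cands <- cands[o]
    out <- list(cands[[1]])
    for (k in 2:length(cands)) {
      lastc <- out[[length(out)]]
      if (cands[[k]][1] <= lastc[2])
        out[[length(out)]] <- c(lastc[1], max(lastc[2], cands[[k]][2]))
      else out[[length(out) + 1]] <- cands[[k]]
    }
    out
  }
  cands <- merge_all(cands)
  if (!length(cands)) return(matrix(numeric(0), ncol = 2))

  ## phases 3 + 4: restart after every single change. After an extension,
  ## the extended candidate merges with the neighbour on the extended side
  ## when they overlap or are separated by just the spanned m6A.
  repeat {
    changed <- FALSE
    for (k in seq_along(cands)) {
      s <- cands[[k]][1]; en <- cands[[k]][2]
      ## left extension across the mark at s - 1
      if (s > 0) {
        prev_marks <- m[m <= s - 2]
        run_start <- if (length(prev_marks)) max(prev_marks) + 1 else 0
        if ((s - 1) - run_start >= e) {
          cands[[k]][1] <- run_start
          if (k > 1 && cands[[k]][1] - cands[[k - 1]][2] <= 1) {
            cands[[k]][1] <- cands[[k - 1]][1]
            cands[[k - 1]] <- NULL
          }
          changed <- TRUE
          break
        }
      }
      ## right extension across the mark at en
      if (en < L) {
        next_marks <- m[m >= en + 1]
        run_end <- if (length(next_marks)) min(next_marks) else L
        if (run_end - en - 1 >= e) {
          cands[[k]][2] <- run_end
          if (k < length(cands) && cands[[k + 1]][1] - cands[[k]][2] <= 1) {
            cands[[k]][2] <- max(cands[[k]][2], cands[[k + 1]][2])
            cands[[k + 1]] <- NULL
          }
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  do.call(rbind, cands)
}

## Two-sided Fisher p by exhaustive hypergeometric enumeration: the sum of
## the probabilities of all tables (same margins) no more likely than the
## observed one.
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Textbook Benjamini-Hochberg step-up adjusted values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}
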