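# Shared fixtures and independent oracles used across test files.

# A small annotation with known geometry: one plus-strand tRNA, one
# minus-strand tRNA, one plus-strand YRNA, far apart on one chromosome.
tiny_annotation <- function() {
  data.frame(
    locus_id = c("tRNA-plus", "tRNA-minus", "YRNA-plus"),
    chrom = "chr1",
    start = c(1000L, 5000L, 9000L),
    end = c(1072L, 5072L, 9095L),
    strand = c("+", "-", "+"),
    class = c("tRNA", "tRNA", "YRNA"),
    stringsAsFactors = FALSE
  )
}

# build a one-row read record
mk_read <- function(start, end, strand = "+", chrom = "chr1",
                    sample_id = "S1", read_id = "r1") {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, length = end - start + 1L,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Independent brute-force BH step-up: q(i) = min_{j >= i} p_(j) * m / j,
# computed by an explicit scan, order restored.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent triple-loop TOM oracle.
tom_oracle <- function(A) {
  A0 <- A
  diag(A0) <- 0
  n <- nrow(A0)
  k <- rowSums(A0)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + A0[i, u] * A0[u, j]
      }
      tom[i, j] <- (l + A0[i, j]) / (min(k[i], k[j]) + 1 - A0[i, j])
    }
  }
  tom
}

# Independent conditional NB exact-test oracle. For two NB group sums with
# sizes r1 = n1/phi, r2 = n2/phi and a common per-sample mean, the success
# probabilities coincide, so the mean-dependent factors cancel and the
# conditional law of the split given the total is negative hypergeometric:
# P(i) proportional to C(i + r1 - 1, i) * C(s - i + r2 - 1, s - i).
# This derivation never touches the pooled-mean plug-in the implementation
# uses.
exact_test_oracle <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  i <- 0:s
  lp <- if (phi <= 1e-10) {
    dbinom(i, s, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    lchoose(i + r1 - 1, i) + lchoose(s - i + r2 - 1, s - i)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[s1 + 1] * (1 + 1e-10)]))
}
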