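# Brute-force oracle for the two-library exact test: direct log-space
# tail summation of the Audic-Claverie kernel
#   P(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y)),
# normalised by its total mass (1 + N2/N1), in the same canonical
# orientation as the implementation (condition on the lower-rate count).

acBruteForce <- function(x, y, n1, n2) {
  if (x / n1 > y / n2 || (x / n1 == y / n2 && x > y)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  pmf <- function(yy)
    exp(yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
        lgamma(yy + 1) - (x + yy) * log(1 + r)) / (1 + r)
  lo <- sum(pmf(0:y))
  # upper tail summed directly (never via 1 - lower) so tiny p-values
  # keep full precision; terms decay geometrically
  hi <- 0; yy <- y
  repeat {
    term <- pmf(yy)
    hi <- hi + term
    yy <- yy + 1
    if ((term < hi * 1e-18 && yy > y + 10) || yy > y + 1e5) break
  }
  min(1, 2 * min(lo, hi))
}
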