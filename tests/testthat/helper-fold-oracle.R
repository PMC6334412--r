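# Independent pure-R oracle for stem-loop folding: exhaustive recursive
# search over every legal single-hairpin structure (nested pair chains
# closed by one terminal loop), scoring each loop/stack from the same
# parameter list but through separately written code.  No memoisation,
# no sharing with the C++ dynamic program.

.oPairType <- function(a, b) {
  key <- paste0(a, b)
  switch(key, CG = 1L, GC = 2L, GT = 3L, TG = 4L, AT = 5L, TA = 6L, 0L)
}

.oExtrap <- function(tab, n, lxc) {
  m <- length(tab)
  if (n <= m) tab[n] else tab[m] + lxc * log(n / m)
}

.oLoopE <- function(P, p1, p2, a, b) {
  if (a == 0 && b == 0) return(P$stack[p1, p2])
  n <- a + b
  if (a == 0 || b == 0) {
    e <- .oExtrap(P$bulge, n, P$lxc)
    if (n == 1) e <- e + P$stack[p1, p2]
    return(e)
  }
  .oExtrap(P$internal, n, P$lxc) + min(P$asymMax, P$asym * abs(a - b))
}

# minimum energy over all hairpin structures closed by pair (i, j)
.oClosed <- function(ch, pt, P, i, j) {
  best <- if (j - i - 1 >= P$minHairpin)
    .oExtrap(P$hairpin, j - i - 1, P$lxc) else Inf
  for (k in (i + 1):(j - 1)) {
    a <- k - i - 1
    if (a > P$maxLoop) break
    if (k + P$minHairpin + 1 > j - 1) break
    for (l in (j - 1):(k + P$minHairpin + 1)) {
      b <- j - l - 1
      if (a + b > P$maxLoop) break
      p2 <- pt[k, l]
      if (p2 == 0) next
      e <- .oLoopE(P, pt[i, j], p2, a, b) + .oClosed(ch, pt, P, k, l)
      if (e < best) best <- e
    }
  }
  best
}

oracleFoldMFE <- function(seq, params = mirswim::foldParams()) {
  ch <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  n <- length(ch)
  pt <- matrix(0L, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) pt[i, j] <- .oPairType(ch[i], ch[j])
  best <- 0
  if (n >= params$minHairpin + 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + params$minHairpin + 1):n) {
        if (j > n) break
        if (pt[i, j] == 0) next
        e <- .oClosed(ch, pt, params, i, j)
        if (e < best) best <- e
      }
    }
  }
  best
}

randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
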