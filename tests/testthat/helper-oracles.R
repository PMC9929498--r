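## Independent oracles and fixture builders shared across the suite.
## These deliberately use brute-force algorithms (label propagation,
## per-pixel counting, direct formulas) that share no code with the
## package's implementations.

## connected-component count by iterated minimum-label propagation
labelCount <- function(b, conn = 8) {
  H <- nrow(b); W <- ncol(b)
  lab <- matrix(0L, H, W)
  lab[b] <- seq_len(sum(b))
  offs <- if (conn == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    p <- matrix(0L, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- lab
    new <- lab
    for (o in offs) {
      nb <- p[2:(H + 1) + o[1], 2:(W + 1) + o[2]]
      upd <- b & nb > 0L & (new == 0L | nb < new)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[lab > 0L]))
}

## flood-fill Euler characteristic: components minus holes, where holes
## are background components (complementary connectivity) that do not
## touch the frame
eulerOracle <- function(b, connectivity = 8) {
  bgconn <- if (connectivity == 8) 4 else 8
  comps <- labelCount(b, connectivity)
  H <- nrow(b); W <- ncol(b)
  padbg <- matrix(TRUE, H + 2, W + 2)
  padbg[2:(H + 1), 2:(W + 1)] <- !b
  nbg <- labelCount(padbg, bgconn)   # the frame joins all outer background
  as.integer(comps - (nbg - 1L))
}

## closed-form Wald statistics for a saturated one-factor logit design:
## log-odds differences and sqrt of summed reciprocal cell counts
saturatedOracle <- function(counts, ns, reference) {
  r0 <- counts[[reference]]; n0 <- ns[[reference]]
  others <- setdiff(names(counts), reference)
  t(vapply(others, function(tr) {
    r <- counts[[tr]]; n <- ns[[tr]]
    est <- log(r / (n - r)) - log(r0 / (n0 - r0))
    se <- sqrt(1 / r + 1 / (n - r) + 1 / r0 + 1 / (n0 - r0))
    c(estimate = est, se = se)
  }, numeric(2)))
}

## per-pixel area count by explicit loop
areaOracle <- function(b) {
  n <- 0L
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b)))
    if (b[i, j]) n <- n + 1L
  n
}

## filled axis-aligned square mask
makeSquare <- function(n, pad = 5) {
  m <- matrix(FALSE, n + 2 * pad, n + 2 * pad)
  m[(pad + 1):(pad + n), (pad + 1):(pad + n)] <- TRUE
  m
}

## digital disc mask
makeDisc <- function(r, pad = 5) {
  d <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  outer(seq_len(d), seq_len(d),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

## two-level image: background 0, markings 1 on the given mask
twoLevelImage <- function(mask) {
  px <- matrix(0, nrow(mask), ncol(mask))
  px[mask] <- 1
  IntensityImage(px)
}

## write a matrix to a temporary PNG, returning the path
writeTempPng <- function(px, bits = 8) {
  f <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(t(px)), f, bits.per.sample = bits)
  f
}
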