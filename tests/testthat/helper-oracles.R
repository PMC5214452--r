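# Independent brute-force oracles and small fixture builders.

# AUC by explicit all-pairs counting (wins + half-ties).
bruteAucPairs <- function(values, case) {
  vc <- values[case]
  vn <- values[!case]
  tot <- 0
  for (a in vc) tot <- tot + sum(a > vn) + 0.5 * sum(a == vn)
  tot / (length(vc) * length(vn))
}

# Connected-component filtering by per-seed breadth-first flood fill.
bruteFloodFilter <- function(mask, minVoxels, neighborhood) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(neighborhood),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  visited <- array(FALSE, d)
  out <- array(FALSE, d)
  for (seed in which(mask)) {
    if (visited[seed]) next
    comp <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (r in seq_len(nrow(off))) {
        nb <- co + rep(off[r, ], each = nrow(co))
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] +
               (nb[ok, 3] - 1) * d[1] * d[2]
        lin <- lin[mask[lin] & !visited[lin]]
        if (length(lin)) {
          visited[lin] <- TRUE
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
      comp <- c(comp, frontier)
    }
    if (length(comp) >= minVoxels) out[comp] <- TRUE
  }
  out
}

# Otsu by exhaustive between-class variance maximization over all
# candidate cuts between adjacent distinct values.
bruteOtsuMask <- function(x) {
  u <- sort(unique(as.numeric(x)))
  cands <- (u[-1] + u[-length(u)]) / 2
  bc <- vapply(cands, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  x > cands[which.max(bc)]
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
enumFisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(ks, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# Freeman-Halton p for a 2xK table by full enumeration of tables with the
# observed margins.
enumFisher2xK <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); K <- ncol(tab)
  logProb <- function(row1) {
    sum(lchoose(cs, row1)) - lchoose(sum(cs), r1)
  }
  rows <- expand.grid(lapply(cs, function(m) 0:m))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  lp <- apply(rows, 1, logProb)
  pObs <- logProb(tab[1, ])
  sum(exp(lp[lp <= pObs + 1e-7]))
}

randomMask <- function(d, p) array(runif(prod(d)) < p, d)

# Tiny grid-by-patient cohort built directly from FTV matrices.
toyCohort <- function(ftvList, pcr, grid,
                      hr = rep("+", length(pcr)),
                      her2 = rep("-", length(pcr))) {
  ids <- sprintf("P%02d", seq_along(pcr))
  assays <- stats::setNames(lapply(ftvList, function(m) {
    dimnames(m) <- list(NULL, ids)
    m
  }), paste0("ftv", seq_along(ftvList)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(grid),
    colData = S4Vectors::DataFrame(
      patient_id = ids, hr = hr, her2 = her2,
      subtype = deriveSubtype(hr, her2), pcr = pcr, row.names = ids))
  methods::new("FtvCohort", se)
}

# EnhancementMaps built directly from arrays (all voxels valid unless told).
toyMaps <- function(pe, ser = array(1, dim(pe)),
                    valid = array(TRUE, dim(pe)),
                    spacing = c(1, 1, 1)) {
  methods::new("EnhancementMaps", pe = pe, ser = ser, valid = valid,
               spacing = spacing)
}

smallPhantom <- function(seed = 1, noiseSd = 0, grid = c(24, 24, 12),
                         radii = c(6, 6, 6), ...) {
  phantomSpec(gridShape = grid, spacingMm = c(1.5, 1.5, 2.5),
              tumorRadiiMm = radii, noiseSd = noiseSd, seed = seed, ...)
}
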