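# Independent reference implementations used as oracles. These are
# deliberately naive (literal formulas, loops, enumeration) and share
# no code with the package internals they check.

# Literal transcription of the biweight midcorrelation formula.
refBicor <- function(x, y) {
  tr <- function(v) {
    d <- v - median(v)
    m <- median(abs(d))
    u <- d / (9 * m)
    a <- (1 - u^2)^2 * (abs(u) < 1)
    w <- d * a
    w / sqrt(sum(w^2))
  }
  sum(tr(x) * tr(y))
}

# Literal triple-loop topological overlap.
refTom <- function(A) {
  n <- nrow(A)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(A[i, -i])
  tom <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(tom) <- dimnames(A)
  tom
}

# All permutations of 1..n by iterative insertion (independent of the
# package's recursive enumerator).
refPermutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(0:(k - 1L), function(pos) append(p, k, after = pos))
    }), recursive = FALSE)
  }
  do.call(rbind, perms)
}

# Exact two-class Wallenius pmf by brute-force enumeration of all draw
# sequences: each length-n binary sequence (TRUE = category gene) gets
# the product of its conditional draw probabilities.
refWalleniusPmf <- function(m1, m2, n, odds) {
  pmf <- numeric(min(n, m1) + 1L)
  for (x in 0:min(n, m1)) {
    if (n - x > m2) next
    sets <- if (x == 0) matrix(integer(0), ncol = 1) else
      combn(n, x)
    tot <- 0
    for (ci in seq_len(ncol(sets))) {
      positions <- sets[, ci]
      prob <- 1
      taken <- 0L
      for (d in 1:n) {
        remT <- m1 - taken
        remO <- m2 - (d - 1L - taken)
        w <- odds * remT + remO
        if (d %in% positions) {
          prob <- prob * odds * remT / w
          taken <- taken + 1L
        } else {
          prob <- prob * remO / w
        }
      }
      tot <- tot + prob
    }
    pmf[x + 1L] <- tot
  }
  pmf
}

# Small three-compartment experiment built in code.
makeToyExperiment <- function(nGenes = 4, nCocs = 3, value = NULL) {
  genes <- paste0("g", seq_len(nGenes))
  cocs <- paste0("coc", seq_len(nCocs))
  comps <- c("oocyte", "innerCC", "outerCC")
  samples <- as.vector(outer(cocs, comps, paste, sep = "_"))
  if (is.null(value)) {
    set.seed(99)
    v <- matrix(round(runif(nGenes * length(samples), 0, 10), 3),
                nGenes, length(samples))
  } else {
    v <- matrix(value, nGenes, length(samples))
  }
  dimnames(v) <- list(genes, samples)
  sheet <- data.frame(sample_id = samples,
                      coc_id = rep(cocs, times = 3),
                      compartment = rep(comps, each = nCocs),
                      stringsAsFactors = FALSE)
  COCExperiment(v, sheet)
}

# LinkedCompartmentPair built directly from two matrices.
makePair <- function(a, b, cocIds = NULL) {
  if (is.null(cocIds)) cocIds <- paste0("coc", seq_len(ncol(a)))
  colnames(a) <- colnames(b) <- cocIds
  if (is.null(rownames(a))) rownames(a) <- paste0("a", seq_len(nrow(a)))
  if (is.null(rownames(b))) rownames(b) <- paste0("b", seq_len(nrow(b)))
  new("LinkedCompartmentPair", a = a, b = b, cocIds = cocIds,
      compartments = c("oocyte", "outerCC"))
}
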