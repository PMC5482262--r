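# Independent oracles used by the test suite. These deliberately share no
# code with the package: brute-force scans and a full-matrix Gotoh dynamic
# program written against the definitions, not against the implementation.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, n_sub = 0, n_indel = 0) {
  s <- strsplit(seq, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(s), n_sub)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  for (k in seq_len(n_indel)) {
    if (runif(1) < 0.5 && length(s) > 2) {
      s <- s[-sample(length(s), 1)]
    } else {
      at <- sample(length(s), 1)
      s <- append(s, sample(c("A", "C", "G", "T"), 1), after = at)
    }
  }
  paste(s, collapse = "")
}

# --- brute-force overlap scorer -------------------------------------------
# All overlap lengths L >= min_overlap between the forward read and the
# reverse-complemented reverse read; returns the qualifying (L, mismatches)
# chosen as: longest, then fewest mismatches, then smallest reverse-mate
# offset (which is a function of L, so redundant here but kept literal).
oracle_overlap <- function(fwd, rev_rc, min_overlap, max_mismatches) {
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rev_rc, "")[[1]]
  m <- length(f); n <- length(r)
  cands <- list()
  for (L in seq_len(min(m, n))) {
    if (L < min_overlap) next
    mm <- sum(f[(m - L + 1):m] != r[1:L] |
                f[(m - L + 1):m] == "N" | r[1:L] == "N")
    if (mm <= max_mismatches) {
      cands[[length(cands) + 1]] <- c(L = L, mm = mm, offset = m - L + 1)
    }
  }
  if (length(cands) == 0) return(NULL)
  tab <- do.call(rbind, cands)
  tab <- tab[order(-tab[, "L"], tab[, "mm"], tab[, "offset"]), , drop = FALSE]
  tab[1, ]
}

# --- brute-force primer matcher -------------------------------------------
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_primer_mismatches <- function(primer, window) {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(!mapply(function(pc, wc) wc != "N" && wc %in% iupac_sets[[pc]], p, w))
}

# --- full-matrix Gotoh global aligner -------------------------------------
# Affine gaps: a gap of length L costs go + L * ge (go, ge >= 0). Row-wise
# fill; the horizontal-gap state uses a running cummax so each row is
# vectorised. Returns score, the two gapped strings, and identity computed
# from them excluding terminal-gap overhangs.
oracle_align <- function(a, b, match = 5, mismatch = -4, go = 10, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[, 1] <- -(go + ge * (0:n)); X[1, 1] <- NEG        # gap in b (vertical)
  Y[1, ] <- -(go + ge * (0:m)); Y[1, 1] <- NEG        # gap in a (horizontal)
  for (i in 2:(n + 1)) {
    s <- ifelse(av[i - 1] == bv & av[i - 1] != "N" & bv != "N",
                match, mismatch)
    prev_best <- pmax(M[i - 1, ], X[i - 1, ], Y[i - 1, ])
    M[i, 2:(m + 1)] <- s + prev_best[1:m]
    X[i, ] <- pmax(M[i - 1, ] - go - ge, X[i - 1, ] - ge,
                   Y[i - 1, ] - go - ge)
    X[i, 1] <- -(go + ge * (i - 1))
    # Y[i, j] = max_{j' < j} (max(M[i,j'], X[i,j']) + ge*j') - go - ge*j
    mx <- pmax(M[i, ], X[i, ]) + ge * (0:m)
    run <- cummax(mx)
    Y[i, 2:(m + 1)] <- run[1:m] - go - ge * (1:m)
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # traceback (scalar; prefers M, then X, then Y on ties)
  i <- n + 1; j <- m + 1
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == "M") {
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      tgt <- M[i, j] - s
      state <- if (i > 1 && j > 1 && M[i - 1, j - 1] == tgt) "M"
               else if (i > 1 && j > 1 && X[i - 1, j - 1] == tgt) "X"
               else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      v <- X[i, j]
      state <- if (i > 1 && M[i - 1, j] - go - ge == v) "M"
               else if (i > 1 && X[i - 1, j] - ge == v) "X"
               else if (i > 1 && Y[i - 1, j] - go - ge == v) "Y"
               else "X"
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      v <- Y[i, j]
      state <- if (j > 1 && M[i, j - 1] - go - ge == v) "M"
               else if (j > 1 && Y[i, j - 1] - ge == v) "Y"
               else if (j > 1 && X[i, j - 1] - go - ge == v) "X"
               else "Y"
      j <- j - 1
    }
  }
  both <- which(pa != "-" & pb != "-")
  span <- both[1]:both[length(both)]
  identity <- sum(pa[span] == pb[span] & pa[span] != "N") / length(span)
  list(score = score, identity = identity,
       alignment = c(paste(pa, collapse = ""), paste(pb, collapse = "")))
}

# --- greedy-clustering replay oracle --------------------------------------
# Replays the greedy definition literally, one variant at a time, using the
# package's pairwise_identity as the identity callback (the partition logic
# under test is replayed independently of the round-based implementation).
oracle_greedy_partition <- function(variants, threshold,
                                    identity_fun = pairwise_identity) {
  v <- variants[order(-variants$count, variants$sequence), ]
  centroids <- character(0)
  assign <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (length(centroids) > 0) {
      ids <- vapply(centroids, function(cs) identity_fun(cs, v$sequence[i]),
                    numeric(1))
      best <- which.max(ids)
      if (ids[best] >= threshold) { assign[i] <- best; next }
    }
    centroids <- c(centroids, v$sequence[i])
    assign[i] <- length(centroids)
  }
  split(v$sequence, assign)
}

# canonical form of a partition for comparison
canon_partition <- function(parts) {
  unname(lapply(parts, sort))[order(vapply(lapply(parts, sort), `[`,
                                           character(1), 1))]
}
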