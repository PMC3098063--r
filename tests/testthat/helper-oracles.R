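# Shared fixtures and independent brute-force oracles.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# cached expensive-ish fixtures
.fix <- new.env()
fix_scheme <- function() {
  if (is.null(.fix$scheme)) .fix$scheme <- scoring_scheme()
  .fix$scheme
}
fix_jtt <- function() {
  if (is.null(.fix$jtt)) .fix$jtt <- build_rate_model("JTT", alpha = 1, K = 4)
  .fix$jtt
}
fix_poisson1 <- function() {
  if (is.null(.fix$p1)) .fix$p1 <- build_rate_model("Poisson", alpha = 1, K = 1)
  .fix$p1
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Quadratic-space affine-gap DP oracles, written independently of the
# package's C++ kernels.  Gap of length k costs open + k * ext.
nw_oracle <- function(a, b, scheme) {
  s <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) D[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) I[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], D[i, j], I[i, j]) + s[ca[i], cb[j]]
    D[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, D[i, j + 1] - ext,
                           I[i, j + 1] - open - ext)
    I[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, I[i + 1, j] - ext,
                           D[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

sw_oracle <- function(a, b, scheme) {
  s <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(0, max(M[i, j], D[i, j], I[i, j], 0) +
                                s[ca[i], cb[j]])
    D[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, D[i, j + 1] - ext,
                           I[i, j + 1] - open - ext)
    I[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, I[i + 1, j] - ext,
                           D[i + 1, j] - open - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# Independent likelihood for the grid-search oracle: rebuilds the
# column-pattern likelihood from the alignment strings and the exported
# transition_matrix(), without touching the estimator's internals.
ll_oracle <- function(aln, model, t) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  use <- a != "-" & b != "-" & a != "X" & b != "X"
  a <- a[use]; b <- b[use]
  P <- Reduce(`+`, lapply(model$category_rates,
                          function(r) transition_matrix(model, t, r)))
  P <- P / model$K
  sum(log(model$pi[a] * P[cbind(a, b)]))
}

# Build the (known, ungapped) alignment of two equal-length sequences.
ungapped_alignment <- function(a, b, id_a = "a", id_b = "b") {
  stopifnot(nchar(a) == nchar(b))
  structure(list(id_a = id_a, id_b = id_b, aligned_a = a, aligned_b = b,
                 score = NA_integer_, length = nchar(a),
                 matched_columns = nchar(a)),
            class = "pairwise_alignment")
}

# Exhaustive enumeration of all global alignments of two short strings
# under affine gap scoring; returns the optimum score and the minimum
# number of gap columns among optimal alignments.
enumerate_global <- function(a, b, scheme) {
  s <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, gaps = Inf)
  rec <- function(i, j, score, state, gaps) {
    if (i > length(ca) && j > length(cb)) {
      if (score > best$score ||
          (score == best$score && gaps < best$gaps)) {
        best <<- list(score = score, gaps = gaps)
      }
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + s[ca[i], cb[j]], "M", gaps)
    }
    if (i <= length(ca)) {
      pen <- if (state == "D") ext else open + ext
      rec(i + 1, j, score - pen, "D", gaps + 1)
    }
    if (j <= length(cb)) {
      pen <- if (state == "I") ext else open + ext
      rec(i, j + 1, score - pen, "I", gaps + 1)
    }
  }
  rec(1, 1, 0, "M", 0)
  best
}

count_gap_columns <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  sum(a == "-" | b == "-")
}
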