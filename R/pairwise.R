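#' Build a protein scoring scheme
#'
#' Bundles a symmetric substitution matrix with affine gap penalties and
#' the ungapped Karlin-Altschul parameters used to convert raw local
#' alignment scores into E-values, E = K * m * n * exp(-lambda * S).
#' `lambda` is solved numerically from the matrix and the background
#' residue frequencies; `K` is a user-settable prefactor (its classical
#' ungapped value for BLOSUM62 is about 0.13).  The ambiguity code `X`
#' scores 0 against every residue.
#'
#' @param matrix Either the name `"BLOSUM62"` (the bundled NCBI matrix) or
#'   a symmetric 20x20 integer matrix with rows/columns in the canonical
#'   residue order `A R N D C Q E G H I L K M F P S T W Y V`.
#' @param gap_open,gap_extend Non-negative affine gap penalties; a gap of
#'   length k costs `gap_open + k * gap_extend` (protein BLAST convention).
#' @param K_u Karlin-Altschul prefactor.
#' @param bg Background residue frequencies (length 20, sum 1).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, K_u = 0.13,
                           bg = rep(1 / 20, 20)) {
  if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62")) {
      stop("unknown matrix name '", matrix, "'; available: BLOSUM62")
    }
    m <- blosum62_matrix()
  } else {
    m <- as.matrix(matrix)
    if (!all(dim(m) == c(20L, 20L))) stop("substitution matrix must be 20x20")
    dimnames(m) <- list(AA_ORDER, AA_ORDER)
  }
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  stopifnot(gap_open >= 0, gap_extend >= 0, K_u > 0,
            length(bg) == 20L, abs(sum(bg) - 1) < 1e-8)
  exp_score <- sum(outer(bg, bg) * m)
  if (exp_score >= 0) {
    stop("expected substitution score under background frequencies is ",
         "non-negative (", signif(exp_score, 3),
         "); E-value theory requires it to be negative")
  }
  if (max(m) <= 0) stop("substitution matrix has no positive score")
  f <- function(lam) sum(outer(bg, bg) * exp(lam * m)) - 1
  lambda <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  stopifnot(abs(f(lambda)) < 1e-6)
  ext <- rbind(cbind(m, X = 0L), X = 0L)  # X scores 0 against everything
  storage.mode(ext) <- "integer"
  structure(list(matrix = m, matrix_ext = ext,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda_u = lambda, K_u = K_u, bg = bg),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to the 20 canonical residues, from the copy bundled
# with Biostrings (the same matrix protein BLAST uses by default).
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  storage.mode(m) <- "integer"
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> gap %d/%d, lambda_u %.4f, K_u %.3f\n",
              x$gap_open, x$gap_extend, x$lambda_u, x$K_u))
  invisible(x)
}

# Accept a query as a named length-1 character vector or a list(id, seq).
as_query <- function(x) {
  if (is.list(x) && !is.null(x$id)) return(list(id = x$id, seq = toupper(x$seq)))
  if (is.character(x) && length(x) == 1L && !is.null(names(x))) {
    return(list(id = names(x), seq = toupper(unname(x))))
  }
  stop("query must be a named length-1 character vector or list(id=, seq=)")
}

#' Search one query against a genome database
#'
#' Computes the optimal Smith-Waterman local alignment score of the query
#' against every database record, converts scores to Karlin-Altschul
#' E-values with m = query length and n = the database's total residue
#' count, and retains hits with `E < evalue_threshold`.  Hits are sorted by
#' ascending E-value, then descending raw score, then subject id, and
#' truncated to `max_hits`.
#'
#' @param query Named length-1 character vector (id = sequence) or
#'   `list(id =, seq =)`.
#' @param db A `genome_db`.
#' @param scheme A `scoring_scheme`.
#' @param evalue_threshold Positive E-value cutoff (classical RSD example:
#'   1e-10).
#' @param max_hits Maximum number of hits to return (`Inf` for all); RSD
#'   only needs the near-smallest-distance candidates.
#' @param score_threshold Optional raw-score cutoff; when given, hits are
#'   retained by `raw_score >= score_threshold` instead of by E-value (for
#'   exactness-sensitive uses, since the E-values carry the ungapped
#'   Karlin-Altschul approximation).
#' @return An object of class `hit_set`: list with `query_id`,
#'   `subject_genome` and a data frame `hits` (subject_id, raw_score,
#'   evalue).
#' @export
local_search <- function(query, db, scheme, evalue_threshold = 1e-10,
                         max_hits = 20L, score_threshold = NULL) {
  q <- as_query(query)
  stopifnot(inherits(db, "genome_db"), inherits(scheme, "scoring_scheme"),
            evalue_threshold > 0)
  if (!nzchar(q$seq)) stop("query sequence has length 0")
  qi <- encode_seq(q$seq) - 1L
  scores <- sw_score_many(qi, lapply(db$enc, function(e) e - 1L),
                          scheme$matrix_ext, scheme$gap_open,
                          scheme$gap_extend)
  m <- nchar(q$seq)
  ev <- scheme$K_u * m * db$total_residues * exp(-scheme$lambda_u * scores)
  keep <- if (is.null(score_threshold)) which(ev < evalue_threshold)
          else which(scores >= score_threshold)
  hits <- data.frame(subject_id = db$ids[keep],
                     raw_score = scores[keep],
                     evalue = ev[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$subject_id), ,
               drop = FALSE]
  if (is.finite(max_hits) && nrow(hits) > max_hits) {
    hits <- hits[seq_len(max_hits), , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(list(query_id = q$id, subject_genome = db$name, hits = hits),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> %s vs %s: %d hits\n", x$query_id,
              x$subject_genome, nrow(x$hits)))
  invisible(x)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps; terminal gaps are penalized.  Ties in
#' the traceback deterministically prefer a substitution column over a gap
#' in `a` over a gap in `b`.
#'
#' @param a,b Named length-1 character vectors (id = sequence) or
#'   `list(id =, seq =)`.
#' @param scheme A `scoring_scheme`.
#' @return An object of class `pairwise_alignment`: `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `score`, `length`, `matched_columns`.
#' @export
global_align <- function(a, b, scheme) {
  ra <- as_query(a); rb <- as_query(b)
  if (!nzchar(ra$seq) || !nzchar(rb$seq)) stop("sequences must be non-empty")
  ea <- encode_seq(ra$seq); eb <- encode_seq(rb$seq)
  res <- nw_align_int(ea - 1L, eb - 1L, scheme$matrix_ext,
                      scheme$gap_open, scheme$gap_extend)
  path <- res$path
  ca <- strsplit(ra$seq, "", fixed = TRUE)[[1]]
  cb <- strsplit(rb$seq, "", fixed = TRUE)[[1]]
  out_a <- character(length(path)); out_b <- character(length(path))
  i <- 0L; j <- 0L
  for (k in seq_along(path)) {
    mv <- path[k]
    if (mv == 0L) { i <- i + 1L; j <- j + 1L; out_a[k] <- ca[i]; out_b[k] <- cb[j] }
    else if (mv == 1L) { j <- j + 1L; out_a[k] <- "-"; out_b[k] <- cb[j] }
    else { i <- i + 1L; out_a[k] <- ca[i]; out_b[k] <- "-" }
  }
  structure(list(id_a = ra$id, id_b = rb$id,
                 aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = res$score,
                 length = length(path),
                 matched_columns = sum(path == 0L)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s / %s: %d columns, %d matched, score %d\n",
              x$id_a, x$id_b, x$length, x$matched_columns, x$score))
  invisible(x)
}

#' Alignable fraction of a global alignment
#'
#' The fraction of alignment columns in which both sequences have a residue
#' (no gap).  RSD's divergence filter requires this fraction to reach a
#' threshold (classical example: 0.8) before a distance is estimated.
#'
#' @param aln A `pairwise_alignment`.
#' @return A number in \[0, 1\].
#' @export
alignable_fraction <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"), aln$length > 0)
  aln$matched_columns / aln$length
}
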