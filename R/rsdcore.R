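#' Parameter setting for an RSD run
#'
#' @param divergence Minimum alignable fraction in (0, 1] (classical
#'   example: 0.8).
#' @param evalue Positive E-value threshold (classical example: 1e-10).
#' @return A list of class `param_setting`.
#' @export
param_setting <- function(divergence, evalue) {
  stopifnot(is.numeric(divergence), length(divergence) == 1L,
            divergence > 0, divergence <= 1,
            is.numeric(evalue), length(evalue) == 1L, evalue > 0)
  structure(list(divergence = divergence, evalue = evalue),
            class = "param_setting")
}

#' Cartesian grid of RSD parameter settings
#'
#' Running RSD over a grid of settings, from conservative to relaxed, is
#' how ortholog databases built on it cover distantly related organisms;
#' the classical production grid has 12 combinations.
#'
#' @param divergences,evalues Non-empty numeric vectors of valid values.
#' @return List of `param_setting`, divergence-major order.
#' @export
param_grid <- function(divergences = c(0.2, 0.5, 0.8),
                       evalues = c(1e-20, 1e-15, 1e-10, 1e-5)) {
  stopifnot(length(divergences) > 0, length(evalues) > 0)
  out <- list()
  for (d in divergences) for (e in evalues) {
    out[[length(out) + 1L]] <- param_setting(d, e)
  }
  out
}

setting_label <- function(setting) {
  sprintf("d%s_e%s", formatC(setting$divergence, format = "g"),
          formatC(setting$evalue, format = "g"))
}

# Shared per-run memo of global alignments/distances, keyed on the
# unordered (genome:id, genome:id) pair; distance and alignable fraction
# are both symmetric in the two sequences.
pair_stats <- function(memo, key_a, seq_a, key_b, seq_b, scheme, model) {
  key <- paste(sort(c(key_a, key_b)), collapse = "||")
  if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
  aln <- global_align(seq_a, seq_b, scheme)
  st <- list(frac = alignable_fraction(aln),
             dist = NULL, aln = aln)
  if (!is.null(memo)) memo[[key]] <- st
  st
}

pair_distance <- function(memo, key_a, seq_a, key_b, seq_b, scheme, model) {
  key <- paste(sort(c(key_a, key_b)), collapse = "||")
  st <- pair_stats(memo, key_a, seq_a, key_b, seq_b, scheme, model)
  if (is.null(st$dist)) {
    st$dist <- ml_distance(st$aln, model)$t_hat
    if (!is.null(memo)) memo[[key]] <- st
  }
  st$dist
}

filter_hits_by_setting <- function(hits, setting, max_hits) {
  hits <- hits[hits$evalue < setting$evalue, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$subject_id), ,
               drop = FALSE]
  if (is.finite(max_hits) && nrow(hits) > max_hits) {
    hits <- hits[seq_len(max_hits), , drop = FALSE]
  }
  hits
}

#' Forward pass of RSD: best hit by smallest distance
#'
#' Searches query `i` against genome `J` (or reuses a supplied hit set),
#' keeps the hits whose global alignment with `i` covers at least
#' `setting$divergence` of its columns, estimates an ML distance for each
#' survivor, and returns the survivor with the smallest distance (ties go
#' to the lexicographically smallest subject id).
#'
#' @param query Named length-1 character vector (id = sequence) or
#'   `list(id =, seq =)`.
#' @param J Subject `genome_db`.
#' @param setting A `param_setting`.
#' @param scheme A `scoring_scheme`.
#' @param model A `rate_model`.
#' @param hits Optional precomputed `hit_set` (or its `hits` data frame)
#'   for this query against `J`; filtered to the setting's E-value here.
#' @param max_hits Truncation applied after E-value filtering.
#' @param memo Optional environment used to cache alignments and distances
#'   across calls within one run.
#' @return `NULL` when no hit survives, else a list with `j_id`,
#'   `distance`, and `cache` (named numeric id -> distance for every
#'   survivor).
#' @export
forward_best_hit <- function(query, J, setting, scheme, model, hits = NULL,
                             max_hits = 20L, memo = NULL) {
  q <- as_query(query)
  if (is.null(hits)) {
    hits <- local_search(q, J, scheme, setting$evalue, max_hits = max_hits)$hits
  } else {
    if (inherits(hits, "hit_set")) hits <- hits$hits
    hits <- filter_hits_by_setting(hits, setting, max_hits)
  }
  if (nrow(hits) == 0L) return(NULL)
  cache <- numeric(0)
  for (sid in hits$subject_id) {
    st <- pair_stats(memo, paste0("Q:", q$id), q, paste0(J$name, ":", sid),
                     list(id = sid, seq = J$seqs[[sid]]), scheme, model)
    if (st$frac >= setting$divergence) {
      cache[sid] <- pair_distance(memo, paste0("Q:", q$id), q,
                                  paste0(J$name, ":", sid),
                                  list(id = sid, seq = J$seqs[[sid]]),
                                  scheme, model)
    }
  }
  if (length(cache) == 0L) return(NULL)
  best <- names(cache)[order(cache, names(cache))][1L]
  list(j_id = best, distance = unname(cache[best]), cache = cache)
}

#' Reciprocal pass of RSD: confirm an ortholog pair
#'
#' Searches `j` back against genome `I`, applies the same divergence
#' filter, reuses the forward-cached `i`-`j` distance for `i`, estimates
#' fresh distances for every other survivor, and confirms the pair iff `i`
#' survives the filter and attains the minimum distance (a tie involving
#' `i` counts as confirmation, so identical duplicates cannot destroy the
#' self-evident pair).
#'
#' @param i_query,j_query The original query and its forward winner, as
#'   named length-1 character vectors or `list(id =, seq =)`.
#' @param I Query-side `genome_db` (searched in this reciprocal pass).
#' @param setting,scheme,model As in [forward_best_hit()].
#' @param forward_cache Named numeric from the forward pass; must contain
#'   the `i`-`j` distance under `i`'s id.
#' @param hits Optional precomputed hit set for `j` against `I`.
#' @param max_hits,memo As in [forward_best_hit()].
#' @return `NULL` if the reciprocal test fails, else a list of class
#'   `ortholog_pair` with `query_id`, `subject_id`, `distance`, `setting`.
#' @export
reciprocal_confirm <- function(i_query, j_query, I, setting, scheme, model,
                               forward_cache, hits = NULL, max_hits = 20L,
                               memo = NULL) {
  qi <- as_query(i_query); qj <- as_query(j_query)
  if (!qi$id %in% names(forward_cache)) {
    stop("internal consistency error: forward cache is missing the ",
         qi$id, " - ", qj$id, " distance")
  }
  if (is.null(hits)) {
    hits <- local_search(qj, I, scheme, setting$evalue, max_hits = max_hits)$hits
  } else {
    if (inherits(hits, "hit_set")) hits <- hits$hits
    hits <- filter_hits_by_setting(hits, setting, max_hits)
  }
  if (!qi$id %in% hits$subject_id) return(NULL)
  d <- numeric(0)
  for (sid in hits$subject_id) {
    st <- pair_stats(memo, paste0("R:", qj$id), qj, paste0(I$name, ":", sid),
                     list(id = sid, seq = I$seqs[[sid]]), scheme, model)
    if (st$frac < setting$divergence) next
    if (sid == qi$id) {
      d[sid] <- forward_cache[[qi$id]]
    } else {
      d[sid] <- pair_distance(memo, paste0("R:", qj$id), qj,
                              paste0(I$name, ":", sid),
                              list(id = sid, seq = I$seqs[[sid]]),
                              scheme, model)
    }
  }
  if (!qi$id %in% names(d)) return(NULL)
  if (d[qi$id] > min(d)) return(NULL)
  structure(list(query_id = qi$id, subject_id = qj$id,
                 distance = unname(forward_cache[[qi$id]]),
                 setting = setting),
            class = "ortholog_pair")
}

#' Reciprocal smallest distance orthologs between two genomes
#'
#' Runs the forward pass for every sequence in `I` and the reciprocal pass
#' for each forward winner.  When a `store` is supplied, hit sets are read
#' from its precomputed `blast_result/` tables instead of searching
#' on the fly (the two routes give identical results as long as the stored
#' tables were computed at an E-value threshold at least as relaxed as the
#' setting's, untruncated).
#'
#' @param I,J Distinct `genome_db` objects.
#' @param setting,scheme,model As in [forward_best_hit()].
#' @param store Optional `result_store` holding `blast_result/` tables
#'   named `<query_genome>__<subject_genome>.tsv`.
#' @param max_hits Hit-list truncation (after E-value filtering).
#' @return Data frame of class `ortholog_table` with columns `query_id`,
#'   `subject_id`, `distance`, sorted by `query_id`; attributes `genome_a`,
#'   `genome_b`, `setting`.
#' @export
rsd_orthologs <- function(I, J, setting, scheme, model, store = NULL,
                          max_hits = 20L) {
  stopifnot(inherits(I, "genome_db"), inherits(J, "genome_db"))
  fwd_tab <- rev_tab <- NULL
  if (!is.null(store)) {
    fwd_tab <- read_hit_table(store, I$name, J$name)
    rev_tab <- read_hit_table(store, J$name, I$name)
  }
  memo <- new.env(parent = emptyenv())
  rec_hits_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (qid in I$ids) {
    q <- list(id = qid, seq = I$seqs[[qid]])
    fhits <- if (is.null(fwd_tab)) NULL else
      fwd_tab[fwd_tab$query_id == qid, , drop = FALSE]
    fw <- forward_best_hit(q, J, setting, scheme, model, hits = fhits,
                           max_hits = max_hits, memo = memo)
    if (is.null(fw)) next
    jq <- list(id = fw$j_id, seq = J$seqs[[fw$j_id]])
    rhits <- if (!is.null(rev_tab)) {
      rev_tab[rev_tab$query_id == fw$j_id, , drop = FALSE]
    } else if (!is.null(rec_hits_cache[[fw$j_id]])) {
      rec_hits_cache[[fw$j_id]]
    } else {
      h <- local_search(jq, I, scheme, setting$evalue, max_hits = max_hits)$hits
      rec_hits_cache[[fw$j_id]] <- h
      h
    }
    pair <- reciprocal_confirm(q, jq, I, setting, scheme, model,
                               forward_cache = setNames(fw$cache[fw$j_id], qid),
                               hits = rhits, max_hits = max_hits, memo = memo)
    if (!is.null(pair)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = pair$query_id, subject_id = pair$subject_id,
        distance = pair$distance, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), subject_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_a") <- I$name
  attr(out, "genome_b") <- J$name
  attr(out, "setting") <- setting
  class(out) <- c("ortholog_table", class(out))
  out
}

#' Serialize an ortholog table to tab-delimited text
#'
#' Three columns (`query_id`, `subject_id`, `distance`); distances printed
#' with full precision so re-reading reproduces the values exactly.
#'
#' @param tab An `ortholog_table` (or compatible data frame).
#' @return Character vector of lines (header + one line per pair).
#' @export
format_ortholog_table <- function(tab) {
  c("query_id\tsubject_id\tdistance",
    sprintf("%s\t%s\t%.17g", tab$query_id, tab$subject_id, tab$distance))
}

#' Parse lines written by [format_ortholog_table()]
#' @param lines Character vector of lines.
#' @return Data frame with `query_id`, `subject_id`, `distance`.
#' @export
parse_ortholog_table <- function(lines) {
  if (length(lines) <= 1L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  data.frame(query_id = vapply(parts, `[`, character(1), 1L),
             subject_id = vapply(parts, `[`, character(1), 2L),
             distance = as.numeric(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

# Store key for an ortholog table, e.g. "A.aa__B.aa__d0.8_e1e-10.orth".
ortholog_key <- function(name_a, name_b, setting) {
  sprintf("%s__%s__%s.orth", name_a, name_b, setting_label(setting))
}
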