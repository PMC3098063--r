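#' Open (or create) a result store
#'
#' A result store is a plain directory tree with three fixed buckets:
#' `log/` for executor event logs, `blast_result/` for precomputed hit
#' tables, and `ortholog_results/` for final ortholog tables.  It is the
#' persistent glue between the two phases of the workflow: phase 2 reads
#' only the store, so it can run in a later process, or be re-run, without
#' repeating the search phase.
#'
#' @param root Directory path (created if needed).
#' @return An object of class `result_store`.
#' @export
result_store <- function(root) {
  buckets <- c("log", "blast_result", "ortholog_results")
  for (b in buckets) {
    dir.create(file.path(root, b), recursive = TRUE, showWarnings = FALSE)
  }
  structure(list(root = normalizePath(root), buckets = buckets),
            class = "result_store")
}

check_bucket <- function(store, bucket) {
  stopifnot(inherits(store, "result_store"))
  if (!bucket %in% store$buckets) {
    stop("unknown bucket '", bucket, "'; buckets: ",
         paste(store$buckets, collapse = ", "))
  }
}

#' Store a text object under a bucket/key
#' @param store A `result_store`.
#' @param bucket One of `"log"`, `"blast_result"`, `"ortholog_results"`.
#' @param key File name within the bucket.
#' @param lines Character vector of lines to write.
#' @return The key, invisibly.
#' @export
store_put <- function(store, bucket, key, lines) {
  check_bucket(store, bucket)
  writeLines(lines, file.path(store$root, bucket, key))
  invisible(key)
}

#' Retrieve a text object from a bucket/key
#' @inheritParams store_put
#' @return Character vector of lines.
#' @export
store_get <- function(store, bucket, key) {
  check_bucket(store, bucket)
  path <- file.path(store$root, bucket, key)
  if (!file.exists(path)) {
    stop("missing store entry: ", bucket, "/", key)
  }
  readLines(path, warn = FALSE)
}

#' Test whether a store entry exists
#' @inheritParams store_put
#' @export
store_exists <- function(store, bucket, key) {
  check_bucket(store, bucket)
  file.exists(file.path(store$root, bucket, key))
}

#' List keys in a bucket, optionally by prefix
#' @inheritParams store_put
#' @param prefix Optional key prefix filter.
#' @return Sorted character vector of keys.
#' @export
store_list <- function(store, bucket, prefix = "") {
  check_bucket(store, bucket)
  keys <- sort(list.files(file.path(store$root, bucket)))
  if (nzchar(prefix)) keys <- keys[startsWith(keys, prefix)]
  keys
}

#' Append a line to the executor event log
#' @param store A `result_store`.
#' @param worker Worker id (integer).
#' @param task Task index (integer).
#' @param event Event name (e.g. `"start"`, `"ok"`, `"retry"`).
#' @export
store_log <- function(store, worker, task, event) {
  line <- sprintf("%.3f\t%d\t%d\t%s", as.numeric(Sys.time()), worker, task,
                  event)
  cat(line, "\n", sep = "",
      file = file.path(store$root, "log", "events.log"), append = TRUE)
  invisible(line)
}

# ---- hit-table serialization (blast_result bucket) ----

hit_table_key <- function(query_genome, subject_genome) {
  sprintf("%s__%s.tsv", query_genome, subject_genome)
}

#' Serialize hit sets for one (query genome, subject genome) direction
#'
#' @param hit_sets List of `hit_set` objects (one per query).
#' @return Character vector of tab-delimited lines with header
#'   `query_id  subject_id  raw_score  evalue`.
#' @export
format_hit_table <- function(hit_sets) {
  lines <- "query_id\tsubject_id\traw_score\tevalue"
  for (hs in hit_sets) {
    h <- hs$hits
    if (nrow(h) == 0L) next
    lines <- c(lines, sprintf("%s\t%s\t%d\t%.17g", hs$query_id,
                              h$subject_id, h$raw_score, h$evalue))
  }
  lines
}

#' Parse lines written by [format_hit_table()]
#' @param lines Character vector of lines.
#' @return Data frame with `query_id`, `subject_id`, `raw_score`, `evalue`.
#' @export
parse_hit_table <- function(lines) {
  if (length(lines) <= 1L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = integer(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  data.frame(query_id = vapply(parts, `[`, character(1), 1L),
             subject_id = vapply(parts, `[`, character(1), 2L),
             raw_score = as.integer(vapply(parts, `[`, character(1), 3L)),
             evalue = as.numeric(vapply(parts, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

read_hit_table <- function(store, query_genome, subject_genome) {
  key <- hit_table_key(query_genome, subject_genome)
  if (!store_exists(store, "blast_result", key)) {
    stop("store is missing the precomputed hit table for (",
         query_genome, ", ", subject_genome, "): blast_result/", key)
  }
  parse_hit_table(store_get(store, "blast_result", key))
}
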