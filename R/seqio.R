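#' Read a protein FASTA file
#'
#' Parses a multi-line amino-acid FASTA file into a named character vector
#' of sequences.  The id of each record is the first whitespace-delimited
#' token of its header line; the rest of the description is discarded.
#' Sequences are uppercased; `*` (stop) characters are stripped with a
#' warning; the rare non-canonical codes `B`, `Z`, `J`, `U`, `O` are mapped
#' to the ambiguity code `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences (possibly empty
#'   for an empty file), names are the raw (unsanitized) ids in file order.
#' @seealso [write_fasta()], [format_genome()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(setNames(character(0), character(0)))
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence data before any header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA records with empty sequence: ", paste(ids[empty], collapse = ", "))
  }
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' (stop) characters from input sequences")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
    if (any(!nzchar(seqs))) {
      stop("FASTA records with empty sequence: ",
           paste(ids[!nzchar(seqs)], collapse = ", "))
    }
  }
  if (any(grepl("[BZJUO]", seqs))) {
    warning("mapping non-canonical residue codes (B, Z, J, U, O) to 'X'")
    seqs <- chartr("BZJUO", "XXXXX", seqs)
  }
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), seqs)
  if (any(bad)) {
    stop("sequences with characters outside the amino-acid alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output file path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Sanitize a sequence or genome identifier
#'
#' Replaces every character outside `[A-Za-z0-9_.-]` with `_` and collapses
#' runs of `_` to a single one, so that ids are safe to embed in runner-file
#' command lines and file names.
#'
#' @param raw Non-empty character vector of raw identifiers.
#' @return Character vector of sanitized identifiers.
#' @examples
#' sanitize_name("gi|123|ref x")  # "gi_123_ref_x"
#' @export
sanitize_name <- function(raw) {
  if (length(raw) == 0L || any(!nzchar(raw))) stop("identifier is empty")
  out <- gsub("[^A-Za-z0-9_.-]", "_", raw)
  out <- gsub("_+", "_", out)
  dead <- grepl("^_*$", out)
  if (any(dead)) {
    stop("identifier(s) unrecoverable after sanitization: ",
         paste(raw[dead], collapse = ", "))
  }
  out
}

#' Build an indexed genome database
#'
#' Sanitizes record ids, checks their uniqueness, and precomputes the
#' integer encoding used by the alignment kernels.  The returned object is
#' treated as immutable by the rest of the package.
#'
#' @param seqs Named character vector of amino-acid sequences (as returned
#'   by [read_fasta()]).
#' @param name Genome name, e.g. `"Homo_sapiens.aa"` (sanitized likewise).
#' @return An object of class `genome_db` with fields `name`, `ids`,
#'   `seqs`, `enc` (integer encodings), and `total_residues`.
#' @export
format_genome <- function(seqs, name) {
  if (length(seqs) == 0L) stop("genome '", name, "' has no records")
  ids <- sanitize_name(names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate ids after sanitization in genome '", name, "': ",
         paste(dup, collapse = ", "))
  }
  seqs <- setNames(toupper(unname(seqs)), ids)
  enc <- lapply(seqs, encode_seq)
  db <- list(
    name = sanitize_name(name),
    ids = ids,
    seqs = seqs,
    enc = enc,
    total_residues = sum(nchar(seqs))
  )
  class(db) <- "genome_db"
  db
}

#' @export
print.genome_db <- function(x, ...) {
  cat(sprintf("<genome_db> %s: %d sequences, %d residues\n",
              x$name, length(x$ids), x$total_residues))
  invisible(x)
}

#' @export
length.genome_db <- function(x) length(x$ids)

#' Write a genome database to its on-disk folder layout
#'
#' Creates `<parent>/<name>/` (the genome name conventionally carries an
#' `.aa` suffix) holding the cleaned FASTA as `<name>.fasta`.
#'
#' @param db A `genome_db`.
#' @param parent Parent directory (created if needed).
#' @return Path of the genome folder, invisibly.
#' @export
write_genome_db <- function(db, parent) {
  stopifnot(inherits(db, "genome_db"))
  dir <- file.path(parent, db$name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(db$seqs, file.path(dir, paste0(db$name, ".fasta")))
  invisible(dir)
}

#' Read a genome database from its on-disk folder layout
#'
#' @param parent Parent directory holding the genome folder.
#' @param name Genome folder name.
#' @return A `genome_db`.
#' @export
read_genome_db <- function(parent, name) {
  dir <- file.path(parent, name)
  fa <- file.path(dir, paste0(name, ".fasta"))
  if (!file.exists(fa)) stop("no genome database at ", fa)
  format_genome(read_fasta(fa), name)
}
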