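# Streaming FASTA/FASTQ readers.  All parsing works on connections (including
# pipes and stdin via the "-" convention) and never seeks.

#' Resolve a file argument to an open text connection
#'
#' `"-"` means stdin.  An already-open connection is returned as-is (and not
#' closed by the caller-facing readers).
#' @keywords internal
open_input <- function(file) {
  if (inherits(file, "connection")) {
    return(list(con = file, close = FALSE))
  }
  stopifnot(is.character(file), length(file) == 1L)
  if (identical(file, "-")) {
    return(list(con = file("stdin"), close = TRUE))
  }
  list(con = file(file, open = "rt"), close = TRUE)
}

open_output <- function(file) {
  if (inherits(file, "connection")) {
    return(list(con = file, close = FALSE))
  }
  stopifnot(is.character(file), length(file) == 1L)
  if (identical(file, "-")) {
    return(list(con = stdout(), close = FALSE))
  }
  list(con = file(file, open = "wt"), close = TRUE)
}

clean_bases <- function(s) {
  s <- toupper(s)
  gsub("[^ACGTN]", "N", s)
}

#' Read reference sequences from FASTA
#'
#' Sequences are uppercased and any character outside `A C G T N` (IUPAC
#' ambiguity codes included) is collapsed to `N`, matching the search alphabet
#' used downstream.  Record names are truncated at the first whitespace so
#' they are safe as SAM `RNAME`s.
#'
#' @param file path, `"-"` for stdin, or an open connection.
#' @return a list of reference sequences, each a list with elements
#'   `name` and `seq`, in file order.
#' @export
#' @examples
#' tf <- tempfile(); writeLines(c(">chr1 desc", "acgtR"), tf)
#' read_fasta(tf)
read_fasta <- function(file) {
  src <- open_input(file)
  on.exit(if (src$close) close(src$con))
  lines <- readLines(src$con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("FASTA format error: empty input", call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) {
    stop("FASTA format error: input does not start with a '>' header",
         call. = FALSE)
  }
  grp <- cumsum(hdr)
  refs <- vector("list", sum(hdr))
  hidx <- which(hdr)
  for (k in seq_along(hidx)) {
    name <- sub("^>\\s*", "", lines[hidx[k]])
    name <- strsplit(name, "\\s+")[[1]][1]
    if (is.na(name) || !nzchar(name)) {
      stop("FASTA format error: record ", k, " has an empty name",
           call. = FALSE)
    }
    body <- lines[grp == k & !hdr]
    if (length(body) == 0L) {
      stop("FASTA format error: header '", name, "' has no sequence",
           call. = FALSE)
    }
    refs[[k]] <- list(name = name, seq = clean_bases(paste(body, collapse = "")))
  }
  refs
}

#' Write FASTA
#' @param refs list of `list(name=, seq=)` records.
#' @param file path, `"-"` for stdout, or connection.
#' @param width line-wrap width.
#' @export
write_fasta <- function(refs, file, width = 70L) {
  dst <- open_output(file)
  on.exit(if (dst$close) close(dst$con))
  for (r in refs) {
    writeLines(paste0(">", r$name), dst$con)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$seq, starts, pmin(starts + width - 1L, n)), dst$con)
  }
  invisible(NULL)
}

parse_fastq_block <- function(lines, offset = 0L) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    # identify the truncated record for the error message
    bad <- offset + (n %/% 4L) + 1L
    stop("FASTQ format error: truncated record #", bad, call. = FALSE)
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  if (any(!startsWith(ids, "@")) || any(!startsWith(plus, "+"))) {
    bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))[1]
    stop("FASTQ format error: malformed record #", offset + bad, " ('",
         ids[bad], "')", call. = FALSE)
  }
  ids <- vapply(strsplit(sub("^@", "", ids), "\\s+"),
                `[`, character(1), 1L)
  seqs <- clean_bases(seqs)
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    bad <- which(mism)[1]
    stop("FASTQ format error: sequence/quality length mismatch for read '",
         ids[bad], "'", call. = FALSE)
  }
  mapply(function(i, s, q) list(id = i, bases = s, quals = q),
         ids, seqs, quals, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Create a lazy FASTQ reader over a connection
#'
#' Returns a closure-based reader suitable for pipes: `$next_record()` yields
#' one record (a list with `id`, `bases`, `quals`) or `NULL` at end of input;
#' `$close()` releases the connection.
#'
#' @param file path, `"-"` for stdin, or an open connection.
#' @param chunk number of records buffered per read.
#' @export
fastq_reader <- function(file, chunk = 1024L) {
  src <- open_input(file)
  if (!isOpen(src$con)) open(src$con, "rt")
  buf <- list()
  pos <- 0L
  seen <- 0L
  fill <- function() {
    lines <- readLines(src$con, n = 4L * chunk, warn = FALSE)
    if (length(lines) == 0L) return(FALSE)
    buf <<- parse_fastq_block(lines, offset = seen)
    seen <<- seen + length(buf)
    pos <<- 0L
    TRUE
  }
  list(
    next_record = function() {
      if (pos >= length(buf) && !fill()) return(NULL)
      pos <<- pos + 1L
      buf[[pos]]
    },
    close = function() if (src$close) close(src$con)
  )
}

#' Read a whole FASTQ file
#'
#' Eager counterpart of [fastq_reader()]; parsing rules are identical
#' (4-line records, Sanger qualities, lengths enforced per record).
#'
#' @inheritParams fastq_reader
#' @return list of records `list(id=, bases=, quals=)` in input order.
#' @export
read_fastq <- function(file) {
  src <- open_input(file)
  on.exit(if (src$close) close(src$con))
  lines <- readLines(src$con, warn = FALSE)
  if (length(lines) == 0L) {
    stop("FASTQ format error: empty input", call. = FALSE)
  }
  parse_fastq_block(lines)
}

#' Write FASTQ
#' @param records list of `list(id=, bases=, quals=)`.
#' @param file path, `"-"` for stdout, or connection.
#' @export
write_fastq <- function(records, file) {
  dst <- open_output(file)
  on.exit(if (dst$close) close(dst$con))
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$bases, "+", r$quals)
  }), use.names = FALSE)
  writeLines(lines, dst$con)
  invisible(NULL)
}
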