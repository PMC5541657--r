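# Plain-text SAM v1 writing and a minimal reader used by the accuracy
# scorer.  Coordinates become 1-based here and nowhere else.

#' SAM flag bits
#' @export
SAM_FLAGS <- c(PAIRED = 1L, PROPER_PAIR = 2L, UNMAPPED = 4L,
               MATE_UNMAPPED = 8L, REVERSE = 16L, MATE_REVERSE = 32L,
               FIRST_IN_PAIR = 64L, SECOND_IN_PAIR = 128L)

#' Construct a SAM record
#'
#' @param qname,flag,rname,pos,mapq,cigar,rnext,pnext,tlen,seq,qual the
#'   eleven mandatory SAM fields (`pos` 1-based; 0 for unmapped).
#' @param tags character vector of preformatted `TAG:TYPE:VALUE` strings.
#' @return a list of class `SamRecord`.
#' @export
sam_record <- function(qname, flag, rname = "*", pos = 0L, mapq = 0L,
                       cigar = "*", rnext = "*", pnext = 0L, tlen = 0L,
                       seq = "*", qual = "*", tags = character(0)) {
  structure(list(qname = qname, flag = as.integer(flag), rname = rname,
                 pos = as.integer(pos), mapq = as.integer(mapq),
                 cigar = cigar, rnext = rnext, pnext = as.integer(pnext),
                 tlen = as.integer(tlen), seq = seq, qual = qual,
                 tags = tags),
            class = "SamRecord")
}

cigar_lengths <- function(cigar) {
  if (identical(cigar, "*")) return(list(read = NA_integer_, ref = NA_integer_))
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(read = sum(n[op %in% c("M", "I", "S", "=", "X")]),
       ref = sum(n[op %in% c("M", "D", "N", "=", "X")]))
}

#' Write SAM
#'
#' Emits `@HD`, one `@SQ` per reference, one `@PG`, then the records.
#' Mapped records must name a declared reference and their CIGAR read
#' length must equal the sequence length; violations are consistency
#' errors, not silently written.
#'
#' @param records list of [sam_record()]s.
#' @param refs list of `list(name=, seq=)` references (names and lengths go
#'   into `@SQ` lines).
#' @param file path, `"-"` for stdout, or connection.
#' @param program program line id (`@PG ID:`).
#' @param cl command-line string recorded on the `@PG` line.
#' @export
write_sam <- function(records, refs, file, program = "gibarra",
                      cl = "") {
  dst <- open_output(file)
  on.exit(if (dst$close) close(dst$con))
  names <- vapply(refs, function(r) r$name, character(1))
  lens <- vapply(refs, function(r) nchar(r$seq), integer(1))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names, lens),
           paste0("@PG\tID:", program, "\tPN:", program,
                  if (nzchar(cl)) paste0("\tCL:", cl) else ""))
  writeLines(hdr, dst$con)
  lines <- vapply(records, function(r) {
    mapped <- bitwAnd(r$flag, SAM_FLAGS[["UNMAPPED"]]) == 0L
    if (mapped) {
      if (!(r$rname %in% names)) {
        stop("SAM consistency error: rname '", r$rname,
             "' not declared in header", call. = FALSE)
      }
      if (r$pos < 1L) {
        stop("SAM consistency error: mapped record '", r$qname,
             "' has pos < 1", call. = FALSE)
      }
      cln <- cigar_lengths(r$cigar)
      if (!is.na(cln$read) && r$seq != "*" && cln$read != nchar(r$seq)) {
        stop("SAM consistency error: CIGAR length ", cln$read,
             " != sequence length ", nchar(r$seq), " for '", r$qname, "'",
             call. = FALSE)
      }
    }
    paste(c(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext,
            r$pnext, r$tlen, r$seq, r$qual, r$tags), collapse = "\t")
  }, character(1))
  if (length(lines)) writeLines(lines, dst$con)
  invisible(NULL)
}

#' Read SAM records into a data.frame
#'
#' Minimal reader for the scorer and tests; header lines are skipped and
#' the eleven mandatory columns plus a concatenated tag string are
#' returned.
#'
#' @param file path, `"-"` for stdin, or connection.
#' @export
read_sam <- function(file) {
  src <- open_input(file)
  on.exit(if (src$close) close(src$con))
  lines <- readLines(src$con, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), tags = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  col <- function(i) vapply(f, `[`, character(1), i)
  data.frame(qname = col(1), flag = as.integer(col(2)), rname = col(3),
             pos = as.integer(col(4)), mapq = as.integer(col(5)),
             cigar = col(6), rnext = col(7), pnext = as.integer(col(8)),
             tlen = as.integer(col(9)), seq = col(10), qual = col(11),
             tags = vapply(f, function(x) {
               if (length(x) > 11L) paste(x[-(1:11)], collapse = "\t") else ""
             }, character(1)),
             stringsAsFactors = FALSE)
}
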