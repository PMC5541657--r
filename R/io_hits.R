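# Pipe-friendly intermediate hits format (the analogue of the .sai files
# between the `aln` and `sampe` stages).  Line-oriented text, versioned,
# readable from non-seekable streams; one block per input read, in input
# order.

HITS_MAGIC <- "#GIBARRA-HITS"
HITS_VERSION <- 1L

#' Write an alignment hits stream
#'
#' The header carries the format version, the checksum of the index the
#' hits were computed against, and the kernel parameters, so `sampe` can
#' detect an index/hits mismatch.
#'
#' @param results list of per-read [align_read()] results (elements `id`,
#'   `hits`, `mapq`, `truncated`).
#' @param file path, `"-"` for stdout, or connection.
#' @param checksum index checksum string (from `index$fwd$checksum`).
#' @param params_label free-text parameter descriptor stored in the header.
#' @export
write_hits <- function(results, file, checksum = "", params_label = "") {
  dst <- open_output(file)
  on.exit(if (dst$close) close(dst$con))
  writeLines(paste(HITS_MAGIC, HITS_VERSION, checksum, params_label,
                   sep = "\t"), dst$con)
  blocks <- vapply(results, function(r) {
    h <- r$hits
    head <- paste("@", r$id, "\t", nrow(h), "\t", r$mapq, "\t",
                  as.integer(isTRUE(r$truncated)), sep = "")
    if (nrow(h) == 0L) return(head)
    body <- paste(h$refname, h$pos, h$strand, h$score, h$n_mismatch,
                  h$n_gap_open, h$n_gap_ext, h$cigar, h$interval_size,
                  sep = "\t")
    paste(c(head, body), collapse = "\n")
  }, character(1))
  writeLines(blocks, dst$con)
  invisible(NULL)
}

#' Read an alignment hits stream
#'
#' @inheritParams write_hits
#' @param file path, `"-"` for stdin, or connection (pipes supported).
#' @return `list(version=, checksum=, params_label=, records=)`; each record
#'   is `list(id=, mapq=, truncated=, hits=)` with `hits` a data.frame in
#'   the same column layout [align_read()] produces.
#' @export
read_hits <- function(file) {
  src <- open_input(file)
  on.exit(if (src$close) close(src$con))
  lines <- readLines(src$con, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], HITS_MAGIC)) {
    stop("hits format error: missing header", call. = FALSE)
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  version <- as.integer(hdr[2])
  if (!identical(version, HITS_VERSION)) {
    stop("hits format version mismatch: stream has ", hdr[2],
         ", this build reads ", HITS_VERSION, call. = FALSE)
  }
  lines <- lines[-1]
  heads <- startsWith(lines, "@")
  if (length(lines) && !heads[1]) {
    stop("hits format error: record body before first read header",
         call. = FALSE)
  }
  idx <- which(heads)
  records <- vector("list", length(idx))
  grp <- cumsum(heads)
  for (k in seq_along(idx)) {
    hf <- strsplit(sub("^@", "", lines[idx[k]]), "\t", fixed = TRUE)[[1]]
    nh <- as.integer(hf[2])
    body <- lines[grp == k][-1]
    if (length(body) != nh) {
      stop("hits format error: read '", hf[1], "' declares ", nh,
           " hits but has ", length(body), call. = FALSE)
    }
    hits <- empty_hits()
    if (nh > 0L) {
      f <- strsplit(body, "\t", fixed = TRUE)
      hits <- data.frame(
        refname = vapply(f, `[`, character(1), 1L),
        pos = as.integer(vapply(f, `[`, character(1), 2L)),
        strand = vapply(f, `[`, character(1), 3L),
        score = as.integer(vapply(f, `[`, character(1), 4L)),
        n_mismatch = as.integer(vapply(f, `[`, character(1), 5L)),
        n_gap_open = as.integer(vapply(f, `[`, character(1), 6L)),
        n_gap_ext = as.integer(vapply(f, `[`, character(1), 7L)),
        cigar = vapply(f, `[`, character(1), 8L),
        interval_size = as.integer(vapply(f, `[`, character(1), 9L)),
        stringsAsFactors = FALSE)
    }
    records[[k]] <- list(id = hf[1], mapq = as.integer(hf[3]),
                         truncated = hf[4] == "1", hits = hits)
  }
  list(version = version, checksum = hdr[3],
       params_label = if (length(hdr) >= 4) hdr[4] else "",
       records = records)
}
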