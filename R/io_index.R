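# Aligner index container: forward FM index plus an index of the reversed
# reference text (used for the per-prefix difference lower bound), packed in
# a versioned, self-describing on-disk container.

GIDX_MAGIC <- "GIBARRA-INDEX"
GIDX_VERSION <- 1L

#' Build the full aligner index for a reference
#'
#' Builds the forward FM index over the concatenated references and a second
#' FM index over the reversed text, which the backtracking search uses to
#' compute its pruning lower bound.
#'
#' @inheritParams build_index
#' @return an object of class `GibarraIndex` with elements `fwd` and `rev`.
#' @export
index_reference <- function(refs, sa_stride = 4L, occ_stride = 64L) {
  fwd <- build_index(refs, sa_stride, occ_stride)
  rev_refs <- list(list(
    name = "rev",
    seq = reverse_string(paste(vapply(refs, function(r) r$seq, character(1)),
                               collapse = ""))))
  rev <- build_index(rev_refs, sa_stride, occ_stride)
  structure(list(fwd = fwd, rev = rev), class = "GibarraIndex")
}

#' @export
print.GibarraIndex <- function(x, ...) {
  cat("GibarraIndex (forward + reversed-text FM indexes)\n")
  print(x$fwd)
  invisible(x)
}

#' Save / load an aligner index
#'
#' The `.gidx` container is self-describing: a magic string, a format
#' version and the reference checksum are stored with the index and checked
#' on load, so an index/hits mismatch is detected instead of silently
#' producing wrong coordinates.
#'
#' @param index a [index_reference()] object.
#' @param path file path (conventionally `PREFIX.gidx`).
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "GibarraIndex"))
  obj <- list(magic = GIDX_MAGIC, version = GIDX_VERSION,
              checksum = index$fwd$checksum, index = index)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a gibarra index file: ", path, call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$magic, GIDX_MAGIC)) {
    stop("not a gibarra index file: ", path, call. = FALSE)
  }
  if (!identical(obj$version, GIDX_VERSION)) {
    stop("index format version mismatch: file has ", obj$version,
         ", this build reads ", GIDX_VERSION, call. = FALSE)
  }
  if (!identical(obj$checksum, obj$index$fwd$checksum)) {
    stop("index checksum mismatch: file is corrupt", call. = FALSE)
  }
  obj$index
}
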