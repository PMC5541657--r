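# shared fixture builders -- everything is generated in code at test time

random_genome_string <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

ref_of <- function(seq, name = "ref") list(name = name, seq = seq)

index_of <- function(seq, name = "ref", ...) {
  index_reference(list(ref_of(seq, name)), ...)
}

read_of <- function(bases, id = "r1") {
  list(id = id, bases = bases, quals = strrep("I", nchar(bases)))
}

# draw a read of length rl from genome position `at` (1-based) and plant a
# fixed number of edits (substitutions or 1-2 bp indels) away from the read
# ends; after an indel the tail is refilled from the genome so the read
# stays genomic except at the planted edits
plant_read <- function(g, at, rl, n_edits, indel_ok = TRUE) {
  slack <- 12L
  stopifnot(at + rl + slack <= nchar(g))
  ch <- strsplit(substr(g, at, at + rl + slack - 1L), "", fixed = TRUE)[[1]]
  for (k in seq_len(n_edits)) {
    kind <- if (indel_ok) sample(c("sub", "ins", "del"), 1L,
                                 prob = c(0.6, 0.2, 0.2)) else "sub"
    p <- sample(seq(5L, rl - 5L), 1L)
    if (kind == "sub") {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    } else if (kind == "ins") {
      w <- sample(1:2, 1L)
      ins <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
      ch <- c(ch[seq_len(p)], ins, ch[(p + 1L):length(ch)])
    } else {
      w <- sample(1:2, 1L)
      ch <- ch[-(p:(p + w - 1L))]
    }
  }
  paste(ch[seq_len(rl)], collapse = "")
}

sam_df_of <- function(records, refs) {
  tf <- tempfile(fileext = ".sam")
  on.exit(unlink(tf))
  write_sam(records, refs, tf)
  read_sam(tf)
}
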