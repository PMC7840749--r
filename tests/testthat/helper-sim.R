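# Fixture builders shared by the caller tests.

# Write a SAM file from a list of alignment records over the given
# sequences. Each record: list(qname, flag, contig, pos (1-based), mapq,
# seq, qual (optional; defaults to constant Phred 37)).
write_test_sam <- function(records, seqs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  body <- vapply(records, function(r) {
    qual <- if (!is.null(r$qual)) r$qual
            else paste(rep("F", nchar(r$seq)), collapse = "")
    paste(r$qname, r$flag, r$contig, r$pos,
          if (!is.null(r$mapq)) r$mapq else 60L,
          paste0(nchar(r$seq), "M"), "=", r$pos, nchar(r$seq),
          r$seq, qual, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

chars_of <- function(seqs) {
  lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

# A proper OT pair (flags 99/147) whose two mates are PCR copies of one
# converted fragment given as a forward-orientation string.
ot_pair <- function(qname, contig, pos, frag, read_length, mapq = 60L) {
  w <- nchar(frag)
  left <- substr(frag, 1L, read_length)
  right <- substr(frag, w - read_length + 1L, w)
  list(
    list(qname = qname, flag = 99L, contig = contig, pos = pos,
         mapq = mapq, seq = left),
    list(qname = qname, flag = 147L, contig = contig,
         pos = pos + w - read_length, mapq = mapq, seq = right))
}

ob_pair <- function(qname, contig, pos, frag, read_length, mapq = 60L) {
  w <- nchar(frag)
  left <- substr(frag, 1L, read_length)
  right <- substr(frag, w - read_length + 1L, w)
  list(
    list(qname = qname, flag = 83L, contig = contig,
         pos = pos + w - read_length, mapq = mapq, seq = right),
    list(qname = qname, flag = 163L, contig = contig, pos = pos,
         mapq = mapq, seq = left))
}
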