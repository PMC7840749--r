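#' Filters applied before counting modification evidence
#'
#' @param min_mapq Minimum mapping quality; alignments below it are excluded
#'   from modified-site calling (default 10).
#' @param min_baseq Minimum Phred base quality for a base to be counted
#'   (default 13).
#' @param exclude_duplicates Honor the duplicate FLAG (duplicates are assumed
#'   to have been marked upstream; no internal dedup).
#' @return A list of class `call_filters`.
#' @export
call_filters <- function(min_mapq = 10L, min_baseq = 13L,
                         exclude_duplicates = TRUE) {
  stopifnot(min_mapq >= 0, min_baseq >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 exclude_duplicates = isTRUE(exclude_duplicates)),
            class = "call_filters")
}

# Convert SAM to sorted BAM if needed; returns a BAM path.
as_bam_path <- function(alignments) {
  ext <- tolower(tools::file_ext(alignments))
  if (ext == "bam") return(alignments)
  if (ext == "sam") {
    dest <- tempfile("bk_aln_")
    return(Rsamtools::asBam(alignments, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE))
  }
  stop("'alignments' must be a .sam or .bam file", call. = FALSE)
}

# Expand one alignment into (reference position, read position) pairs for
# aligned bases. Handles M/=/X (aligned), I/S (read only), D/N (ref only),
# H/P (neither).
cigar_aligned_pairs <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  rpos <- 0L; qpos <- 0L
  ref <- integer(0); qry <- integer(0)
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      ref <- c(ref, rpos + seq_len(len)); qry <- c(qry, qpos + seq_len(len))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    }
  }
  list(ref_off = ref, read_off = qry)
}

#' Call per-cytosine modification counts from aligned reads
#'
#' Strand-aware pileup over a SAM/BAM file: counts, at every reference
#' cytosine, the chemistry transitions (C→T on the top strand, G→A in
#' top-strand coordinates for bottom-strand cytosines) versus retained bases.
#' Read pairs in original-top orientation (FLAGs 99/147) contribute to `+`
#' records; original-bottom pairs (83/163) to `-` records. Overlapping mate
#' bases are counted once (first mate wins). Unmapped, secondary,
#' supplementary, QC-fail and (by default) duplicate alignments are excluded;
#' unpaired reads are skipped with a message.
#'
#' @param alignments Path to a SAM or BAM file.
#' @param reference A `bk_reference`, `DNAStringSet` or FASTA path; must
#'   contain every contig the alignments refer to.
#' @param filters A [call_filters()].
#' @return A mods table: `data.table` with columns `contig`, `pos0` (0-based,
#'   top strand), `strand`, `context` (CpG/CHG/CHH), `context5`, `n_mod`,
#'   `n_unmod`, `n_other`, `coverage`, `signal` = n_mod/(n_mod+n_unmod).
#'   Records with zero coverage are not emitted.
#' @export
call_mods <- function(alignments, reference, filters = call_filters()) {
  stopifnot(inherits(filters, "call_filters"))
  seqs <- reference_seqs(reference)
  bam <- as_bam_path(alignments)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
    isDuplicate = if (filters$exclude_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  aln <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(aln$pos)
  sites <- cytosine_sites(seqs)
  empty <- sites[0][, `:=`(n_mod = integer(0), n_unmod = integer(0),
                           n_other = integer(0), coverage = integer(0),
                           signal = numeric(0))]
  if (n == 0L) return(empty[])
  if (!all(as.character(aln$rname) %in% names(seqs))) {
    stop("alignment refers to a contig absent from the reference",
         call. = FALSE)
  }
  keep <- !is.na(aln$mapq) & aln$mapq >= filters$min_mapq
  fl <- aln$flag
  paired <- bitwAnd(fl, 0x1) > 0
  n_unpaired <- sum(keep & !paired)
  if (n_unpaired > 0) {
    message(n_unpaired, " unpaired alignment(s) skipped")
  }
  keep <- keep & paired
  if (!any(keep)) return(empty[])
  idx <- which(keep)
  first <- bitwAnd(fl[idx], 0x40) > 0
  reverse <- bitwAnd(fl[idx], 0x10) > 0
  # original-top molecules: forward first mates and reverse second mates
  ot <- (first & !reverse) | (!first & reverse)

  seq_chr <- as.character(aln$seq[idx])
  qual_chr <- as.character(aln$qual[idx])
  cigars <- aln$cigar[idx]
  simple <- grepl("^[0-9]+M$", cigars)

  qname_v <- aln$qname[idx]
  contig_v <- as.character(aln$rname[idx])
  pos_v <- aln$pos[idx]

  # bulk expansion for all-match alignments; per-read walk otherwise
  parts <- list()
  is_sim <- which(simple)
  if (length(is_sim)) {
    lens <- nchar(seq_chr[is_sim])
    rid <- rep.int(seq_along(is_sim), lens)
    off <- sequence(lens)
    parts$simple <- data.table::data.table(
      qname = qname_v[is_sim][rid],
      first = first[is_sim][rid],
      ot = ot[is_sim][rid],
      contig = contig_v[is_sim][rid],
      refpos = pos_v[is_sim][rid] + off - 1L,
      base = strsplit(paste(seq_chr[is_sim], collapse = ""), "",
                      fixed = TRUE)[[1]],
      bq = utf8ToInt(paste(qual_chr[is_sim], collapse = "")) - 33L)
  }
  for (i in which(!simple)) {
    pr <- cigar_aligned_pairs(cigars[i])
    if (!length(pr$read_off)) next
    parts[[length(parts) + 1L]] <- data.table::data.table(
      qname = qname_v[i], first = first[i], ot = ot[i],
      contig = contig_v[i],
      refpos = pos_v[i] + pr$ref_off - 1L,
      base = strsplit(seq_chr[i], "", fixed = TRUE)[[1]][pr$read_off],
      bq = utf8ToInt(qual_chr[i])[pr$read_off] - 33L)
  }
  bases <- data.table::rbindlist(parts)
  if (nrow(bases)) bases <- bases[bq >= filters$min_baseq][, bq := NULL]
  if (nrow(bases) == 0L) return(empty[])
  # count each molecule once where mates overlap: first mate wins
  data.table::setorder(bases, contig, refpos, qname, -first)
  bases <- unique(bases, by = c("qname", "contig", "refpos"))

  count_strand <- function(b, mod_base, unmod_base) {
    b[, .(n_mod = sum(base == mod_base),
          n_unmod = sum(base == unmod_base),
          n_other = sum(base != mod_base & base != unmod_base)),
      by = .(contig, refpos)]
  }
  plus <- count_strand(bases[ot == TRUE], "T", "C")
  minus <- count_strand(bases[ot == FALSE], "A", "G")
  plus[, `:=`(pos0 = refpos - 1L, strand = "+")]
  minus[, `:=`(pos0 = refpos - 1L, strand = "-")]
  counts <- data.table::rbindlist(list(plus, minus))[, refpos := NULL]
  mods <- merge(sites, counts, by = c("contig", "pos0", "strand"))
  mods[, coverage := n_mod + n_unmod + n_other]
  mods <- mods[coverage > 0]
  mods[, signal := ifelse(n_mod + n_unmod > 0,
                          n_mod / (n_mod + n_unmod), NA_real_)]
  data.table::setorder(mods, contig, pos0, strand)
  mods[]
}

# Accept a GRanges or a BED path (0-based half-open on disk; rtracklayer
# imports to 1-based closed GRanges).
as_granges_regions <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(rtracklayer::import(x, format = "BED"))
  }
  stop("regions must be a GRanges or a BED file path", call. = FALSE)
}

#' Remove mods records falling in masked regions
#'
#' Drops records whose cytosine position overlaps a blacklist (mapping
#' artifact) or SNV-mask interval. BED input is 0-based half-open per the
#' standard.
#'
#' @param mods A mods table from [call_mods()].
#' @param blacklist,snv_mask `GRanges` or BED paths; `NULL` to skip.
#' @return The filtered mods table; the number of removed records is
#'   reported with a message.
#' @export
apply_masks <- function(mods, blacklist = NULL, snv_mask = NULL) {
  mods <- data.table::as.data.table(mods)
  drop <- rep(FALSE, nrow(mods))
  if (nrow(mods)) {
    pts <- GenomicRanges::GRanges(
      mods$contig, IRanges::IRanges(mods$pos0 + 1L, mods$pos0 + 1L))
    for (msk in list(as_granges_regions(blacklist),
                     as_granges_regions(snv_mask))) {
      if (!is.null(msk)) {
        drop <- drop | IRanges::overlapsAny(pts, msk)
      }
    }
  }
  message(sum(drop), " masked record(s) removed")
  mods[!drop]
}

#' Pool the two strands of each CpG dyad
#'
#' Sums the `+` and `-` records of a CpG dyad into one record keyed at the
#' `+` cytosine (dyads with a single strand observed pass through). Records
#' in other contexts are unchanged. Optional: strand-resolved analysis is
#' the default elsewhere.
#'
#' @param mods A mods table.
#' @return A mods table with merged CpG records (strand `+`).
#' @export
merge_cpg_strands <- function(mods) {
  mods <- data.table::as.data.table(mods)
  is_cpg <- !is.na(mods$context) & mods$context == "CpG"
  cpg <- mods[is_cpg]
  if (nrow(cpg)) {
    cpg[, dyad0 := ifelse(strand == "+", pos0, pos0 - 1L)]
    data.table::setorder(cpg, contig, dyad0, strand)  # '+' first
    merged <- cpg[, .(pos0 = dyad0[1L], strand = "+",
                      context = "CpG", context5 = context5[1L],
                      n_mod = sum(n_mod), n_unmod = sum(n_unmod),
                      n_other = sum(n_other)),
                  by = .(contig, dyad0)][, dyad0 := NULL]
    merged[, coverage := n_mod + n_unmod + n_other]
    merged[, signal := ifelse(n_mod + n_unmod > 0,
                              n_mod / (n_mod + n_unmod), NA_real_)]
  } else {
    merged <- cpg
  }
  out <- data.table::rbindlist(list(mods[!is_cpg], merged), use.names = TRUE)
  data.table::setorder(out, contig, pos0, strand)
  out[]
}

#' Write / read a mods table
#'
#' Tab-separated with a '#'-prefixed header and columns contig, pos0, end
#' (pos0+1), signal (6 decimals), n_mod, n_unmod, context3, context5,
#' strand, coverage.
#'
#' @param mods A mods table.
#' @param path File path.
#' @return `path` (write) or a mods table (read).
#' @export
write_mods <- function(mods, path) {
  out <- data.table::data.table(
    contig = mods$contig, pos0 = mods$pos0, end = mods$pos0 + 1L,
    signal = sprintf("%.6f", mods$signal),
    n_mod = mods$n_mod, n_unmod = mods$n_unmod,
    context3 = mods$context, context5 = mods$context5,
    strand = mods$strand, coverage = mods$coverage)
  writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mods
#' @export
read_mods <- function(path) {
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = c("contig", "pos0", "end", "signal",
                                        "n_mod", "n_unmod", "context3",
                                        "context5", "strand", "coverage"))
  out <- dt[, .(contig, pos0, strand, context = context3, context5,
                n_mod, n_unmod,
                n_other = coverage - n_mod - n_unmod, coverage,
                signal = as.numeric(signal))]
  out[]
}

#' Export the modification signal as bedGraph
#'
#' @param mods A mods table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(mods, path) {
  dt <- data.table::as.data.table(mods)[!is.na(signal)]
  out <- dt[, .(contig, pos0, end = pos0 + 1L,
                signal = sprintf("%.6f", signal))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
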