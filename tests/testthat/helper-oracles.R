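# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Upper-tail binomial probability by explicit pmf summation.
pmf_tail_oracle <- function(k, n, p0) {
  if (k <= 0) return(1)
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# Brute-force grid search of the constrained two-assay MLE over the simplex
# at the given step. Exploits separability of the log-likelihood: for each
# value of theta1 the best theta2 under the ordering constraint is found by
# a prefix argmax, so the full grid optimum at the stated step is exact.
# design "nested":   assay1 reads m+h, assay2 reads m   (theta2 <= theta1)
# design "disjoint": assay1 reads m,   assay2 reads h   (theta1+theta2 <= 1)
grid_mle_oracle <- function(k1, n1, k2, n2, design = c("nested", "disjoint"),
                            step = 1e-4) {
  design <- match.arg(design)
  g <- seq(0, 1, by = step)
  ll1 <- stats::dbinom(k1, n1, g, log = TRUE)
  ll2 <- stats::dbinom(k2, n2, g, log = TRUE)
  # prefix argmax of ll2: index i is a new running maximum iff ll2[i] equals
  # the running cummax; carrying the latest such index forward
  cm <- cummax(ll2)
  best2 <- cummax(seq_along(g) * (ll2 >= cm))
  if (design == "nested") {
    tot <- ll1 + ll2[best2]
    i1 <- which.max(tot)
    th1 <- g[i1]; th2 <- g[best2[i1]]
    c(m = th2, h = th1 - th2)
  } else {
    # best theta2 with theta2 <= 1 - theta1
    lim <- rev(best2)  # index of argmax over g[1..(G-i+1)] reversed
    tot <- ll1 + ll2[lim]
    i1 <- which.max(tot)
    th1 <- g[i1]; th2 <- g[lim[i1]]
    c(m = th1, h = th2)
  }
}

# Naive, independent strand-aware pileup over a plain-text SAM file with
# all-match CIGARs. First mate wins where mates overlap; honors MAPQ,
# base-quality, paired and exclude flags.
brute_pileup <- function(sam_path, ref_chars_by_contig,
                         min_mapq = 10, min_baseq = 13) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  seen <- new.env(hash = TRUE)
  counts <- new.env(hash = TRUE)
  bump <- function(key, slot) {
    cur <- if (!is.null(counts[[key]])) counts[[key]] else c(0, 0, 0)
    cur[slot] <- cur[slot] + 1
    counts[[key]] <- cur
  }
  # read2 lines processed after read1 lines so that read1 wins overlaps
  fields <- strsplit(lines, "\t", fixed = TRUE)
  flags <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  ord <- order(bitwAnd(flags, 0x40) == 0)  # first mates first
  for (f in fields[ord]) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x1) == 0) next                      # unpaired
    if (bitwAnd(flag, 0x4 + 0x100 + 0x200 + 0x400 + 0x800) != 0) next
    if (as.integer(f[5]) < min_mapq) next
    stopifnot(grepl("^[0-9]+M$", f[6]))
    contig <- f[3]; pos <- as.integer(f[4])
    bases <- strsplit(f[10], "")[[1]]
    quals <- utf8ToInt(f[11]) - 33L
    first <- bitwAnd(flag, 0x40) > 0
    reverse <- bitwAnd(flag, 0x10) > 0
    ot <- (first && !reverse) || (!first && reverse)
    for (i in seq_along(bases)) {
      if (quals[i] < min_baseq) next
      rp <- pos + i - 1L
      mol <- paste(f[1], contig, rp)
      if (!is.null(seen[[mol]])) next
      seen[[mol]] <- TRUE
      refbase <- ref_chars_by_contig[[contig]][rp]
      if (ot && refbase == "C") {
        key <- paste(contig, rp - 1L, "+")
        bump(key, if (bases[i] == "T") 1L else if (bases[i] == "C") 2L else 3L)
      } else if (!ot && refbase == "G") {
        key <- paste(contig, rp - 1L, "-")
        bump(key, if (bases[i] == "A") 1L else if (bases[i] == "G") 2L else 3L)
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(data.table::data.table(contig = character(0), pos0 = integer(0),
                                  strand = character(0), n_mod = integer(0),
                                  n_unmod = integer(0), n_other = integer(0)))
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.table::data.table(
    contig = parts[, 1], pos0 = as.integer(parts[, 2]), strand = parts[, 3],
    n_mod = vapply(keys, function(k) as.integer(counts[[k]][1]), integer(1)),
    n_unmod = vapply(keys, function(k) as.integer(counts[[k]][2]), integer(1)),
    n_other = vapply(keys, function(k) as.integer(counts[[k]][3]), integer(1)))
  data.table::setorder(out, contig, pos0, strand)
  out[]
}
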