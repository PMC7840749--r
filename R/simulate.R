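#' Spike-in specification
#'
#' Describes one control contig of known modification state added to a
#' simulated library, mirroring the spike-in controls used to measure
#' conversion and false-positive rates:
#' \describe{
#'   \item{lambda_meth}{fully CpG-methylated contig (M.SssI-treated lambda
#'     DNA analogue): `mC = 1` at every CpG cytosine, 0 elsewhere.}
#'   \item{unmod_2kb}{completely unmodified contig; its cytosines measure the
#'     false-positive rate.}
#'   \item{oligo_mC_hmC}{synthetic oligo analogue carrying 5mC and 5hmC at
#'     designated CpG positions (alternating dyads).}
#'   \item{fC_oligo}{oligo extended with 5-formyl-dCTP: every cytosine is
#'     5fC.}
#'   \item{caC_2kb}{PCR product methylated then fully TET-oxidised:
#'     `caC = 1` at every CpG cytosine.}
#' }
#' The generated sequences are synthetic random contigs, not the real
#' spike-in sequences; only their truth structure is emulated.
#'
#' @param kind One of `"lambda_meth"`, `"unmod_2kb"`, `"oligo_mC_hmC"`,
#'   `"fC_oligo"`, `"caC_2kb"`.
#' @param length Contig length in bp (>= 200).
#' @param depth_multiplier Fold-coverage multiplier relative to the genomic
#'   depth passed to [simulate_reads()] (spike-ins are minor mass fractions of
#'   a real library but are usually simulated deep).
#' @return An object of class `spikein_spec`.
#' @export
spikein_spec <- function(kind = c("lambda_meth", "unmod_2kb", "oligo_mC_hmC",
                                  "fC_oligo", "caC_2kb"),
                         length = NULL, depth_multiplier = 1) {
  kind <- match.arg(kind)
  if (is.null(length)) {
    length <- switch(kind,
      lambda_meth = 5000L, unmod_2kb = 2000L, caC_2kb = 2000L,
      oligo_mC_hmC = 400L, fC_oligo = 400L)
  }
  length <- as.integer(length)
  if (length < 200L) stop("spike-in length must be >= 200 bp", call. = FALSE)
  structure(list(kind = kind, length = length,
                 depth_multiplier = depth_multiplier),
            class = "spikein_spec")
}

#' Default spike-in set
#'
#' The five-control set used for conversion-rate QC.
#' @return List of [spikein_spec()] objects.
#' @export
default_spikeins <- function() {
  lapply(c("lambda_meth", "unmod_2kb", "oligo_mC_hmC", "fC_oligo", "caC_2kb"),
         spikein_spec)
}

#' Generate a synthetic reference with optional spike-in contigs
#'
#' Draws i.i.d. bases at the requested GC fraction for `n_contigs` genomic
#' contigs, plus one contig per spike-in (GC 0.5). Deterministic for a fixed
#' seed.
#'
#' @param n_contigs Number of genomic contigs.
#' @param contig_length Length of each genomic contig in bp (>= 200).
#' @param gc_fraction Target G+C fraction in \[0,1\].
#' @param spikeins List of [spikein_spec()] objects (may be empty).
#' @param seed Integer seed.
#' @return An object of class `bk_reference`: a list with `seq` (a named
#'   [Biostrings::DNAStringSet]) and `spikein` (named character vector
#'   mapping spike-in contig names to kinds).
#' @export
generate_reference <- function(n_contigs, contig_length, gc_fraction,
                               spikeins = list(), seed) {
  if (n_contigs > 0 && contig_length < 200) {
    stop("contig_length must be >= 200 bp", call. = FALSE)
  }
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  withr::with_seed(seed, {
    draw <- function(len, gc) {
      probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = "")
    }
    seqs <- character(0)
    if (n_contigs > 0) {
      seqs <- vapply(seq_len(n_contigs), function(i)
        draw(contig_length, gc_fraction), character(1))
      names(seqs) <- paste0("contig", seq_len(n_contigs))
    }
    spk <- character(0)
    for (sp in spikeins) {
      nm <- paste0("spike_", sp$kind)
      seqs[[nm]] <- draw(sp$length, 0.5)
      spk[[nm]] <- sp$kind
    }
    structure(list(seq = Biostrings::DNAStringSet(seqs), spikein = spk),
              class = "bk_reference")
  })
}

#' Write the reference to FASTA
#' @param reference A `bk_reference` or [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  seq <- if (inherits(reference, "bk_reference")) reference$seq else reference
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

reference_seqs <- function(reference) {
  if (inherits(reference, "bk_reference")) return(reference$seq)
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  stop("'reference' must be a bk_reference, DNAStringSet or FASTA path",
       call. = FALSE)
}

# Complement lookup for single characters.
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(chars) rev(unname(.comp[chars]))

#' Enumerate all cytosine sites of a reference
#'
#' One row per cytosine on either strand, with the trinucleotide context read
#' 5'→3' on the cytosine's own strand. Positions are 0-based on the top
#' strand; a `-` row is a G on the top strand (a cytosine on the bottom
#' strand). Context is `CpG`, `CHG` or `CHH`; `NA` within 2 bp of a contig
#' end where the context is undefined.
#'
#' @param reference See [generate_reference()].
#' @return A [data.table::data.table] with columns `contig`, `pos0`, `strand`,
#'   `context`, `context5`.
#' @export
cytosine_sites <- function(reference) {
  seqs <- reference_seqs(reference)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(as.character(seqs[[i]]), "", fixed = TRUE)[[1]]
    n <- length(chars)
    pad <- c(chars, "N", "N")
    # top strand: C at p, context = pad[p..p+2]
    p_top <- which(chars == "C")
    # bottom strand: C opposite a top-strand G; 5'->3' runs leftwards
    p_bot <- which(chars == "G")
    padl <- c("N", "N", chars)
    ctx_of <- function(c2, c3) {
      ifelse(c2 == "G", "CpG",
             ifelse(c2 == "N", NA_character_,
                    ifelse(c3 == "G", "CHG",
                           ifelse(c3 == "N", NA_character_, "CHH"))))
    }
    top <- NULL
    if (length(p_top)) {
      c2 <- pad[p_top + 1L]; c3 <- pad[p_top + 2L]
      top <- data.table::data.table(
        contig = names(seqs)[i], pos0 = p_top - 1L, strand = "+",
        context = ctx_of(c2, c3), context5 = paste0("C", c2, c3))
    }
    bot <- NULL
    if (length(p_bot)) {
      # on the bottom strand the next bases are complements of top p-1, p-2
      c2 <- unname(.comp[padl[p_bot + 1L]])  # top index p-1
      c3 <- unname(.comp[padl[p_bot]])       # top index p-2
      bot <- data.table::data.table(
        contig = names(seqs)[i], pos0 = p_bot - 1L, strand = "-",
        context = ctx_of(c2, c3), context5 = paste0("C", c2, c3))
    }
    out[[i]] <- data.table::rbindlist(list(top, bot))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, contig, pos0, strand)
  res[]
}

#' Methylome generator configuration
#'
#' Defaults emulate a mammalian (mESC-like) methylome: bimodal CpG 5mC drawn
#' from a U-shaped Beta, sparse 5hmC at a mean level well below 5mC, and
#' trace 5fC/5caC; non-CpG cytosines are unmodified.
#'
#' @param cpg_mC_beta_params Length-2 shape parameters of the Beta
#'   distribution for CpG 5mC levels. The default `c(0.6, 0.15)` is bimodal
#'   (mass at 0 and 1) with mean 0.8.
#' @param hmC_site_fraction Fraction of CpG dyads carrying 5hmC.
#' @param hmC_mean_level Mean 5hmC level at carrying sites.
#' @param fC_site_fraction,caC_site_fraction Fractions of CpG dyads carrying
#'   5fC / 5caC (disjoint from each other and from the 5hmC subset).
#' @param fC_level,caC_level Level assigned at carrying sites.
#' @param symmetric_cpg If `TRUE` (default) both cytosines of a CpG dyad
#'   share one level draw.
#' @return A list of class `methylome_config`.
#' @export
methylome_config <- function(cpg_mC_beta_params = c(0.6, 0.15),
                             hmC_site_fraction = 0.10,
                             hmC_mean_level = 0.2,
                             fC_site_fraction = 0.001,
                             caC_site_fraction = 0.001,
                             fC_level = 0.2, caC_level = 0.2,
                             symmetric_cpg = TRUE) {
  stopifnot(length(cpg_mC_beta_params) == 2L, all(cpg_mC_beta_params > 0),
            hmC_site_fraction >= 0, hmC_site_fraction <= 1,
            fC_site_fraction >= 0, caC_site_fraction <= 1)
  structure(list(cpg_mC_beta_params = cpg_mC_beta_params,
                 hmC_site_fraction = hmC_site_fraction,
                 hmC_mean_level = hmC_mean_level,
                 fC_site_fraction = fC_site_fraction,
                 caC_site_fraction = caC_site_fraction,
                 fC_level = fC_level, caC_level = caC_level,
                 symmetric_cpg = symmetric_cpg),
            class = "methylome_config")
}

#' Generate a ground-truth methylome for a reference
#'
#' Every cytosine of the reference receives a record of per-state levels
#' (fractions of molecules carrying each state). Genomic contigs follow the
#' configuration; spike-in contigs are overridden by their known truth
#' (see [spikein_spec()]). Oxidised states replace part of the 5mC mass at
#' the sites that carry them, so level sums stay within 1; should a custom
#' configuration still overflow, levels are rescaled with a warning.
#'
#' @param reference A `bk_reference` (spike-in truth requires one; a plain
#'   `DNAStringSet` is treated as all-genomic).
#' @param config A [methylome_config()].
#' @param seed Integer seed.
#' @return A `data.table` with columns `contig`, `pos0`, `strand`, `context`,
#'   `context5`, `mC`, `hmC`, `fC`, `caC`.
#' @export
generate_methylome <- function(reference, config = methylome_config(), seed) {
  sites <- cytosine_sites(reference)
  spk <- if (inherits(reference, "bk_reference")) reference$spikein
         else character(0)
  sites[, c("mC", "hmC", "fC", "caC") := 0]
  withr::with_seed(seed, {
    genomic <- !(sites$contig %in% names(spk))
    icpg <- which(genomic & !is.na(sites$context) & sites$context == "CpG")
    if (length(icpg)) {
      cg <- sites[icpg]
      # dyad key: the + cytosine position of the CG pair
      dyad <- ifelse(cg$strand == "+", cg$pos0, cg$pos0 - 1L)
      key <- paste(cg$contig, dyad)
      ukey <- unique(key)
      a <- config$cpg_mC_beta_params[1]; b <- config$cpg_mC_beta_params[2]
      m_d <- stats::rbeta(length(ukey), a, b)
      # disjoint dyad subsets for the oxidised states
      nd <- length(ukey)
      pool <- sample.int(nd)
      n_h <- round(config$hmC_site_fraction * nd)
      n_f <- round(config$fC_site_fraction * nd)
      n_c <- round(config$caC_site_fraction * nd)
      if (n_h + n_f + n_c > nd) {
        stop("hmC/fC/caC site fractions exceed the available CpG dyads",
             call. = FALSE)
      }
      h_d <- f_d <- c_d <- numeric(nd)
      if (n_h > 0) {
        mu <- config$hmC_mean_level
        h_d[pool[seq_len(n_h)]] <- stats::rbeta(n_h, 2, 2 * (1 / mu - 1))
      }
      if (n_f > 0) f_d[pool[n_h + seq_len(n_f)]] <- config$fC_level
      if (n_c > 0) c_d[pool[n_h + n_f + seq_len(n_c)]] <- config$caC_level
      # oxidation consumes existing 5mC mass
      m_d <- pmin(m_d, 1 - (h_d + f_d + c_d))
      idx <- match(key, ukey)
      if (!config$symmetric_cpg) {
        # independent redraw of 5mC per strand; oxidised subsets stay dyad-level
        m_site <- stats::rbeta(length(key), a, b)
        m_site <- pmin(m_site, 1 - (h_d + f_d + c_d)[idx])
        sites[icpg, mC := m_site]
      } else {
        sites[icpg, mC := m_d[idx]]
      }
      sites[icpg, `:=`(hmC = h_d[idx], fC = f_d[idx], caC = c_d[idx])]
    }
    # spike-in truth overrides
    for (nm in names(spk)) {
      kind <- spk[[nm]]
      isp <- which(sites$contig == nm)
      sites[isp, c("mC", "hmC", "fC", "caC") := 0]
      cpg <- isp[!is.na(sites$context[isp]) & sites$context[isp] == "CpG"]
      if (kind == "lambda_meth") {
        sites[cpg, mC := 1]
      } else if (kind == "caC_2kb") {
        sites[cpg, caC := 1]
      } else if (kind == "fC_oligo") {
        sites[isp, fC := 1]
      } else if (kind == "oligo_mC_hmC") {
        cgd <- sites[cpg]
        dyad <- ifelse(cgd$strand == "+", cgd$pos0, cgd$pos0 - 1L)
        udy <- sort(unique(dyad))
        # alternate dyads between the two designed states
        state <- ifelse(match(dyad, udy) %% 2L == 1L, "mC", "hmC")
        sites[cpg[state == "mC"], mC := 1]
        sites[cpg[state == "hmC"], hmC := 1]
      } # unmod_2kb: all zero
    }
  })
  tot <- sites$mC + sites$hmC + sites$fC + sites$caC
  bad <- tot > 1
  if (any(bad)) {
    warning(sum(bad), " site(s) had level sums > 1; rescaled to 1")
    for (col in c("mC", "hmC", "fC", "caC")) {
      data.table::set(sites, which(bad), col, sites[[col]][bad] / tot[bad])
    }
  }
  sites[]
}

#' Write / read a ground-truth methylome table
#'
#' Tab-separated with a '#'-prefixed header: contig, pos0, strand, context,
#' context5, mC, hmC, fC, caC.
#' @param truth Table from [generate_methylome()].
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_truth <- function(truth, path) {
  hdr <- paste0("#", paste(names(truth), collapse = "\t"))
  writeLines(hdr, path)
  data.table::fwrite(truth, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = FALSE)
  data.table::setnames(dt, cols)
  dt[]
}

# Marginal probability that a read base over this cytosine is T: states are
# drawn per molecule from the site's levels, then converted independently, so
# the per-read T probability is the level-weighted readout probability.
site_t_prob <- function(truth, profile) {
  u <- 1 - (truth$mC + truth$hmC + truth$fC + truth$caC)
  u * readout_prob(profile, "C") +
    truth$mC * readout_prob(profile, "mC") +
    truth$hmC * readout_prob(profile, "hmC") +
    truth$fC * readout_prob(profile, "fC") +
    truth$caC * readout_prob(profile, "caC")
}

#' Simulate chemistry-converted paired-end reads
#'
#' Emulates a double-stranded library: each fragment is assigned an original
#' strand (top/bottom) uniformly; every cytosine of that original strand is
#' read as T with probability [readout_prob()] under the state drawn from its
#' truth levels, otherwise as C. The mate is the exact reverse complement
#' (PCR copy), so a top-strand conversion appears as T on `+`-aligned bases
#' and as A at the G of `-`-aligned mates in top-strand coordinates.
#' Output is FASTQ (R1/R2), a pre-aligned SAM (FLAGs 99/147 for
#' original-top, 83/163 for original-bottom pairs; all-match CIGAR; constant
#' Phred 37 base qualities) and a per-site expected T-probability table, so
#' no aligner is needed downstream. Byte-identical for a fixed seed.
#'
#' @param reference A `bk_reference` or `DNAStringSet`.
#' @param truth Methylome table from [generate_methylome()].
#' @param profile A [chemistry_profile()].
#' @param depth Mean fold-coverage of genomic contigs.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param depth_by_contig Optional named numeric vector of per-contig
#'   fold-coverage multipliers (e.g. deep spike-ins).
#' @return Invisibly, a list with paths `sam`, `fastq1`, `fastq2`,
#'   `expected`, and `n_pairs`.
#' @export
simulate_reads <- function(reference, truth, profile, depth,
                           read_length = 80L, insert_mean = 200,
                           insert_sd = 30, seed,
                           out_dir = tempfile("bk_sim_"),
                           prefix = profile$name,
                           depth_by_contig = NULL) {
  stopifnot(inherits(profile, "chemistry_profile"), depth > 0,
            read_length <= insert_mean)
  seqs <- reference_seqs(reference)
  truth <- data.table::as.data.table(truth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sam_path <- file.path(out_dir, paste0(prefix, ".sam"))
  fq1_path <- file.path(out_dir, paste0(prefix, "_R1.fastq"))
  fq2_path <- file.path(out_dir, paste0(prefix, "_R2.fastq"))
  exp_path <- file.path(out_dir, paste0(prefix, "_expected.tsv"))

  qual <- paste(rep(rawToChar(as.raw(33L + 37L)), read_length), collapse = "")
  cigar <- paste0(read_length, "M")

  # expected per-site transition probability table
  expd <- truth[, .(contig, pos0, strand, context,
                    p_T = site_t_prob(truth, profile))]
  hdr <- paste0("#", paste(names(expd), collapse = "\t"))
  writeLines(hdr, exp_path)
  data.table::fwrite(expd, exp_path, sep = "\t", append = TRUE,
                     col.names = FALSE)

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqs), "\tLN:", Biostrings::width(seqs)),
              "@PG\tID:boranekit\tPN:boranekit")

  sam <- list(); fq1 <- list(); fq2 <- list(); pair_id <- 0L
  withr::with_seed(seed, {
    for (ci in seq_along(seqs)) {
      cname <- names(seqs)[ci]
      chars <- strsplit(as.character(seqs[[ci]]), "", fixed = TRUE)[[1]]
      L <- length(chars)
      tr <- truth[contig == cname]
      p_top <- numeric(L); p_bot <- numeric(L)
      if (nrow(tr)) {
        pt <- site_t_prob(tr, profile)
        top <- tr$strand == "+"
        p_top[tr$pos0[top] + 1L] <- pt[top]
        p_bot[tr$pos0[!top] + 1L] <- pt[!top]
      }
      top_sites <- which(chars == "C")
      bot_sites <- which(chars == "G")
      d <- depth
      if (!is.null(depth_by_contig) && cname %in% names(depth_by_contig)) {
        d <- depth * depth_by_contig[[cname]]
      }
      n_frags <- as.integer(round(d * L / (2 * read_length)))
      if (n_frags < 1L) next
      ins <- as.integer(round(stats::rnorm(n_frags, insert_mean, insert_sd)))
      ins <- pmax(read_length, pmin(ins, L))
      if (L < read_length) {
        warning("contig ", cname, " shorter than the read length; skipped")
        next
      }
      starts <- as.integer(floor(stats::runif(n_frags) * (L - ins + 1))) + 1L
      is_top <- stats::runif(n_frags) < 0.5
      e <- profile$seq_error
      csam <- vector("list", n_frags)
      cf1 <- vector("list", n_frags); cf2 <- vector("list", n_frags)
      for (fi in seq_len(n_frags)) {
        s <- starts[fi]; w <- ins[fi]; epos <- s + w - 1L
        frag <- chars[s:epos]
        if (is_top[fi]) {
          loc <- top_sites[top_sites >= s & top_sites <= epos]
          if (length(loc)) {
            hit <- stats::runif(length(loc)) < p_top[loc]
            frag[loc[hit] - s + 1L] <- "T"
          }
        } else {
          loc <- bot_sites[bot_sites >= s & bot_sites <= epos]
          if (length(loc)) {
            hit <- stats::runif(length(loc)) < p_bot[loc]
            frag[loc[hit] - s + 1L] <- "A"
          }
        }
        if (e > 0) {
          site_rel <- if (length(loc)) loc - s + 1L else integer(0)
          non_site <- setdiff(seq_len(w), site_rel)
          err <- non_site[stats::runif(length(non_site)) < e]
          if (length(err)) {
            for (j in err) {
              frag[j] <- sample(setdiff(c("A", "C", "G", "T"), frag[j]), 1L)
            }
          }
        }
        pair_id <- pair_id + 1L
        qname <- sprintf("frag%08d", pair_id)
        left <- paste(frag[seq_len(read_length)], collapse = "")
        right <- paste(frag[(w - read_length + 1L):w], collapse = "")
        pos_l <- s; pos_r <- s + w - read_length
        if (is_top[fi]) {
          # original top: R1 forward at the left end (99), R2 reverse (147)
          csam[[fi]] <- c(
            paste(qname, 99L, cname, pos_l, 60L, cigar, "=", pos_r, w,
                  left, qual, sep = "\t"),
            paste(qname, 147L, cname, pos_r, 60L, cigar, "=", pos_l, -w,
                  right, qual, sep = "\t"))
          cf1[[fi]] <- c(paste0("@", qname, "/1"), left, "+", qual)
          cf2[[fi]] <- c(paste0("@", qname, "/2"),
                         paste(revcomp_chars(strsplit(right, "")[[1]]),
                               collapse = ""), "+", qual)
        } else {
          # original bottom: R1 reverse at the right end (83), R2 forward (163)
          csam[[fi]] <- c(
            paste(qname, 83L, cname, pos_r, 60L, cigar, "=", pos_l, -w,
                  right, qual, sep = "\t"),
            paste(qname, 163L, cname, pos_l, 60L, cigar, "=", pos_r, w,
                  left, qual, sep = "\t"))
          cf1[[fi]] <- c(paste0("@", qname, "/1"),
                         paste(revcomp_chars(strsplit(right, "")[[1]]),
                               collapse = ""), "+", qual)
          cf2[[fi]] <- c(paste0("@", qname, "/2"), left, "+", qual)
        }
      }
      sam[[ci]] <- unlist(csam); fq1[[ci]] <- unlist(cf1)
      fq2[[ci]] <- unlist(cf2)
    }
  })
  writeLines(c(header, unlist(sam)), sam_path)
  writeLines(unlist(fq1), fq1_path)
  writeLines(unlist(fq2), fq2_path)
  invisible(list(sam = sam_path, fastq1 = fq1_path, fastq2 = fq2_path,
                 expected = exp_path, n_pairs = pair_id, out_dir = out_dir))
}
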