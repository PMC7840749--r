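#' Read a BED file of labelled regions
#'
#' Column 4 (name) is used as the class label when present. Intervals on
#' disk are 0-based half-open per the BED standard.
#'
#' @param path BED path.
#' @return A `data.table` with `contig`, `start0`, `end0` (half-open),
#'   `class`, `strand`.
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  regions_to_dt(gr)
}

# Normalise region input (GRanges or data.table) to 0-based half-open.
regions_to_dt <- function(x) {
  if (inherits(x, "GRanges")) {
    nm <- if (!is.null(x$name)) as.character(x$name) else NA_character_
    st <- as.character(BiocGenerics::strand(x))
    return(data.table::data.table(
      contig = as.character(GenomicRanges::seqnames(x)),
      start0 = BiocGenerics::start(x) - 1L,
      end0 = BiocGenerics::end(x),
      class = nm,
      strand = ifelse(st == "*", NA_character_, st)))
  }
  dt <- data.table::as.data.table(x)
  stopifnot(all(c("contig", "start0", "end0") %in% names(dt)))
  if (!"class" %in% names(dt)) dt[, class := NA_character_]
  if (!"strand" %in% names(dt)) dt[, strand := NA_character_]
  if (any(dt$start0 >= dt$end0)) {
    stop("regions must satisfy start0 < end0", call. = FALSE)
  }
  dt[]
}

#' Pool modification signal into fixed-origin genomic bins
#'
#' Tiles each contig into half-open windows \[i*b, (i+1)*b) and reports the
#' pooled count ratio per non-empty bin.
#'
#' @param mods A mods table.
#' @param bin_size Bin width in bp (> 0).
#' @param convention `"mod"` (default) reports the converted fraction
#'   T/(C+T); `"retained"` reports the bisulfite-style retained fraction
#'   C/(C+T) for comparisons against deamination-based assays.
#' @return `data.table` with `contig`, `bin_start`, `bin_end`, `n_sites`,
#'   `n_mod`, `n_unmod`, `signal`.
#' @export
bin_signal <- function(mods, bin_size, convention = c("mod", "retained")) {
  stopifnot(bin_size > 0)
  convention <- match.arg(convention)
  dt <- data.table::as.data.table(mods)
  dt[, bin_start := (pos0 %/% as.integer(bin_size)) * as.integer(bin_size)]
  out <- dt[, .(n_sites = .N, n_mod = sum(n_mod), n_unmod = sum(n_unmod)),
            by = .(contig, bin_start)]
  out[, bin_end := bin_start + as.integer(bin_size)]
  out[, signal := ifelse(n_mod + n_unmod > 0,
                         n_mod / (n_mod + n_unmod), NA_real_)]
  if (convention == "retained") out[, signal := 1 - signal]
  data.table::setorder(out, contig, bin_start)
  out[, .(contig, bin_start, bin_end, n_sites, n_mod, n_unmod, signal)]
}

#' Pearson correlation of two mods tables at a minimum depth
#'
#' Correlates per-site signals over the intersection of sites with at least
#' `min_depth` informative reads in both tables.
#'
#' @param a,b Mods tables.
#' @param min_depth Minimum informative coverage in each table (default 10).
#' @return List with `r` (NA if fewer than two shared sites) and `n_sites`.
#' @export
pearson_at_depth <- function(a, b, min_depth = 10L) {
  da <- data.table::as.data.table(a)[, .(contig, pos0, strand,
                                         sa = signal,
                                         na = n_mod + n_unmod)]
  db <- data.table::as.data.table(b)[, .(contig, pos0, strand,
                                         sb = signal,
                                         nb = n_mod + n_unmod)]
  j <- merge(da, db, by = c("contig", "pos0", "strand"))
  j <- j[na >= min_depth & nb >= min_depth & !is.na(sa) & !is.na(sb)]
  if (nrow(j) < 2L) {
    return(list(r = NA_real_, n_sites = nrow(j)))
  }
  list(r = stats::cor(j$sa, j$sb, method = "pearson"), n_sites = nrow(j))
}

# Sites-in-regions overlap helper: returns, per class, the number of sites
# falling in any interval of the class (each site once per class) and the
# class footprint in bp (union of its intervals).
class_overlap <- function(sites, regions) {
  reg <- regions_to_dt(regions)
  classes <- unique(reg$class)
  pts <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos0 + 1L, sites$pos0 + 1L))
  res <- lapply(classes, function(cl) {
    r <- reg[class == cl]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      r$contig, IRanges::IRanges(r$start0 + 1L, r$end0)))
    data.table::data.table(
      class = cl,
      n_overlap = sum(IRanges::overlapsAny(pts, gr)),
      class_bp = sum(BiocGenerics::width(gr)))
  })
  data.table::rbindlist(res)
}

#' Enrichment of called sites in region classes against random CG background
#'
#' For each region class, compares the density of called sites (overlapping
#' sites per bp of the class footprint) with the density obtained from
#' `n_samplings` random draws of equally many sites from the background CG
#' universe (sampling without replacement). A site lying in several classes
#' counts once per class.
#'
#' @param sites `data.table` with `contig`, `pos0` (the called sites).
#' @param regions Labelled regions (`GRanges`, BED path via
#'   [read_regions()], or `data.table` with `contig`, `start0`, `end0`,
#'   `class`).
#' @param background `data.table` with `contig`, `pos0`: the universe of
#'   qualifying CG sites from which the observed set arose.
#' @param n_samplings Number of random draws (default 10).
#' @param seed Integer seed.
#' @return `data.table` with per class: `n_observed`, `class_bp`,
#'   `observed_density`, `random_mean`, `random_sd`, `ratio`
#'   (observed / mean random). The per-draw densities are kept in attribute
#'   `samplings`.
#' @export
enrichment <- function(sites, regions, background, n_samplings = 10L, seed) {
  sites <- data.table::as.data.table(sites)
  background <- data.table::as.data.table(background)
  if (nrow(background) < nrow(sites)) {
    stop("background universe smaller than the site set", call. = FALSE)
  }
  obs <- class_overlap(sites, regions)
  obs[, observed_density := n_overlap / class_bp]
  rnd <- withr::with_seed(seed, {
    vapply(seq_len(n_samplings), function(i) {
      draw <- background[sample.int(nrow(background), nrow(sites))]
      class_overlap(draw, regions)$n_overlap / obs$class_bp
    }, numeric(nrow(obs)))
  })
  rnd <- matrix(rnd, nrow = nrow(obs))
  obs[, random_mean := rowMeans(rnd)]
  obs[, random_sd := apply(rnd, 1L, stats::sd)]
  obs[, ratio := ifelse(random_mean > 0, observed_density / random_mean,
                        ifelse(observed_density > 0, Inf, 0))]
  out <- obs[, .(class, n_observed = n_overlap, class_bp,
                 observed_density, random_mean, random_sd, ratio)]
  data.table::setattr(out, "samplings", rnd)
  out[]
}

#' Partition sites into a single class by precedence
#'
#' First-match assignment for pie-chart style summaries: each site is
#' assigned to the first class of `precedence` whose intervals contain it;
#' sites matching none are labelled `"none"`.
#'
#' @param sites `data.table` with `contig`, `pos0`.
#' @param regions Labelled regions (see [enrichment()]).
#' @param precedence Character vector ordering the classes; defaults to
#'   their order of first appearance.
#' @return `data.table` with `class` and `n_sites`.
#' @export
site_class_partition <- function(sites, regions, precedence = NULL) {
  sites <- data.table::as.data.table(sites)
  reg <- regions_to_dt(regions)
  if (is.null(precedence)) precedence <- unique(reg$class)
  pts <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos0 + 1L, sites$pos0 + 1L))
  assigned <- rep("none", nrow(sites))
  free <- rep(TRUE, nrow(sites))
  for (cl in precedence) {
    r <- reg[class == cl]
    if (!nrow(r)) next
    gr <- GenomicRanges::GRanges(
      r$contig, IRanges::IRanges(r$start0 + 1L, r$end0))
    hit <- IRanges::overlapsAny(pts, gr) & free
    assigned[hit] <- cl
    free[hit] <- FALSE
  }
  data.table::data.table(class = assigned)[
    , .(n_sites = .N), by = class][order(-n_sites)]
}

#' Average signal profile around genomic centers
#'
#' Tiles the \[-flank, +flank) window around each center point into
#' `2*flank/bin` half-open bins of `bin` bp and reports, per bin, the mean of
#' per-site signals pooled across all centers. For centers on the `-`
#' strand the offset axis is flipped so profiles are orientation-aware.
#'
#' @param mods A mods table.
#' @param centers `data.table` with `contig`, `pos` (0-based point, e.g.
#'   peak centers) and optional `strand`; or a `GRanges`/regions table whose
#'   interval midpoints are used.
#' @param flank Flank size in bp on each side (default 3000).
#' @param bin Bin width in bp (default 100); must divide `flank`.
#' @return `data.table` with `bin` (index from 0), `offset_start` (bin left
#'   edge relative to the center), `n_sites`, `mean_signal`.
#' @export
metaplot <- function(mods, centers, flank = 3000L, bin = 100L) {
  stopifnot(flank %% bin == 0)
  flank <- as.integer(flank); bin <- as.integer(bin)
  dt <- data.table::as.data.table(mods)[!is.na(signal)]
  if (!is.data.frame(centers) || !"pos" %in% names(centers)) {
    ct <- regions_to_dt(centers)
    centers <- ct[, .(contig, pos = (start0 + end0) %/% 2L, strand)]
  }
  centers <- data.table::as.data.table(centers)
  if (!"strand" %in% names(centers)) centers[, strand := NA_character_]
  n_bins <- 2L * flank %/% bin
  win <- centers[, .(contig, cpos = pos, cstrand = strand,
                     start = pos - flank, end = pos + flank - 1L)]
  s <- dt[, .(contig, start = pos0, end = pos0, signal)]
  data.table::setkey(win, contig, start, end)
  hits <- data.table::foverlaps(s, win, type = "within", nomatch = NULL)
  if (nrow(hits) == 0L) {
    return(data.table::data.table(bin = seq_len(n_bins) - 1L,
                                  offset_start = seq(-flank, flank - bin, bin),
                                  n_sites = 0L, mean_signal = NA_real_))
  }
  off <- ifelse(!is.na(hits$cstrand) & hits$cstrand == "-",
                hits$cpos - hits$i.start, hits$i.start - hits$cpos)
  hits[, bin_idx := (off + flank) %/% bin]
  prof <- hits[bin_idx >= 0L & bin_idx < n_bins,
               .(n_sites = .N, mean_signal = mean(signal)), by = bin_idx]
  out <- data.table::data.table(bin = seq_len(n_bins) - 1L,
                                offset_start = seq(-flank, flank - bin, bin))
  out <- merge(out, prof, by.x = "bin", by.y = "bin_idx", all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[]
}

#' CpG-island coverage profiles of two datasets
#'
#' Bins each island body into `body_bins` equal windows and each flank into
#' `flank_bins` windows of `flank/flank_bins` bp, averages the informative
#' coverage (n_mod + n_unmod) per window, and rescales dataset `b` by the
#' ratio of overall coverage so profiles are comparable. Islands shorter
#' than `body_bins` bp are binned proportionally with a warning.
#'
#' @param a,b Mods tables.
#' @param islands Regions (`GRanges` or table with `contig`, `start0`,
#'   `end0`).
#' @param body_bins Number of body windows (default 10).
#' @param flank Flank size in bp (default 4000).
#' @param flank_bins Number of windows per flank (default 20).
#' @return `data.table` with `window` (1..flank_bins+body_bins+flank_bins,
#'   left flank first), `region` ("left_flank"/"body"/"right_flank"),
#'   `mean_cov_a`, `mean_cov_b` (normalised).
#' @export
island_coverage_profile <- function(a, b, islands, body_bins = 10L,
                                    flank = 4000L, flank_bins = 20L) {
  isl <- regions_to_dt(islands)
  if (!nrow(isl)) stop("no islands given", call. = FALSE)
  if (any(isl$end0 - isl$start0 < body_bins)) {
    warning("island(s) shorter than body_bins; binned proportionally")
  }
  fw <- flank / flank_bins
  da <- data.table::as.data.table(a)[, .(contig, pos0,
                                         cov = n_mod + n_unmod)]
  db <- data.table::as.data.table(b)[, .(contig, pos0,
                                         cov = n_mod + n_unmod)]
  scale_b <- sum(da$cov) / sum(db$cov)
  assign_windows <- function(d) {
    res <- lapply(seq_len(nrow(isl)), function(i) {
      s0 <- isl$start0[i]; e0 <- isl$end0[i]; len <- e0 - s0
      x <- d[contig == isl$contig[i] & pos0 >= s0 - flank &
               pos0 < e0 + flank]
      if (!nrow(x)) return(NULL)
      w <- integer(nrow(x))
      left <- x$pos0 < s0
      right <- x$pos0 >= e0
      body <- !left & !right
      w[left] <- as.integer((x$pos0[left] - (s0 - flank)) %/% fw) + 1L
      w[body] <- flank_bins +
        pmin(as.integer(((x$pos0[body] - s0) * body_bins) %/% len),
             body_bins - 1L) + 1L
      w[right] <- flank_bins + body_bins +
        as.integer((x$pos0[right] - e0) %/% fw) + 1L
      data.table::data.table(window = w, cov = x$cov)
    })
    data.table::rbindlist(c(
      list(data.table::data.table(window = integer(0), cov = numeric(0))),
      res))
  }
  wa <- assign_windows(da)
  wb <- assign_windows(db)
  n_win <- flank_bins + body_bins + flank_bins
  out <- data.table::data.table(window = seq_len(n_win))
  out[, region := c(rep("left_flank", flank_bins),
                    rep("body", body_bins),
                    rep("right_flank", flank_bins))]
  ma <- wa[, .(mean_cov_a = mean(cov)), by = window]
  mb <- wb[, .(mean_cov_b = mean(cov) * scale_b), by = window]
  out <- merge(out, ma, by = "window", all.x = TRUE)
  out <- merge(out, mb, by = "window", all.x = TRUE)
  data.table::setorder(out, window)
  out[]
}
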