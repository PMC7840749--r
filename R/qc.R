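#' Conversion-rate and false-positive report from spike-in controls
#'
#' Pools transition counts over all truth sites of each pure modification
#' state on the spike-in contigs and reports, per (spike-in, state), the
#' conversion rate n_mod/(n_mod+n_unmod). The false-positive rate is computed
#' identically over the truth-unmodified cytosines of the unmodified
#' spike-in. Pooling (sum counts, then divide) rather than averaging
#' per-site signals makes the estimate robust at low per-site coverage and
#' equals the coverage-weighted mean of per-site signals.
#'
#' @param mods A mods table from [call_mods()].
#' @param truth Methylome truth from [generate_methylome()].
#' @param spikeins Named character vector mapping spike-in contig names to
#'   kinds (as in `bk_reference$spikein`), or a `bk_reference`.
#' @return A `data.table` of class `conversion_report` with columns
#'   `spikein`, `kind`, `state`, `n_sites`, `n_mod`, `n_unmod`, `rate`, and
#'   attribute `false_positive_rate` (NA if no unmodified spike-in present).
#' @export
conversion_report <- function(mods, truth, spikeins) {
  if (inherits(spikeins, "bk_reference")) spikeins <- spikeins$spikein
  stopifnot(is.character(spikeins), !is.null(names(spikeins)))
  mods <- data.table::as.data.table(mods)
  truth <- data.table::as.data.table(truth)
  rows <- list()
  for (nm in names(spikeins)) {
    kind <- spikeins[[nm]]
    tr <- truth[contig == nm]
    if (!nrow(tr)) {
      warning("no truth sites for spike-in contig '", nm, "'; skipped")
      next
    }
    for (state in c("mC", "hmC", "fC", "caC", "C")) {
      if (state == "C") {
        # false-positive sites: fully unmodified cytosines of unmod_2kb
        if (kind != "unmod_2kb") next
        sel <- tr[mC + hmC + fC + caC == 0]
      } else {
        sel <- tr[get(state) == 1]
      }
      if (!nrow(sel)) next
      mm <- merge(sel[, .(contig, pos0, strand)], mods,
                  by = c("contig", "pos0", "strand"))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        spikein = nm, kind = kind, state = state,
        n_sites = nrow(mm),
        n_mod = sum(mm$n_mod), n_unmod = sum(mm$n_unmod),
        rate = if (sum(mm$n_mod + mm$n_unmod) > 0)
          sum(mm$n_mod) / sum(mm$n_mod + mm$n_unmod) else NA_real_)
    }
  }
  rep <- data.table::rbindlist(rows)
  fpr <- rep[state == "C"]$rate
  data.table::setattr(rep, "false_positive_rate",
                      if (length(fpr)) fpr[1L] else NA_real_)
  data.table::setattr(rep, "class",
                      c("conversion_report", class(rep)))
  rep[]
}

#' Write a conversion report as JSON
#'
#' @param report A [conversion_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conversion_report <- function(report, path) {
  obj <- list(
    false_positive_rate = attr(report, "false_positive_rate"),
    rates = lapply(seq_len(nrow(report)), function(i) as.list(report[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a spike-in control library and run the full QC pipeline
#'
#' Convenience wrapper: builds a reference holding the standard spike-in set,
#' assigns their known truth, simulates converted reads under the requested
#' chemistry, calls modifications and returns the conversion report together
#' with the intermediate objects.
#'
#' @param chemistry Chemistry name or a [chemistry_profile()].
#' @param depth Fold-coverage for every spike-in contig.
#' @param depth_by_kind Optional named vector of per-kind depth multipliers.
#' @param seed Integer seed.
#' @param spikeins List of [spikein_spec()]; defaults to [default_spikeins()].
#' @param read_length,insert_mean,insert_sd Passed to [simulate_reads()].
#' @return List with `report`, `mods`, `truth`, `reference`, `profile`,
#'   `sim` (simulation file paths).
#' @export
spikein_qc_run <- function(chemistry, depth = 50, depth_by_kind = NULL,
                           seed, spikeins = default_spikeins(),
                           read_length = 80L, insert_mean = 200,
                           insert_sd = 30) {
  profile <- if (inherits(chemistry, "chemistry_profile")) chemistry
             else default_profile(chemistry)
  ref <- generate_reference(0L, 0L, 0.5, spikeins = spikeins, seed = seed)
  truth <- generate_methylome(ref, methylome_config(), seed = seed + 1L)
  dbc <- NULL
  if (!is.null(depth_by_kind)) {
    dbc <- stats::setNames(unname(depth_by_kind),
                           paste0("spike_", names(depth_by_kind)))
  }
  sim <- simulate_reads(ref, truth, profile, depth = depth,
                        read_length = read_length,
                        insert_mean = insert_mean, insert_sd = insert_sd,
                        seed = seed + 2L, depth_by_contig = dbc)
  mods <- call_mods(sim$sam, ref)
  rep <- conversion_report(mods, truth, ref)
  list(report = rep, mods = mods, truth = truth, reference = ref,
       profile = profile, sim = sim)
}
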