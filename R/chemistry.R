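#' Cytosine modification states
#'
#' The five cytosine states handled by the borane-reduction chemistries:
#' unmodified cytosine and its four epigenetic derivatives
#' (5-methyl, 5-hydroxymethyl, 5-formyl, 5-carboxyl). The ordering is fixed
#' so that serialisation is deterministic.
#'
#' @return Character vector `c("C","mC","hmC","fC","caC")`.
#' @export
mod_states <- function() c("C", "mC", "hmC", "fC", "caC")

#' Canonical chemistry names
#'
#' @return Character vector of the five supported chemistries.
#' @export
chemistry_names <- function() c("TAPS", "TAPSB", "CAPS", "PS", "PSc")

# Accepts common spellings (Greek beta, hyphenated PS-c) and returns the
# canonical ASCII identifier.
canonical_chemistry <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(gsub("[^A-Za-z]", "", gsub("β", "B", name)))
  canon <- c(
    TAPS = "TAPS",
    TAPSB = "TAPSB", TAPSBETA = "TAPSB",
    CAPS = "CAPS",
    PS = "PS",
    PSC = "PSc"
  )
  if (!key %in% names(canon)) {
    stop("Unknown chemistry '", name, "'. Valid options: ",
         paste(chemistry_names(), collapse = ", "),
         " (aliases TAPSbeta/TAPSβ and PS-c are accepted).",
         call. = FALSE)
  }
  unname(canon[[key]])
}

#' Construct a chemistry profile
#'
#' A chemistry profile gives, for each cytosine state, the probability that a
#' cytosine of that state is read out as T (the borane-reduction
#' C-to-T conversion probability), plus an optional uniform sequencing
#' substitution error applied on top.
#'
#' @param name Chemistry name (one of [chemistry_names()], aliases accepted).
#' @param conv Named numeric vector of conversion probabilities; names must be
#'   exactly the five states of [mod_states()], values in \[0,1\].
#' @param seq_error Probability of a uniform random substitution, in \[0,1\].
#' @return An object of class `chemistry_profile`.
#' @seealso [default_profile()], [readout_prob()]
#' @export
chemistry_profile <- function(name, conv, seq_error = 0) {
  name <- canonical_chemistry(name)
  states <- mod_states()
  if (!is.numeric(conv) || is.null(names(conv)) ||
      !setequal(names(conv), states)) {
    stop("'conv' must be a numeric vector named by all five states: ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  conv <- conv[states]
  if (anyNA(conv) || any(conv < 0 | conv > 1)) {
    stop("conversion probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(seq_error) || length(seq_error) != 1L ||
      is.na(seq_error) || seq_error < 0 || seq_error > 1) {
    stop("'seq_error' must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, conv = conv, seq_error = as.numeric(seq_error)),
    class = "chemistry_profile"
  )
}

# Which states each chemistry reads as T (its "bold" transitions), and the
# false-positive floor used when calling against background.
.assay_measured <- list(
  TAPS  = c("mC", "hmC", "fC", "caC"),
  TAPSB = c("mC", "fC", "caC"),
  CAPS  = c("hmC", "fC", "caC"),
  PS    = c("fC", "caC"),
  PSc   = "caC"
)

# Measured conversion/false-positive rates from the spike-in controls of the
# five assays; gaps (states the assays do not act on, or that were not
# quantified) are filled with the nearest mechanistically-equivalent measured
# rate -- see the methods vignette.
.default_conv <- list(
  TAPS  = c(C = 0.0023, mC = 0.965, hmC = 0.891, fC = 0.95,  caC = 0.95),
  TAPSB = c(C = 0.0024, mC = 0.976, hmC = 0.019, fC = 0.849, caC = 0.944),
  CAPS  = c(C = 0.0072, mC = 0.0072, hmC = 0.831, fC = 0.768, caC = 0.938),
  PS    = c(C = 0.0027, mC = 0.0027, hmC = 0.0027, fC = 0.768, caC = 0.938),
  PSc   = c(C = 0.0022, mC = 0.0022, hmC = 0.0022, fC = 0.152, caC = 0.953)
)

#' Default chemistry profile with measured spike-in rates
#'
#' Returns the per-state C-to-T readout probabilities measured on spike-in
#' controls for the requested chemistry. States a chemistry does not act on
#' are set to its false-positive rate; the TAPS 5fC/5caC rates, which borane
#' reduction converts but which were not separately quantified for TAPS, are
#' set to 0.95. `seq_error` defaults to 0 so that simulated chemistry is
#' exactly the conversion model.
#'
#' @inheritParams chemistry_profile
#' @return A [chemistry_profile()].
#' @examples
#' default_profile("TAPSB")$conv[["mC"]]   # 0.976
#' default_profile("CAPS")$conv[["C"]]     # 0.0072
#' @export
default_profile <- function(name) {
  name <- canonical_chemistry(name)
  chemistry_profile(name, .default_conv[[name]], seq_error = 0)
}

#' Assay design: which states a chemistry reads as modified
#'
#' @inheritParams chemistry_profile
#' @return An object of class `assay_design` with elements `chemistry`,
#'   `measured_states` and `background_rate` (the chemistry's false-positive
#'   rate, used as the binomial background when calling).
#' @export
assay_design <- function(name) {
  name <- canonical_chemistry(name)
  structure(
    list(
      chemistry = name,
      measured_states = .assay_measured[[name]],
      background_rate = .default_conv[[name]][["C"]]
    ),
    class = "assay_design"
  )
}

#' Probability that a cytosine of a given state is reported as T
#'
#' Composes the conversion probability with the uniform substitution error:
#' with error rate e, a converted base stays T unless hit by an error away
#' from T, and an unconverted C can still be read as T by one of the three
#' equally likely substitutions, giving `conv*(1-e) + e/3`.
#'
#' @param profile A [chemistry_profile()].
#' @param state One of [mod_states()].
#' @return Probability in \[0,1\].
#' @export
readout_prob <- function(profile, state) {
  stopifnot(inherits(profile, "chemistry_profile"))
  if (!all(state %in% mod_states())) {
    stop("unknown state; must be one of ", paste(mod_states(), collapse = ", "),
         call. = FALSE)
  }
  p <- unname(profile$conv[state])
  e <- profile$seq_error
  if (e > 0) p <- p * (1 - e) + e / 3
  p
}

#' @export
print.chemistry_profile <- function(x, ...) {
  cat("<chemistry_profile> ", x$name, "\n", sep = "")
  cat("  seq_error: ", format(x$seq_error), "\n", sep = "")
  for (s in mod_states()) {
    cat(sprintf("  conv[%-3s] = %.4f\n", s, x$conv[[s]]))
  }
  invisible(x)
}

#' Write / read a chemistry profile as YAML
#'
#' Round-trips bit-exactly: probabilities are serialised at full double
#' precision.
#'
#' @param profile A [chemistry_profile()].
#' @param path File path.
#' @return `write_profile_yaml` returns `path` invisibly; `read_profile_yaml`
#'   returns a [chemistry_profile()].
#' @export
write_profile_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "chemistry_profile"))
  obj <- list(
    name = profile$name,
    conv = lapply(as.list(profile$conv), function(v) sprintf("%.17g", v)),
    seq_error = sprintf("%.17g", profile$seq_error)
  )
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' @rdname write_profile_yaml
#' @export
read_profile_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  conv <- vapply(obj$conv, function(v) as.numeric(v), numeric(1))
  chemistry_profile(obj$name, conv[mod_states()],
                    seq_error = as.numeric(obj$seq_error))
}
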