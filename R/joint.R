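#' One-sided binomial test for modification above background
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, p0): the p-value for
#' observing k or more converted reads out of n at a site whose true
#' conversion probability is the assay's false-positive rate p0.
#'
#' @param k Modified-read count(s), 0 <= k <= n.
#' @param n Coverage(s), >= 1.
#' @param p0 Background (false-positive) probability in (0, 1), e.g. 0.0072
#'   for the 5hmC chemistry.
#' @return p-value(s) in \[0, 1\]; k = 0 gives exactly 1.
#' @export
binomial_mod_test <- function(k, n, p0) {
  stopifnot(length(p0) == 1L, p0 > 0, p0 < 1, all(n >= 1))
  if (any(k > n)) stop("k must not exceed n", call. = FALSE)
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with monotone enforcement; input order preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Call significant 5hmC sites from a 5hmC-reading chemistry
#'
#' Tests every site with at least `min_cov` informative reads
#' (n_mod + n_unmod) against the assay's false-positive rate with
#' [binomial_mod_test()], adjusts across exactly the tested set with
#' [bh_adjust()], and calls sites with q-value below `alpha`.
#'
#' @param mods A mods table (typically from the 5hmC-specific chemistry).
#' @param p0 Background probability; default the 5hmC chemistry
#'   false-positive rate 0.0072.
#' @param min_cov Minimum informative coverage (default 5).
#' @param alpha FDR threshold (default 0.05).
#' @return `data.table` with `contig`, `pos0`, `strand`, `context`, `k`,
#'   `n`, `p_value`, `q_value`, `called`.
#' @export
call_hmc <- function(mods, p0 = 0.0072, min_cov = 5L, alpha = 0.05) {
  stopifnot(p0 > 0, p0 < 1)
  dt <- data.table::as.data.table(mods)
  dt[, n_inf := n_mod + n_unmod]
  tested <- dt[n_inf >= min_cov]
  out <- tested[, .(contig, pos0, strand, context, k = n_mod, n = n_inf)]
  out[, p_value := binomial_mod_test(k, n, p0)]
  out[, q_value := bh_adjust(p_value)]
  out[, called := q_value < alpha]
  out[]
}

#' Assay observation at one site
#'
#' @param design An [assay_design()] or chemistry name.
#' @param k Modified-read count.
#' @param n Coverage.
#' @return An object of class `assay_observation`.
#' @export
assay_observation <- function(design, k, n) {
  if (!inherits(design, "assay_design")) design <- assay_design(design)
  stopifnot(k >= 0, k <= n, n >= 1)
  structure(list(design = design, k = as.numeric(k), n = as.numeric(n)),
            class = "assay_observation")
}

# Measured states restricted to the estimable pair {mC, hmC}; 5fC/5caC are
# fixed at 0 in the likelihood (negligible genomic abundance).
measured_mh <- function(design) {
  intersect(design$measured_states, c("mC", "hmC"))
}

new_joint_estimate <- function(m, h, conflict, n_conflicts) {
  structure(list(m_hat = m, h_hat = h, u_hat = 1 - m - h,
                 conflict = conflict, n_conflicts = n_conflicts),
            class = "joint_estimate")
}

#' Closed-form constrained MLE of (unmodified, 5mC, 5hmC) from two assays
#'
#' Maximises the product of the two binomial likelihoods over the simplex
#' \{u, m, h >= 0, u + m + h = 1\}, where each assay's success probability is
#' the sum of levels over the states it reads as modified (restricted to
#' \{mC, hmC\}). Supported design pairs: nested (one assay reads mC+hmC, the
#' other a single state) and disjoint (one reads mC, the other hmC). When
#' the unconstrained per-assay proportions leave the simplex the estimate is
#' the boundary solution and the conflict flag is set.
#'
#' @param obs1,obs2 [assay_observation()] objects.
#' @return A `joint_estimate`: `m_hat`, `h_hat`, `u_hat`, `conflict`,
#'   `n_conflicts`.
#' @export
mle_two_assay <- function(obs1, obs2) {
  stopifnot(inherits(obs1, "assay_observation"),
            inherits(obs2, "assay_observation"))
  s1 <- measured_mh(obs1$design); s2 <- measured_mh(obs2$design)
  p1 <- obs1$k / obs1$n; p2 <- obs2$k / obs2$n
  both <- c("mC", "hmC")
  if (setequal(s1, both) || setequal(s2, both)) {
    # nested: put the superset assay first
    if (!setequal(s1, both)) {
      tmp <- obs1; obs1 <- obs2; obs2 <- tmp
      tmp <- p1; p1 <- p2; p2 <- tmp
      s2 <- s1
    }
    if (length(s2) != 1L) {
      stop("nested designs require the second assay to read a single state",
           call. = FALSE)
    }
    sub_state <- s2
    if (p1 >= p2) {
      lev <- c(mC = 0, hmC = 0)
      lev[sub_state] <- p2
      lev[setdiff(both, sub_state)] <- p1 - p2
      new_joint_estimate(lev[["mC"]], lev[["hmC"]], FALSE, 0L)
    } else {
      pool <- (obs1$k + obs2$k) / (obs1$n + obs2$n)
      lev <- c(mC = 0, hmC = 0)
      lev[sub_state] <- pool
      new_joint_estimate(lev[["mC"]], lev[["hmC"]], TRUE, 1L)
    }
  } else if (length(s1) == 1L && length(s2) == 1L && !setequal(s1, s2)) {
    # disjoint: one assay per state
    if (s1 == "hmC") {
      tmp <- obs1; obs1 <- obs2; obs2 <- tmp
      tmp <- p1; p1 <- p2; p2 <- tmp
    }
    if (p1 + p2 <= 1) {
      new_joint_estimate(p1, p2, FALSE, 0L)
    } else {
      m <- (obs1$k + obs2$n - obs2$k) / (obs1$n + obs2$n)
      new_joint_estimate(m, 1 - m, TRUE, 1L)
    }
  } else {
    stop("incompatible designs: need nested (mC+hmC with mC or hmC) or ",
         "disjoint (mC with hmC) measured sets", call. = FALSE)
  }
}

#' Vectorised two-assay joint estimation over matched mods tables
#'
#' Joins two mods tables on (contig, pos0, strand), keeps sites with at
#' least `min_cov` informative reads in both, and applies the
#' [mle_two_assay()] closed forms site-wise.
#'
#' @param mods1,mods2 Mods tables.
#' @param design1,design2 [assay_design()]s or chemistry names for the two
#'   tables.
#' @param min_cov Minimum informative coverage in each assay (default 5).
#' @return `data.table` with `contig`, `pos0`, `strand`, `k1`, `n1`, `k2`,
#'   `n2`, `m_hat`, `h_hat`, `u_hat`, `conflict`.
#' @export
joint_estimate_table <- function(mods1, mods2, design1, design2,
                                 min_cov = 5L) {
  if (!inherits(design1, "assay_design")) design1 <- assay_design(design1)
  if (!inherits(design2, "assay_design")) design2 <- assay_design(design2)
  s1 <- measured_mh(design1); s2 <- measured_mh(design2)
  both <- c("mC", "hmC")
  a <- data.table::as.data.table(mods1)[, .(contig, pos0, strand,
                                            k1 = n_mod,
                                            n1 = n_mod + n_unmod)]
  b <- data.table::as.data.table(mods2)[, .(contig, pos0, strand,
                                            k2 = n_mod,
                                            n2 = n_mod + n_unmod)]
  j <- merge(a, b, by = c("contig", "pos0", "strand"))
  j <- j[n1 >= min_cov & n2 >= min_cov]
  p1 <- j$k1 / j$n1; p2 <- j$k2 / j$n2
  if (setequal(s1, both) && length(s2) == 1L) {
    conflict <- p1 < p2
    sub <- ifelse(conflict, (j$k1 + j$k2) / (j$n1 + j$n2), p2)
    other <- ifelse(conflict, 0, p1 - p2)
    if (s2 == "mC") { m <- sub; h <- other } else { m <- other; h <- sub }
  } else if (setequal(s2, both) && length(s1) == 1L) {
    return(joint_estimate_table(mods2, mods1, design2, design1, min_cov))
  } else if (length(s1) == 1L && length(s2) == 1L && !setequal(s1, s2)) {
    if (s1 == "hmC") {
      pm <- p2; ph <- p1; km <- j$k2; nm <- j$n2; kh <- j$k1; nh <- j$n1
    } else {
      pm <- p1; ph <- p2; km <- j$k1; nm <- j$n1; kh <- j$k2; nh <- j$n2
    }
    conflict <- pm + ph > 1
    m <- ifelse(conflict, (km + nh - kh) / (nm + nh), pm)
    h <- ifelse(conflict, 1 - m, ph)
  } else {
    stop("incompatible designs", call. = FALSE)
  }
  j[, `:=`(m_hat = m, h_hat = h, u_hat = 1 - m - h, conflict = conflict)]
  j[]
}

#' Iterative constrained MLE from two or more assays
#'
#' EM-style ascent on the joint binomial likelihood over the simplex: each
#' read's latent state is one of \{unmodified, 5mC, 5hmC\}; an observed
#' conversion restricts it to the assay's measured set, a retained base to
#' the complement; expected state counts are renormalised each iteration.
#' Agrees with the [mle_two_assay()] closed forms for two assays.
#'
#' @param obs List of [assay_observation()]s whose designs jointly identify
#'   (m, h).
#' @param tol Convergence tolerance on the parameter change (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return A `joint_estimate`; `n_conflicts` counts the violated pairwise
#'   simplex constraints among the unconstrained per-assay proportions.
#' @export
mle_multi_assay <- function(obs, tol = 1e-8, max_iter = 10000L) {
  stopifnot(is.list(obs), length(obs) >= 2L,
            all(vapply(obs, inherits, logical(1), "assay_observation")))
  sets <- lapply(obs, function(o) measured_mh(o$design))
  # identifiability: indicator rows over (m, h) must span rank 2
  ind <- do.call(rbind, lapply(sets, function(s)
    c(m = as.numeric("mC" %in% s), h = as.numeric("hmC" %in% s))))
  if (qr(ind)$rank < 2L) {
    stop("non-identifiable design set: the assays cannot separate 5mC ",
         "from 5hmC", call. = FALSE)
  }
  k <- vapply(obs, `[[`, numeric(1), "k")
  n <- vapply(obs, `[[`, numeric(1), "n")
  states <- c("u", "mC", "hmC")
  succ_set <- lapply(sets, function(s) match(s, states))
  fail_set <- lapply(succ_set, function(s) setdiff(1:3, s))
  lev <- c(1, 1, 1) / 3
  for (it in seq_len(max_iter)) {
    cnt <- numeric(3)
    for (i in seq_along(obs)) {
      ws <- lev[succ_set[[i]]]
      ws <- if (sum(ws) > 0) ws / sum(ws) else
        rep(1 / length(ws), length(ws))
      wf <- lev[fail_set[[i]]]
      wf <- if (sum(wf) > 0) wf / sum(wf) else
        rep(1 / length(wf), length(wf))
      cnt[succ_set[[i]]] <- cnt[succ_set[[i]]] + k[i] * ws
      cnt[fail_set[[i]]] <- cnt[fail_set[[i]]] + (n[i] - k[i]) * wf
    }
    new <- cnt / sum(cnt)
    if (max(abs(new - lev)) < tol) { lev <- new; break }
    lev <- new
  }
  # conflict accounting on the unconstrained proportions
  p <- k / n
  n_conf <- 0L
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j) next
      if (length(sets[[i]]) > length(sets[[j]]) &&
          all(sets[[j]] %in% sets[[i]]) && p[i] < p[j]) {
        n_conf <- n_conf + 1L
      }
      if (i < j && length(intersect(sets[[i]], sets[[j]])) == 0L &&
          p[i] + p[j] > 1) {
        n_conf <- n_conf + 1L
      }
    }
  }
  new_joint_estimate(lev[2L], lev[3L], n_conf > 0L, n_conf)
}

#' Naive subtraction estimator of 5hmC
#'
#' The two-assay subtraction (mC+hmC signal minus mC signal). Sampling noise
#' in either assay can push it negative; negatives are preserved and
#' flagged, illustrating why the direct 5hmC readout is preferred.
#'
#' @param taps_signal Signal(s) from the mC+hmC-reading assay, in \[0,1\].
#' @param tapsb_signal Signal(s) from the mC-only assay, in \[0,1\].
#' @return `data.table` with `h_naive` and logical `negative`.
#' @export
subtract_estimate <- function(taps_signal, tapsb_signal) {
  stopifnot(all(taps_signal >= 0 & taps_signal <= 1),
            all(tapsb_signal >= 0 & tapsb_signal <= 1))
  h <- taps_signal - tapsb_signal
  data.table::data.table(h_naive = h, negative = h < 0)
}

#' Simulate site-level assay observations through a chemistry profile
#'
#' Draws, for each truth site, a binomial modified-read count at the site's
#' marginal per-read conversion probability under the profile (the exact
#' site-level collapse of the read simulator).
#'
#' @param truth Methylome truth table.
#' @param profile A [chemistry_profile()] or chemistry name.
#' @param depth Coverage per site (constant).
#' @param seed Integer seed.
#' @param context Restrict to a context (default `"CpG"`; `NULL` for all).
#' @return `data.table` with `contig`, `pos0`, `strand`, `context`, `n_mod`,
#'   `n_unmod` (a minimal mods table).
#' @export
simulate_observations <- function(truth, profile, depth, seed,
                                  context = "CpG") {
  if (!inherits(profile, "chemistry_profile")) {
    profile <- default_profile(profile)
  }
  tr <- data.table::as.data.table(truth)
  if (!is.null(context)) {
    ctx <- context
    tr <- tr[!is.na(tr$context) & tr$context == ctx]
  }
  theta <- site_t_prob(tr, profile)
  withr::with_seed(seed, {
    k <- stats::rbinom(nrow(tr), depth, theta)
  })
  out <- tr[, .(contig, pos0, strand, context)]
  out[, `:=`(n_mod = k, n_unmod = depth - k)]
  out[]
}
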