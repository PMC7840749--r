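mk_mods <- function(contig, pos0, n_mod, n_unmod, strand = "+") {
  dt <- data.table::data.table(
    contig = contig, pos0 = as.integer(pos0), strand = strand,
    context = "CpG", context5 = "CGA",
    n_mod = as.integer(n_mod), n_unmod = as.integer(n_unmod), n_other = 0L)
  dt[, coverage := n_mod + n_unmod]
  dt[, signal := ifelse(coverage > 0, n_mod / coverage, NA_real_)]
  dt[]
}

test_that("binned signal pools counts over half-open fixed-origin tiles", {
  one <- bin_signal(mk_mods("c", 123, 4, 6), bin_size = 10000)
  expect_equal(one$signal, 0.4)
  expect_identical(one$bin_start, 0L)

  two <- bin_signal(mk_mods("c", c(5, 9), c(1, 3), c(9, 7)), bin_size = 10000)
  expect_identical(nrow(two), 1L)
  expect_equal(two$signal, 4 / 20)

  # a record exactly at a bin boundary belongs to the right-hand tile
  edge <- bin_signal(mk_mods("c", 10000, 2, 2), bin_size = 10000)
  expect_identical(edge$bin_start, 10000L)
  expect_identical(edge$bin_end, 20000L)

  # pooled counts conserve totals
  set.seed(60)
  mods <- mk_mods("c", sample(0:50000, 200), sample(0:9, 200, TRUE),
                  sample(0:9, 200, TRUE))
  binned <- bin_signal(mods, 1000)
  expect_identical(sum(binned$n_mod), sum(mods$n_mod))
  expect_identical(sum(binned$n_unmod), sum(mods$n_unmod))

  # retained convention mirrors the converted fraction
  expect_equal(bin_signal(mk_mods("c", 1, 3, 7), 100,
                          convention = "retained")$signal, 0.7)
})

test_that("depth-filtered Pearson correlation matches the textbook formula", {
  a <- mk_mods("c", 1:5, c(1, 5, 9, 3, 7), 10 - c(1, 5, 9, 3, 7))
  self <- pearson_at_depth(a, a, min_depth = 10)
  expect_equal(self$r, 1)
  expect_identical(self$n_sites, 5L)

  b <- mk_mods("c", 1:3, c(9, 5, 1), c(1, 5, 9))
  anti <- pearson_at_depth(mk_mods("c", 1:3, c(1, 5, 9), c(9, 5, 1)), b,
                           min_depth = 10)
  expect_equal(anti$r, -1)

  x <- c(0.1, 0.5, 0.9, 0.3, 0.7); y <- c(0.2, 0.4, 0.8, 0.1, 0.9)
  bx <- mk_mods("c", 1:5, round(x * 10), 10 - round(x * 10))
  by <- mk_mods("c", 1:5, round(y * 10), 10 - round(y * 10))
  got <- pearson_at_depth(bx, by, min_depth = 10)$r
  sx <- bx$signal; sy <- by$signal
  hand <- sum((sx - mean(sx)) * (sy - mean(sy))) /
    sqrt(sum((sx - mean(sx))^2) * sum((sy - mean(sy))^2))
  expect_equal(got, hand, tolerance = 1e-12)

  # depth filter respects the intersection; <2 shared sites is undefined
  shallow <- mk_mods("c", 1:5, c(1, 5, 9, 3, 7), 0)  # coverage 1-9
  und <- pearson_at_depth(a, shallow, min_depth = 10)
  expect_true(is.na(und$r))
})

test_that("enrichment matches exhaustive enumeration on a toy genome", {
  # 1-kb genome, one 100-bp class holding 5 of 20 background CGs,
  # 4 called sites of which 2 fall in the class
  background <- data.table::data.table(
    contig = "toy", pos0 = as.integer(c(
      seq(100, 180, by = 20),          # 5 CGs inside [100, 200)
      seq(300, 990, length.out = 15))) # 15 CGs outside
  )
  regions <- data.table::data.table(contig = "toy", start0 = 100L,
                                    end0 = 200L, class = "enhancer")
  sites <- background[c(1, 3, 8, 15)]  # 2 inside the class
  res <- enrichment(sites, regions, background, n_samplings = 10, seed = 1)
  expect_equal(res$observed_density, 2 / 100)

  # exhaustive mean over all C(20, 4) draws: E[#in-class] via hypergeometric
  draws <- utils::combn(20, 4)
  in_class <- colSums(draws <= 5)
  exact_mean <- mean(in_class) / 100
  # sampling mean is unbiased; with 10 draws allow 3 SD of the mean
  sd_one <- stats::sd(in_class / 100)
  expect_lt(abs(res$random_mean - exact_mean), 3 * sd_one / sqrt(10))

  # a class with no observed overlap has ratio 0
  cold <- data.table::data.table(contig = "toy", start0 = 900L, end0 = 950L,
                                 class = "desert")
  res0 <- enrichment(sites, cold, background, n_samplings = 10, seed = 1)
  expect_equal(res0$ratio, 0)

  # fixed seed reproduces; the site universe itself is unenriched
  again <- enrichment(sites, regions, background, n_samplings = 10, seed = 1)
  expect_identical(res$random_mean, again$random_mean)
  self <- enrichment(background, regions, background, n_samplings = 3,
                     seed = 2)
  expect_equal(self$ratio, 1)

  expect_error(enrichment(background, regions, sites), "smaller")
})

test_that("first-match partition respects class precedence", {
  background <- data.table::data.table(contig = "toy",
                                       pos0 = as.integer(seq(0, 90, 10)))
  regions <- data.table::data.table(
    contig = "toy", start0 = c(0L, 0L), end0 = c(50L, 30L),
    class = c("promoter", "enhancer"))
  part <- site_class_partition(background, regions,
                               precedence = c("enhancer", "promoter"))
  expect_identical(part[class == "enhancer"]$n_sites, 3L)  # 0,10,20
  expect_identical(part[class == "promoter"]$n_sites, 2L)  # 30,40
  expect_identical(part[class == "none"]$n_sites, 5L)
})

test_that("metaplot bins offsets around centers with half-open arithmetic", {
  centers <- data.table::data.table(contig = "c", pos = 5000L)
  flat <- mk_mods("c", seq(2000, 8000, 50), 3, 7)
  prof <- metaplot(flat, centers, flank = 3000, bin = 100)
  expect_identical(nrow(prof), 60L)
  expect_true(all(abs(prof[n_sites > 0]$mean_signal - 0.3) < 1e-12))

  # hand-placed sites at offsets -150, -50, +50 -> bins 28, 29, 30
  three <- mk_mods("c", c(4850, 4950, 5050), c(2, 4, 6), c(8, 6, 4))
  p3 <- metaplot(three, centers, flank = 3000, bin = 100)
  expect_identical(p3[n_sites > 0]$bin, c(28L, 29L, 30L))
  expect_equal(p3[bin == 28]$mean_signal, 0.2)

  # signal only at the center elevates the central bin alone
  spike <- rbind(mk_mods("c", 5000, 10, 0), mk_mods("c", 3500, 0, 10))
  ps <- metaplot(spike, centers, flank = 3000, bin = 100)
  expect_equal(ps[bin == 30]$mean_signal, 1)
  expect_equal(ps[bin == 15]$mean_signal, 0)

  # strand flip mirrors the profile
  minus <- data.table::data.table(contig = "c", pos = 5000L, strand = "-")
  pm <- metaplot(three, minus, flank = 3000, bin = 100)
  expect_identical(pm[n_sites > 0]$bin, c(29L, 30L, 31L))
  expect_equal(pm[bin == 31]$mean_signal, 0.2)
})

test_that("island profiles tile bodies evenly and normalise coverage scale", {
  islands <- data.table::data.table(contig = "c", start0 = 10000L,
                                    end0 = 11000L)
  sites <- seq(6000, 15000, 10)
  a <- mk_mods("c", sites, 5, 5)
  prof_aa <- island_coverage_profile(a, a, islands)
  expect_identical(nrow(prof_aa), 50L)
  expect_equal(prof_aa$mean_cov_a, prof_aa$mean_cov_b)

  # doubling every count leaves the normalised profile unchanged
  b <- mk_mods("c", sites, 10, 10)
  prof_ab <- island_coverage_profile(a, b, islands)
  expect_equal(prof_ab$mean_cov_a, prof_ab$mean_cov_b)

  # a 1000-bp body splits into ten 100-bp tiles: a site at body offset 250
  # lands in body window 3 (window index 20 + 3)
  one <- mk_mods("c", 10250, 1, 1)
  pr <- island_coverage_profile(one, one, islands)
  expect_identical(pr[!is.na(mean_cov_a)]$window, 23L)
  expect_identical(pr[window == 23L]$region, "body")

  # flank windows are 200 bp: a site 4000 bp left of the island start is in
  # window 1; one at start-1 in window 20; island start itself in window 21
  edge <- mk_mods("c", c(6000, 9999, 10000), 1, 1)
  pe <- island_coverage_profile(edge, edge, islands)
  expect_identical(pe[!is.na(mean_cov_a)]$window, c(1L, 20L, 21L))

  expect_warning(
    island_coverage_profile(one, one,
                            data.table::data.table(contig = "c",
                                                   start0 = 0L, end0 = 5L)),
    "proportionally")
})
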