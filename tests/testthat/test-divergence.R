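test_that("intraspecific distances of japonica ITS2 match the derived counts", {
  d <- intra_distances(its2_dm(), JAPONICA)
  expect_length(d, 496L)            # choose(32, 2)
  expect_identical(sum(d > 0), 112L)  # 4 x 28 cross-haplotype pairs
  expect_equal(round(mean(d), 4), 0.0010)
  # closed-form check: mean = 112 * d1 / 496 with d1 = one transition in 228
  d1 <- k2p_from_counts(1 / 228, 0)
  expect_equal(mean(d), 112 * d1 / 496)

  expect_error(intra_distances(its2_dm(), "missing sp"), "absent")
  one <- toy_panel(c("s1", "s1", "s2"), c("h1", "h1", "h2"),
                   c("ACGTACGT", "ACGTACGT", "ACTTACGT"), c(1L, 1L, 1L))
  dm <- distance_matrix(build_msa(one), species_labels(one))
  expect_error(intra_distances(dm, "s2"), "single record")
})

test_that("interspecific distances have the right cardinality and bounds", {
  d <- inter_distances(its2_dm(), JAPONICA)
  expect_length(d, 32L * 21L)  # 672 focal-vs-other pairs
  expect_true(all(d >= min(d)))
  g <- inter_distances(its2_dm(), mode = "global")
  expect_length(g, choose(53L, 2L) - 496L - choose(5L, 2L) * 3L -
                  choose(2L, 2L) * 0L - 1L * 3L)
  expect_error(inter_distances(its2_dm(), "missing sp"), "absent")

  same <- toy_panel(c("s1", "s2"), c("h", "h"),
                    c("ACGTACGT", "ACGTACGT"), c(2L, 2L))
  dm <- distance_matrix(build_msa(same), species_labels(same))
  expect_true(all(inter_distances(dm, "s1") == 0))
})

test_that("six_metrics reproduces the published intraspecific values", {
  m_its2 <- six_metrics(its2_dm(), JAPONICA)
  expect_identical(attr(m_its2, "convention"), "focal")
  v <- function(m, k) m$mean[m$metric == k]
  expect_equal(round(v(m_its2, "All intra-specific distance"), 4), 0.0010)
  m_psba <- six_metrics(psba_dm(), JAPONICA)
  expect_equal(round(v(m_psba, "All intra-specific distance"), 4), 0.0000)
  # internal consistency
  for (m in list(m_its2, m_psba)) {
    expect_true(all(m$mean >= 0))
    expect_lte(v(m, "The minimum inter-specific distance"),
               v(m, "All inter-specific distance"))
    expect_true(all(is.finite(m$mean)), all(is.finite(m$sd)))
  }
})

test_that("metrics are invariant under record relabeling within species", {
  dm <- its2_dm()
  perm <- sample(rownames(dm$d))
  dm2 <- structure(list(d = dm$d[perm, perm], species = dm$species[perm]),
                   class = "k2p_dm")
  m1 <- six_metrics(dm, JAPONICA)
  m2 <- six_metrics(dm2, JAPONICA)
  expect_equal(m1$mean, m2$mean)
  expect_equal(m1$sd, m2$sd)
})

test_that("degenerate but valid panels yield finite metrics plus warnings", {
  two <- toy_panel(c("s1", "s2"), c("h1", "h2"),
                   c("ACGTACGTGG", "ACTTACGTGG"), c(2L, 2L))
  dm <- distance_matrix(build_msa(two), species_labels(two))
  m <- six_metrics(dm, "s1")
  expect_true(all(is.finite(m$mean)))
  expect_equal(m$mean[m$metric == "All intra-specific distance"], 0)

  lone <- toy_panel(c("s1", "s2"), c("h1", "h2"),
                    c("ACGTACGTGG", "ACTTACGTGG"), c(3L, 1L))
  dml <- distance_matrix(build_msa(lone), species_labels(lone))
  expect_warning(six_metrics(dml, "s1"), "single record")
})

test_that("gap histogram bins half-open classes and conserves pair counts", {
  h <- gap_histogram(its2_dm())
  expect_s3_class(h, "gap_histogram")
  # all conspecific ITS2 pairs sit below 0.01
  expect_identical(h$intra_count[1L], sum(h$intra_count))
  n_intra_expected <- 496L + as.integer(choose(5, 2)) * 3L + 1L * 3L
  expect_identical(sum(h$intra_count), n_intra_expected)
  expect_identical(sum(h$intra_count) + sum(h$inter_count), 1378L)
  # each bin's count equals an independent recount over [start, end)
  dm <- its2_dm()
  inter <- inter_distances(dm, mode = "global")
  for (k in seq_len(nrow(h))) {
    expect_identical(h$inter_count[k],
                     sum(inter >= h$bin_start[k] & inter < h$bin_end[k]))
  }

  expect_error(gap_histogram(its2_dm(), bin_width = 0), "positive")
  single <- toy_panel("s1", "h1", "ACGTACGT", 3L)
  dms <- distance_matrix(build_msa(single), species_labels(single))
  expect_error(gap_histogram(dms), "species")
})

test_that("the barcoding gap is detected on both loci and absent when faked", {
  for (dm in list(its2_dm(), psba_dm())) {
    g <- gap_exists(dm)
    expect_true(g$gap)
    expect_gt(g$min_inter, g$max_intra)
  }
  # one species duplicated under two labels with identical sequences
  fake <- toy_panel(c("s1", "s2"), c("h", "h"),
                    c("ACGTACGTAA", "ACGTACGTAA"), c(2L, 2L))
  dm <- distance_matrix(build_msa(fake), species_labels(fake))
  expect_false(gap_exists(dm)$gap)
})
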