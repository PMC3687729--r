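test_that("ancestor generation hits the exact GC composition deterministically", {
  expect_setequal(strsplit(generate_ancestor(40, 1.0, 3), "")[[1L]],
                  c("G", "C"))
  anc <- generate_ancestor(228, 0.754, 11)
  expect_identical(nchar(anc), 228L)
  gc_count <- sum(strsplit(anc, "")[[1L]] %in% c("G", "C"))
  expect_identical(gc_count, 172L)  # round(0.754 * 228), counted directly
  expect_identical(generate_ancestor(228, 0.754, 11),
                   generate_ancestor(228, 0.754, 11))
  expect_false(generate_ancestor(228, 0.754, 11) ==
                 generate_ancestor(228, 0.754, 12))
  expect_error(generate_ancestor(0, 0.5), "positive")
  expect_error(generate_ancestor(10, 1.5), "fraction")
})

test_that("default ITS2 panel reproduces the study's haplotype structure", {
  p <- its2_panel()
  r <- p$records
  expect_identical(nrow(r), 53L)
  expect_identical(length(unique(r$species)), 7L)
  counts <- table(paste(r$species, r$haplotype))
  expect_identical(sum(r$haplotype == "A1"), 4L)
  expect_identical(sum(r$haplotype == "A2"), 28L)
  expect_identical(as.vector(table(r$haplotype)[c("B1", "B2", "B3", "B4",
                                                  "B5", "B6")]),
                   c(5L, 5L, 2L, 2L, 5L, 2L))
  expect_setequal(unique(nchar(r$sequence)), c(228L, 229L))
  # A1 and A2 differ only by the C/T transition at base 27
  a1 <- strsplit(r$sequence[r$haplotype == "A1"][1L], "")[[1L]]
  a2 <- strsplit(r$sequence[r$haplotype == "A2"][1L], "")[[1L]]
  diff <- which(a1 != a2)
  expect_identical(diff, 27L)
  expect_setequal(c(a1[27L], a2[27L]), c("C", "T"))
  # 8 of the A2 records are public-database entries
  expect_identical(sum(r$source == "genbank"), 8L)
  expect_true(all(r$haplotype[r$source == "genbank"] == "A2"))
  # one haplotype (a non-japonica one) carries the 229 bp insertion
  long <- unique(r$haplotype[nchar(r$sequence) == 229L])
  expect_length(long, 1L)
  expect_false(long %in% c("A1", "A2"))
})

test_that("realized japonica ITS2 GC matches the target within one base", {
  r <- its2_panel()$records
  jap_gc <- gc_content(r$sequence[r$species == JAPONICA])
  expect_true(all(abs(jap_gc - 0.754) <= 1 / 228))
})

test_that("default psbA-trnH panel matches the study's structure", {
  q <- psba_panel()
  r <- q$records
  expect_identical(nrow(r), 45L)
  expect_identical(as.vector(table(r$species)[c(
    JAPONICA, "Lonicera macranthoides", "Lonicera fulvotomentosa",
    "Lonicera hypoglauca", "Lonicera confusa", "Lonicera similis",
    "Lonicera acuminata")]), c(24L, 5L, 5L, 2L, 2L, 5L, 2L))
  jap_seq <- unique(r$sequence[r$species == JAPONICA])
  expect_length(jap_seq, 1L)        # no within-species variation
  expect_identical(nchar(jap_seq), 339L)
  expect_identical(range(nchar(r$sequence)), c(332L, 356L))
})

test_that("panel realization is deterministic and seed-sensitive", {
  expect_identical(realize_panel(default_its2_spec()), its2_panel())
  other <- realize_panel(default_its2_spec(seed = 99L))
  expect_false(identical(other$ancestor, its2_panel()$ancestor))
  # structure is seed-invariant even though the ancestor differs
  expect_identical(other$records$id, its2_panel()$records$id)
  msa <- build_msa(other)
  expect_identical(count_variable_sites(msa), 14L)
})

test_that("every heterospecific haplotype pair is separable", {
  for (p in list(its2_panel(), psba_panel())) {
    r <- p$records
    haps <- r[!duplicated(paste(r$species, r$haplotype)), ]
    for (i in seq_len(nrow(haps) - 1L)) {
      for (j in (i + 1L):nrow(haps)) {
        if (haps$species[i] == haps$species[j]) next
        ap <- align_pair(haps$sequence[i], haps$sequence[j])
        ca <- strsplit(ap$a, "")[[1L]]
        cb <- strsplit(ap$b, "")[[1L]]
        expect_gte(sum(ca != cb), 1L)
      }
    }
  }
})

test_that("generic specs realize as documented and invalid specs fail", {
  one <- panel_spec("ITS2", 50L, 0.5,
                    species_spec("sp", haplotype_spec("h", 3L)),
                    n_variable_sites = 0L, seed = 5L)
  p <- realize_panel(one)
  expect_identical(nrow(p$records), 3L)
  expect_length(unique(p$records$sequence), 1L)

  expect_error(
    panel_spec("ITS2", 50L, 0.5,
               species_spec("sp", haplotype_spec(
                 "h", 2L, substitutions = data.frame(position = 60L,
                                                     base = "A"))),
               n_variable_sites = 1L),
    "beyond ancestor length")
  expect_error(
    panel_spec("ITS2", 50L, 0.5,
               species_spec("sp", haplotype_spec("h", 2L)),
               n_variable_sites = 3L),
    "variable sites")
  expect_error(haplotype_spec("h", 0L), "positive")
  expect_error(haplotype_spec("h", 2L, substitutions = data.frame(
    position = c(4L, 4L), base = c("A", "G"))), "duplicate")
})
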