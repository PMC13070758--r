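test_that("to_relative normalises rows and rejects empty samples", {
  tab <- abundance_table(rbind(c(2, 2, 6), c(1, 1, 2)),
                         c("A", "B"), c("t1", "t2", "t3"))
  rel <- to_relative(tab)
  expect_equal(unname(rel$values[1, ]), c(0.2, 0.2, 0.6))
  expect_true(rel$is_relative)
  # already-relative input is the identity
  expect_identical(to_relative(rel), rel)
  bad <- abundance_table(rbind(c(1, 1, 1), c(0, 0, 0)),
                         c("A", "B"), c("t1", "t2", "t3"))
  expect_error(to_relative(bad), "sample B")
})

test_that("abundance_table enforces uniqueness and row sums", {
  expect_error(abundance_table(matrix(1, 2, 2), c("A", "A"), c("t1", "t2")),
               "duplicated sample")
  expect_error(abundance_table(matrix(1, 2, 2), c("A", "B"), c("t", "t")),
               "duplicated taxon")
  expect_error(abundance_table(matrix(0.4, 2, 2), c("A", "B"),
                               c("t1", "t2"), is_relative = TRUE),
               "sum to 1")
})

test_that("genus collapse sums shared genera and conserves totals", {
  taxa <- c("k__Bacteria;p__Actinobacteriota;c__C;o__O;f__Bifidobacteriaceae;g__Bifidobacterium",
            "k__Bacteria;p__Actinobacteriota;c__C2;o__O2;f__Bifidobacteriaceae;g__Bifidobacterium",
            "k__Bacteria;p__Firmicutes;c__C;o__O;f__Lachnospiraceae;g__",
            "k__Bacteria;p__Firmicutes;c__C;o__O;f__Lachnospiraceae;g__Blautia")
  tab <- abundance_table(rbind(c(0.10, 0.05, 0.25, 0.60),
                               c(0.30, 0.10, 0.20, 0.40)),
                         c("A", "B"), taxa, is_relative = TRUE)
  gen <- collapse_to_genus(tab)
  bif <- grep("g__Bifidobacterium", gen$taxa, value = TRUE)
  expect_length(bif, 1)
  expect_equal(unname(gen$values[, bif]), c(0.15, 0.40))
  # genus-free lineage becomes a family proxy column
  expect_true(any(grepl("f__Lachnospiraceae$", gen$taxa)))
  # per-sample totals conserved exactly
  expect_equal(rowSums(gen$values), rowSums(tab$values))
  # provenance retained
  prov <- attr(gen, "provenance")
  expect_length(prov[[bif]], 2)
})

test_that("collapse keeps phylum labels and is idempotent at genus level", {
  tab <- rel_table(rbind(c(1, 2, 3), c(2, 2, 2)), unname(balance_taxa))
  gen <- collapse_to_genus(tab)
  expect_setequal(vapply(gen$taxa, function(t) lineage_rank(t, "p"),
                         character(1)),
                  c("Actinobacteriota", "Firmicutes"))
  gen2 <- collapse_to_genus(gen)
  expect_equal(sort(gen2$taxa), sort(gen$taxa))
  expect_equal(gen2$values[, sort(gen2$taxa)], gen$values[, sort(gen$taxa)])
  expect_error(collapse_to_genus(
    abundance_table(matrix(1, 1, 1), "A", "k__;p__;f__;g__")),
    "lineage")
})

test_that("taxon filter applies inclusive prevalence/abundance bounds", {
  # 20 samples: t_rare present in 1, t_thin at prevalence 1 but mean
  # below 0.1%, t_edge exactly at both boundaries (prevalence 3/20,
  # mean 0.001), t_ok well above both
  vals20 <- matrix(0, 20, 4,
                   dimnames = list(sprintf("S%02d", 1:20),
                                   c("t_rare", "t_thin", "t_edge", "t_ok")))
  vals20[1, "t_rare"] <- 0.02
  vals20[, "t_thin"] <- 0.0005
  vals20[1:3, "t_edge"] <- 0.02 / 3  # prevalence 3/20 = 0.15
  vals20[, "t_ok"] <- 0.5
  tab <- abundance_table(vals20, is_relative = FALSE)
  tab$is_relative <- TRUE
  # abundance threshold set to t_edge's exact mean: boundary retains
  out <- filter_taxa(tab, min_prevalence = 0.15,
                     min_mean_rel_abundance = mean(vals20[, "t_edge"]))
  expect_setequal(out$taxa, c("t_edge", "t_ok"))
  rep <- attr(out, "filter_report")
  expect_false(rep$kept[rep$taxon == "t_rare"])
  expect_false(rep$kept[rep$taxon == "t_thin"])
  expect_equal(rep$prevalence[rep$taxon == "t_edge"], 0.15)
  # filtering is idempotent and a subset of the input
  out2 <- filter_taxa(out, min_prevalence = 0.15,
                      min_mean_rel_abundance = mean(vals20[, "t_edge"]))
  expect_identical(out2$taxa, out$taxa)
  expect_true(all(out$taxa %in% tab$taxa))
})

test_that("an empty filter result warns rather than errors", {
  vals <- matrix(0, 10, 1, dimnames = list(sprintf("S%02d", 1:10), "t"))
  vals[1, 1] <- 1e-5
  tab <- abundance_table(vals)
  tab$is_relative <- TRUE
  expect_warning(filter_taxa(tab), "no taxa")
})

test_that("candidate ranking is by descending mean with lexicographic ties", {
  tab <- rel_table(rbind(c(0.02, 0.05, 0.001, 0.929),
                         c(0.02, 0.05, 0.001, 0.929)),
                   c("A", "B", "C", "D"))
  expect_equal(rank_by_mean_abundance(tab, c("A", "B", "C")),
               c("B", "A", "C"))
  tie <- rel_table(rbind(c(0.3, 0.3, 0.4)), c("zeta", "alpha", "rest"))
  expect_equal(rank_by_mean_abundance(tie, c("zeta", "alpha")),
               c("alpha", "zeta"))
  expect_equal(rank_by_mean_abundance(tab, "A"), "A")
  expect_error(rank_by_mean_abundance(tab, "nope"), "nope")
})

test_that("micro-balance matches its closed form", {
  spec <- balance_spec("bif", c("pha", "lac"), epsilon = 1e-6)
  mk <- function(b, p, l) {
    t <- abundance_table(matrix(c(b, p, l, 1 - b - p - l), 1,
                                dimnames = list("S1", c("bif", "pha", "lac", "other"))))
    t$is_relative <- TRUE
    t
  }
  # equal abundances cancel by symmetry
  expect_equal(unname(compute_balance(mk(0.1, 0.1, 0.1), spec)), 0)
  # worked value, natural log with eps = 1e-6
  expect_equal(unname(compute_balance(mk(0.1, 0.01, 0.001), spec)),
               3.45334, tolerance = 1e-5)
  # all-zero sample gives exactly 0
  expect_equal(unname(compute_balance(mk(0, 0, 0), spec)), 0)
  expect_error(compute_balance(mk(0.1, 0.1, 0.1),
                               balance_spec("absent", c("pha", "lac"))),
               "absent")
})

test_that("balance is scale-invariant under compositional closure", {
  # multiplying a sample's raw abundances by any c > 0 and renormalising
  # to relative abundances must leave the balance unchanged
  spec <- balance_spec("t1", c("t2", "t3"), epsilon = 1e-6)
  set.seed(11)
  for (i in 1:50) {
    raw <- runif(4, 1e-3, 0.5)
    cc <- runif(1, 0.05, 20)
    taxa <- c("t1", "t2", "t3", "t4")
    b1 <- compute_balance(to_relative(abundance_table(
      matrix(raw, 1, dimnames = list("S1", taxa)))), spec)
    b2 <- compute_balance(to_relative(abundance_table(
      matrix(raw * cc, 1, dimnames = list("S1", taxa)))), spec)
    expect_lt(abs(b2 - b1), 1e-6)
  }
})

test_that("balance spec validates its fields", {
  expect_error(balance_spec("a", c("a", "b")), "numerator")
  expect_error(balance_spec("a", character(0)), "denominators")
  expect_error(balance_spec("a", "b", epsilon = 0), "positive")
})

test_that("F/B ratio resolves phyla including updated synonyms", {
  taxa <- c("k__Bacteria;p__Firmicutes;g__X",
            "k__Bacteria;p__Bacteroidetes;g__Y",
            "k__Bacteria;p__Proteobacteria;g__Z")
  tab <- abundance_table(rbind(c(0.5, 0.25, 0.25), c(0.4, 0.4, 0.2)),
                         c("A", "B"), taxa, is_relative = TRUE)
  fb <- fb_ratio(tab)
  expect_equal(unname(fb$per_sample), c(2, 1))
  # Bacillota/Bacteroidota synonyms give the same ratio
  syn <- c("k__Bacteria;p__Bacillota;g__X",
           "k__Bacteria;p__Bacteroidota;g__Y",
           "k__Bacteria;p__Proteobacteria;g__Z")
  tab2 <- abundance_table(tab$values, tab$sample_ids, syn,
                          is_relative = TRUE)
  expect_equal(fb_ratio(tab2)$per_sample, fb$per_sample)
  # zero-Bacteroidetes sample excluded from the mean
  tab3 <- abundance_table(rbind(c(0.5, 0, 0.5), c(0.4, 0.4, 0.2)),
                          c("A", "B"), taxa, is_relative = TRUE)
  expect_equal(fb_ratio(tab3)$mean_ratio, 1)
  expect_error(fb_ratio(abundance_table(matrix(1, 1, 1), "A",
                                        "k__Bacteria;p__Firmicutes;g__X")),
               "Bacteroidetes")
})

test_that("Chao1 equals the bias-corrected closed form", {
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1(c(3, 4, 5, 0)), 3)      # no singletons
  expect_equal(chao1(c(5, 7, 9)), 3)          # all >= 3
  expect_error(chao1(c(0.3, 1)), "integer")
  expect_error(chao1(c(-1, 2)), "non-negative")
  set.seed(3)
  for (i in 1:30) {
    cts <- rpois(50, 2)
    expect_gte(chao1(cts), sum(cts > 0))
  }
})

test_that("differential screen flags planted shifts and nothing else", {
  set.seed(5)
  n <- 20
  base <- matrix(runif(n * 3, 0.01, 0.05), n, 3,
                 dimnames = list(sprintf("A%02d", 1:n), c("up", "flat", "zero")))
  other <- base
  other[, "up"] <- runif(n, 0.25, 0.35)   # non-overlapping shift
  base[, "zero"] <- 0
  other[, "zero"] <- 0
  rownames(other) <- sprintf("B%02d", 1:n)
  ta <- abundance_table(base); tb <- abundance_table(other)
  scr <- differential_screen(ta, tb)
  row_up <- scr[scr$taxon == "up", ]
  expect_true(row_up$flagged)
  expect_equal(row_up$direction, -1)      # higher in group B
  expect_lt(row_up$p_value, 0.05)
  # exact rank-sum oracle for complete separation
  expect_equal(row_up$p_value,
               wilcox.test(base[, "up"], other[, "up"], exact = TRUE)$p.value)
  # constant-zero genus: degenerate, not flagged
  expect_false(scr[scr$taxon == "zero", "flagged"])
  expect_true(is.na(scr[scr$taxon == "zero", "p_value"]))
  # identical groups: nothing flagged
  scr0 <- differential_screen(ta, abundance_table(base + 0,
                                                  sprintf("C%02d", 1:n)))
  expect_false(any(scr0$flagged))
  expect_error(differential_screen(ta, abundance_table(other[, 1:2])),
               "taxa")
})
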