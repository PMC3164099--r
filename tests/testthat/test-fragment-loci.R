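test_that("allele frequencies follow the peak-counting convention", {
  pop <- population_sample(list(a = 184, b = c(184, 221)))
  fr <- allele_frequencies(pop)
  expect_equal(as.numeric(fr), c(2 / 3, 1 / 3))
  expect_equal(names(fr), c("184", "221"))
  expect_equal(sum(fr), 1)
  one <- population_sample(list(a = 200))
  expect_equal(as.numeric(allele_frequencies(one)), 1)
  expect_error(population_sample(list()), "empty")
})

test_that("peak counting underestimates the common allele frequency", {
  # truth: allele 100 at 0.8, allele 200 at 0.2, one locus, HWE diploids
  set.seed(21)
  gts <- replicate(4000, sort(unique(sample(c(100, 200), 2, replace = TRUE,
                                            prob = c(0.8, 0.2)))),
                   simplify = FALSE)
  names(gts) <- paste0("i", seq_along(gts))
  fr <- allele_frequencies(population_sample(gts))
  expect_lt(fr[["100"]], 0.8)
  expect_gt(fr[["200"]], 0.2)
})

test_that("gene diversity has the right limits", {
  expect_equal(gene_diversity(c(a = 1), 100), 0)
  expect_equal(gene_diversity(c(0.5, 0.5), 1e6), 0.5, tolerance = 1e-5)
  k <- 8
  expect_equal(gene_diversity(rep(1 / k, k), 1e6), 1 - 1 / k,
               tolerance = 1e-5)
  expect_error(gene_diversity(c(0.5, 0.4), 10), "sum to 1")
})

test_that("minimum locus count is ceil(max peaks / 2) and monotone", {
  mk <- function(maxp) suppressWarnings(population_sample(
    list(a = seq_len(maxp) * 10, b = 100)))
  expect_equal(min_locus_count(mk(4)), 2L)
  expect_equal(min_locus_count(mk(2)), 1L)
  # more than 4 peaks warns (diploid with two loci cannot show them)
  expect_warning(population_sample(list(a = 1:5 * 10)), "more than 4")
  expect_equal(min_locus_count(mk(5)), 3L)
  counts <- vapply(1:6, function(p) min_locus_count(mk(p)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("double-heterozygote expectations reproduce He^2", {
  expect_equal(round(expected_multiheterozygote(0.779, 2) * 100, 1), 60.7)
  expect_equal(round(expected_multiheterozygote(0.761, 2) * 100, 1), 57.9)
  expect_equal(round(expected_multiheterozygote(0.899, 2) * 100, 1), 80.8)
  expect_lt(abs(expected_multiheterozygote(0.913, 2) * 100 - 83.3), 0.1)
  expect_equal(expected_multiheterozygote(0, 2), 0)
  expect_error(expected_multiheterozygote(1.2, 2), "\\[0, 1\\]")
})

test_that("observed multi-heterozygote proportion is a plain fraction", {
  gts <- c(replicate(2, list(c(10, 20, 30, 40))),
           replicate(28, list(c(10, 20))))
  names(gts) <- paste0("i", 1:30)
  pop <- population_sample(gts)
  expect_equal(observed_multiheterozygote(pop, 2), 2 / 30)
  expect_equal(observed_multiheterozygote(pop, 3), 0)
})

test_that("simulated peak genotypes match the exact four-peak probability", {
  # with 4 iid allele draws per individual, P(4 distinct peaks) is a sum
  # over distinct quadruples of the mode frequencies
  p4_exact <- function(modes) {
    k <- length(modes)
    if (k < 4) return(0)
    tot <- 0
    for (q in combn(k, 4, simplify = FALSE))
      tot <- tot + prod(modes[q]) * factorial(4)
    tot
  }
  cfg <- sim_config(seed = 77, n_individuals = 600L)
  pops <- simulate_population_peaks(cfg)
  for (intr in names(pops)) {
    obs <- observed_multiheterozygote(pops[[intr]], 2L)
    exact <- p4_exact(cfg$intron_size_modes[[intr]])
    expect_lt(abs(obs - exact), 0.05)
  }
})

test_that("with many rare alleles the four-peak fraction approaches He^2", {
  # the He^2 expectation neglects allele sharing between the duplicated
  # loci, so it is only reached when most alleles are rare
  modes <- setNames(rep(1 / 60, 60), 100 + seq_len(60))
  cfg <- sim_config(seed = 78, n_individuals = 500L,
                    intron_size_modes = list("1" = modes, "2" = modes))
  pops <- simulate_population_peaks(cfg)
  li <- locus_inference(pops[["1"]], n_loci = 2L)
  expect_lt(abs(li$observed_multihet - li$expected_multihet), 0.08)
})

test_that("WMW test handles identical, disjoint and permutation checks", {
  a <- population_sample(list(x = c(100, 110), y = c(100, 120)))
  res <- compare_populations_wmw(a, a)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  lo <- population_sample(setNames(as.list(100 + 1:20), paste0("a", 1:20)))
  hi <- population_sample(setNames(as.list(300 + 1:20), paste0("b", 1:20)))
  expect_gt(abs(compare_populations_wmw(lo, hi)$z), 5)

  set.seed(31)
  xa <- sample(c(184, 221, 376), 15, replace = TRUE)
  xb <- sample(c(184, 221, 376), 15, replace = TRUE, prob = c(2, 1, 1))
  pa <- population_sample(setNames(as.list(xa), paste0("a", 1:15)))
  pb <- population_sample(setNames(as.list(xb), paste0("b", 1:15)))
  p_norm <- compare_populations_wmw(pa, pb)$p
  p_perm <- oracle_wmw_perm(xa, xb)
  expect_lt(abs(p_norm - p_perm), 0.02)
})

test_that("locus inference bundles A, He and multi-het comparison", {
  gts <- list(a = c(184, 221, 376, 380), b = c(184, 221), c = 184,
              d = c(221, 376), e = c(184, 380))
  li <- locus_inference(population_sample(gts, name = "toy"))
  expect_equal(li$A, 4)
  expect_equal(li$min_loci, 2)
  expect_equal(li$observed_multihet, 1 / 5)
  expect_equal(li$expected_multihet, li$gene_diversity^2)
})
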