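make_cross <- function(father1, father2, mother1, mother2, n_each = 4,
                       intron = "1", extra = NULL) {
  rows <- NULL
  add <- function(rows, member, sizes, intr = intron) {
    rbind(rows, data.frame(family = "f1", member = member, intron = intr,
                           size = sizes))
  }
  rows <- add(rows, "father", unique(c(father1, father2)))
  rows <- add(rows, "mother", unique(c(mother1, mother2)))
  k <- 0
  for (fb in list(father1, father2)) for (mb in list(mother1, mother2))
    for (i in seq_len(n_each)) {
      k <- k + 1
      rows <- add(rows, sprintf("o%02d", k), unique(c(fb, mb)))
    }
  if (!is.null(extra)) rows <- rbind(rows, extra)
  family_cross(rows)
}

test_that("singleton blocks are recovered for two-allele parents", {
  cross <- make_cross(223, 376, 219, 362)
  bl <- infer_parental_haplotypes(cross, "1")
  expect_setequal(lapply(bl$father_blocks, as.numeric), list(223, 376))
  expect_setequal(lapply(bl$mother_blocks, as.numeric), list(219, 362))
  expect_equal(bl$n_consistent, bl$n_offspring)
  expect_equal(bl$duplicates, 0)
})

test_that("a three-peak parent yields a multi-allele co-transmission block", {
  cross <- make_cross(223, 376, c(221, 223), 369)
  bl <- infer_parental_haplotypes(cross, "1")
  expect_setequal(lapply(bl$mother_blocks, as.numeric),
                  list(c(221, 223), 369))
  expect_equal(length(bl$violating), 0)
})

test_that("hidden duplicate alleles are inferred when offspring require them", {
  # father carries 201 on both haplotypes: blocks {201,203} and {201,205};
  # no duplicate-free partition of peaks {201,203,205} explains both
  # offspring classes
  cross <- make_cross(c(201, 203), c(201, 205), 219, 219, n_each = 5)
  bl <- infer_parental_haplotypes(cross, "1")
  expect_setequal(lapply(bl$father_blocks, as.numeric),
                  list(c(201, 203), c(201, 205)))
  expect_gte(bl$duplicates, 1)
  expect_equal(length(bl$violating), 0)
})

test_that("duplicate-free explanations are preferred when sets allow them", {
  # a plainly heterozygous father: singleton blocks explain every
  # offspring, so no hidden duplicate is invoked
  cross <- make_cross(201, 205, 219, 362, n_each = 5)
  bl <- infer_parental_haplotypes(cross, "1")
  expect_equal(bl$duplicates, 0)
  expect_setequal(lapply(bl$father_blocks, as.numeric), list(201, 205))
  expect_equal(length(bl$violating), 0)
})

test_that("offspring peaks absent from both parents are flagged", {
  extra <- data.frame(family = "f1", member = "o01", intron = "1",
                      size = 999)
  cross <- make_cross(223, 376, 219, 362, extra = extra)
  bl <- suppressWarnings(infer_parental_haplotypes(cross, "1"))
  expect_true(length(bl$incompatible_peaks) >= 1)
})

test_that("few offspring trigger a power warning", {
  cross <- make_cross(223, 376, 219, 362, n_each = 1)
  expect_warning(infer_parental_haplotypes(cross, "1"), "power")
})

test_that("chi-square segregation matches closed forms", {
  r <- chi_square_segregation(c(5, 5, 5, 5))
  expect_equal(r$chi2, 0); expect_equal(r$p, 1); expect_equal(r$df, 3)
  r2 <- chi_square_segregation(c(8, 4, 4, 3))
  expect_equal(r2$chi2, sum((c(8, 4, 4, 3) - 4.75)^2 / 4.75))
  expect_equal(r2$df, 3)
  r3 <- chi_square_segregation(c(10, 0))
  expect_equal(r3$chi2, 10)
  expect_equal(r3$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  # invariance under class relabeling
  o <- c(7, 3, 6, 4)
  expect_equal(chi_square_segregation(o)$chi2,
               chi_square_segregation(rev(o))$chi2)
  expect_error(chi_square_segregation(c(5)), "2 classes")
  expect_error(chi_square_segregation(c(5, 5), ratio = c(1, 0)), "expected")
})

test_that("genotype classes count offspring per block combination", {
  cross <- make_cross(223, 376, 219, 362, n_each = 5)
  bl <- infer_parental_haplotypes(cross, "1")
  gc <- genotype_class_counts(cross, bl, "1")
  expect_equal(sort(as.vector(gc$counts)), c(5, 5, 5, 5))
  cs <- chi_square_segregation(as.vector(gc$counts))
  expect_equal(cs$p, 1)
})

test_that("intron linkage detects complete disequilibrium and recombinants", {
  # father haplotypes: (223 | 202) and (376 | 211); mother homozygous
  rows <- NULL
  add <- function(rows, member, i1, i2)
    rbind(rows,
          data.frame(family = "f1", member = member, intron = "1", size = i1),
          data.frame(family = "f1", member = member, intron = "2", size = i2))
  rows <- add(rows, "father", c(223, 376), c(202, 211))
  rows <- add(rows, "mother", 219, 198)
  for (i in 1:5) rows <- add(rows, sprintf("o%02d", i), c(223, 219),
                             c(202, 198))
  for (i in 6:10) rows <- add(rows, sprintf("o%02d", i), c(376, 219),
                              c(211, 198))
  cross <- family_cross(rows)
  b1 <- infer_parental_haplotypes(cross, "1")
  b2 <- infer_parental_haplotypes(cross, "2")
  lk <- test_intron_linkage(cross, b1, b2)
  expect_equal(lk$father$n_recombinant, 0)
  expect_true(lk$complete_disequilibrium)

  # one discordant offspring breaks completeness
  rows2 <- rbind(rows[rows$member != "o10", ],
                 data.frame(family = "f1", member = "o10", intron = "1",
                            size = c(376, 219)),
                 data.frame(family = "f1", member = "o10", intron = "2",
                            size = c(202, 198)))
  cross2 <- family_cross(rows2)
  lk2 <- test_intron_linkage(cross2,
                             infer_parental_haplotypes(cross2, "1"),
                             infer_parental_haplotypes(cross2, "2"))
  expect_equal(lk2$father$n_recombinant, 1)
  expect_false(lk2$complete_disequilibrium)
})

test_that("locus-model verdicts follow the block structure", {
  # multi-allele block -> two linked loci
  cross <- make_cross(c(221, 372), 218, 219, 362, n_each = 5)
  bl <- list("1" = infer_parental_haplotypes(cross, "1"))
  expect_equal(fit_locus_model(cross, bl)$verdict, "two_linked_loci")
  # all parents two singleton alleles -> consistent with a single locus
  cross2 <- make_cross(223, 376, 219, 362, n_each = 5)
  bl2 <- list("1" = infer_parental_haplotypes(cross2, "1"))
  expect_equal(fit_locus_model(cross2, bl2)$verdict, "single_locus")
})

test_that("independently simulated introns break linkage about half the time", {
  cfg <- sim_config(seed = 55, family_offspring = 40L)
  set.seed(55)
  father <- list(ampliclone:::draw_haplotype(cfg, rep("x", 3)),
                 ampliclone:::draw_haplotype(cfg, rep("x", 3)))
  mother <- list(ampliclone:::draw_haplotype(cfg, rep("x", 3)),
                 ampliclone:::draw_haplotype(cfg, rep("x", 3)))
  fam <- simulate_family(cfg, father, mother, rec_fraction = 0.5)
  frac <- mean(vapply(fam$truth, function(t)
    t$father_recombined || t$mother_recombined, TRUE))
  expect_gt(frac, 0.5)  # each parent recombines at 0.5: 75% expected
  expect_lt(frac, 0.95)
})
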