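test_that("site classification distinguishes singleton and informative", {
  m <- rbind(c("A"), c("A"), c("A"), c("T"))
  ss <- segregating_sites(m)
  expect_equal(ss$S, 1); expect_equal(ss$singletons, 1)
  expect_equal(ss$parsimony_informative, 0)

  m <- rbind(c("A"), c("A"), c("T"), c("T"))
  ss <- segregating_sites(m)
  expect_equal(ss$S, 1); expect_equal(ss$singletons, 0)
  expect_equal(ss$parsimony_informative, 1)

  # triallelic site with one rare state stays informative; eta counts 2
  m <- cbind(c("A", "A", "T", "T", "G"))
  ss <- segregating_sites(m)
  expect_equal(ss$S, 1); expect_equal(ss$parsimony_informative, 1)
  expect_equal(ss$eta, 2)

  # property: singletons + informative = S on random biallelic data
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "G"), 8 * 20, replace = TRUE), nrow = 8)
    ss <- segregating_sites(m)
    expect_equal(ss$singletons + ss$parsimony_informative, ss$S)
  }
})

test_that("Watterson's theta matches closed-form values", {
  expect_equal(round(watterson_theta(29, 94, 120), 5), 0.04724)
  expect_equal(round(watterson_theta(26, 22, 120), 5), 0.05944)
  expect_equal(round(watterson_theta(15, 22, 120), 5), 0.03429)
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_error(watterson_theta(5, 1, 100), "insufficient")
})

test_that("pi counts pairwise differences per site", {
  a <- paste(rep("A", 300), collapse = "")
  b <- mutate_str(mutate_str(mutate_str(a, 1, "T"), 100, "T"), 200, "T")
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  expect_equal(nucleotide_diversity_pi(m), 0.01)
  expect_equal(nucleotide_diversity_pi(rbind(m[1, ], m[1, ])), 0)
  # complete vs pairwise deletion differ in the presence of gaps
  g <- m; g[1, 2] <- "-"
  expect_equal(nucleotide_diversity_pi(g, "complete"), 3 / 299)
  expect_equal(nucleotide_diversity_pi(g, "pairwise"), 3 / 299)
})

test_that("haplotype diversity uses the small-sample correction", {
  seqs <- vapply(1:10, function(i)
    paste(c(rep("A", i), rep("C", 10 - i)), collapse = ""), "")
  names(seqs) <- sprintf("a_%02d_cDNA", 1:10)
  expect_equal(haplotype_diversity(make_aln(seqs)), 1.0)
  one <- make_aln(c(a_1_cDNA = "AAAA", a_2_cDNA = "AAAA"))
  expect_equal(haplotype_diversity(one), 0)
})

test_that("Tajima's D agrees with an independent transcription", {
  # numerator exactly zero
  k <- ampliclone:::tajima_constants(10)
  d <- tajimas_d(5, 10, 5 / k$a1)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(tajimas_d(0, 10, 0), "defined") == FALSE)
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    m <- matrix(sample(c("A", "G"), n * 25, replace = TRUE,
                       prob = c(0.8, 0.2)), nrow = n)
    expect_equal(as.numeric(tajimas_d_aln(m)), oracle_tajima(m),
                 tolerance = 1e-12)
  }
})

test_that("Fu and Li's D* agrees with an independent transcription", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    m <- matrix(sample(c("A", "G"), n * 25, replace = TRUE,
                       prob = c(0.85, 0.15)), nrow = n)
    got <- fu_li_d(m, "star")
    expect_equal(as.numeric(got), oracle_fu_li_star(m), tolerance = 1e-12)
  }
  m0 <- matrix("A", 5, 10)
  expect_false(attr(fu_li_d(m0), "defined"))
  expect_error(fu_li_d(m0, "outgroup"), "outgroup")
})

test_that("an excess of singletons lowers Fu and Li's D* at fixed S", {
  n <- 10; S <- 6
  sing <- matrix("A", n, S); bal <- matrix("A", n, S)
  for (j in 1:S) {
    sing[j, j] <- "G"          # every variant a singleton
    bal[1:5, j] <- "G"         # every variant balanced
  }
  expect_lt(as.numeric(fu_li_d(sing, "star")),
            as.numeric(fu_li_d(bal, "star")))
})

test_that("outgroup-polarized D responds to external mutations", {
  n <- 8
  m <- matrix("A", n, 6)
  for (j in 1:3) m[j, j] <- "G"        # derived singletons
  for (j in 4:6) m[1:4, j] <- "G"      # internal variants
  out <- rep("A", 6)
  d <- fu_li_d(m, "outgroup", outgroup = out)
  expect_true(attr(d, "defined"))
  # flipping the outgroup at singleton sites changes eta_e, hence D
  out2 <- out; out2[1:3] <- "G"
  d2 <- fu_li_d(m, "outgroup", outgroup = out2)
  expect_false(isTRUE(all.equal(as.numeric(d), as.numeric(d2))))
})

test_that("Rm detects four-gamete incompatibility and matches brute force", {
  m <- rbind(c("A", "A"), c("A", "T"), c("G", "A"), c("G", "T"))
  expect_equal(hudson_kaplan_rm(m)$rm, 1)
  m2 <- rbind(c("A", "A"), c("A", "T"), c("G", "T"), c("G", "T"))
  expect_equal(hudson_kaplan_rm(m2)$rm, 0)
  set.seed(5)
  for (rep in 1:25) {
    m <- matrix(sample(c("A", "G"), 8 * 10, replace = TRUE), nrow = 8)
    expect_equal(hudson_kaplan_rm(m)$rm, oracle_rm_bruteforce(m))
  }
})

test_that("Nei-Gojobori pathway counting matches hand enumeration", {
  # two synonymous-only paths
  expect_equal(unname(ampliclone:::ng86_path_counts("TTA", "CTG")),
               c(2, 0))
  # two nonsynonymous-only paths
  expect_equal(unname(ampliclone:::ng86_path_counts("GCT", "AGT")),
               c(0, 2))
  # mixed: GCT -> GCA (syn at pos3), GCT -> ACT (nonsyn at pos1)
  expect_equal(unname(ampliclone:::ng86_path_counts("GCT", "ACA")),
               c(1, 1))
  # synonymous sites of GCT: third position fully degenerate
  expect_equal(ampliclone:::ng86_codon_syn_sites("GCT"), 1)
  expect_equal(ampliclone:::ng86_codon_syn_sites("TTT"), 1 / 3)
})

test_that("Ka/Ks handles the degenerate and single-difference cases", {
  a <- "AAAGCTCCATTT"; b <- "AAAGCCCCATTT"  # one synonymous diff
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  res <- ng86_kaks(m)
  expect_equal(res$ka, 0)
  # hand-computed: Sd=1, syn sites = (1/3 + 1 + 1 + 1/3) = 8/3 per seq
  expect_equal(res$ks, -3 / 4 * log(1 - 4 / 3 * (1 / (8 / 3))))
  expect_equal(res$omega, 0)
  ident <- rbind(m[1, ], m[1, ])
  res2 <- ng86_kaks(ident)
  expect_false(res2$defined)
  expect_error(ng86_kaks(m[, 1:4]), "frame")
})

test_that("theta and pi vanish together exactly when S is zero", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    m <- matrix(sample(c("A", "G"), n * 12, replace = TRUE,
                       prob = c(0.95, 0.05)), nrow = n)
    ss <- segregating_sites(m)
    th <- watterson_theta(ss$S, n, ncol(m))
    pi <- nucleotide_diversity_pi(m)
    expect_equal(ss$S == 0, th == 0)
    expect_equal(th == 0, pi == 0)
  }
})

test_that("diversity_stats assembles a coherent table row", {
  ds <- synthetic_study_dataset()
  row <- diversity_stats(ds$basics, region = "all", kaks = FALSE)
  expect_equal(row$n, 22)
  expect_equal(row$S, 48)
  expect_equal(row$singletons, 17)
  expect_equal(row$informative, 31)
  expect_equal(row$rm, 5)
  expect_equal(row$theta_w, watterson_theta(48, 22, 300))
})
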