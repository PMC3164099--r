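#' Build a population sample of intron size genotypes
#'
#' Each individual's genotype at an intron is the set of distinct peak
#' sizes (bp) seen in fragment analysis; up to 4 peaks are expected for a
#' diploid with two duplicated loci (more triggers a warning). Fractional
#' sizes are rounded half-up with a note.
#'
#' @param peaks Data frame with columns `individual`, `intron`, `size`
#'   (one row per peak), or a named list individual -> sizes.
#' @param intron Which intron to keep when `peaks` is a data frame.
#' @param name Population label.
#' @return Object of class `population_sample`.
#' @export
population_sample <- function(peaks, intron = NULL, name = "pop") {
  if (is.data.frame(peaks)) {
    if (!is.null(intron)) peaks <- peaks[peaks$intron == intron, ]
    if (!nrow(peaks)) stop("empty population: no peaks")
    gt <- split(peaks$size, peaks$individual)
  } else gt <- peaks
  if (!length(gt)) stop("empty population: no genotypes")
  gt <- lapply(gt, function(s) {
    if (any(s != round(s)))
      message("fractional peak sizes rounded half-up")
    sort(unique(as.integer(floor(s + 0.5))))
  })
  np <- vapply(gt, length, 0L)
  if (any(np > 4L))
    warning(sprintf("%d individual(s) with more than 4 peaks",
                    sum(np > 4L)))
  structure(list(name = name, genotypes = gt, intron = intron),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("population_sample '%s': %d individuals, %d distinct sizes\n",
              x$name, length(x$genotypes),
              length(unique(unlist(x$genotypes)))))
  invisible(x)
}

#' Allele frequencies under the peak-counting convention
#'
#' Each distinct peak in an individual contributes one count. This is the
#' convention forced by not knowing locus assignment; it slightly
#' underestimates the frequency of common alleles because homozygous
#' individuals contribute a single count.
#'
#' @param pop A [population_sample].
#' @return Named numeric vector of frequencies (sums to 1), with
#'   attribute `counts`.
#' @export
allele_frequencies <- function(pop) {
  if (!length(pop$genotypes)) stop("empty population")
  counts <- table(unlist(pop$genotypes))
  fr <- as.numeric(counts) / sum(counts)
  names(fr) <- names(counts)
  attr(fr, "counts") <- as.integer(counts)
  fr
}

#' Nei unbiased gene diversity
#'
#' He = n/(n-1) (1 - sum p_i^2), n = total allele count.
#'
#' @param freqs Named frequency vector (sums to 1 within 1e-9).
#' @param n_counts Total number of counted alleles.
#' @return He.
#' @export
gene_diversity <- function(freqs, n_counts) {
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (n_counts < 2L) stop("need at least 2 counted alleles")
  n_counts / (n_counts - 1) * (1 - sum(freqs^2))
}

#' Minimum number of loci consistent with the peak counts
#'
#' A diploid carries at most 2 alleles per locus, so the minimum locus
#' number is ceil(max peaks per individual / 2).
#'
#' @param pop A [population_sample].
#' @return Integer.
#' @export
min_locus_count <- function(pop) {
  as.integer(ceiling(max(vapply(pop$genotypes, length, 0L)) / 2))
}

#' Expected proportion of fully heterozygous multi-locus individuals
#'
#' Under `n_loci` independent duplicated loci drawing from one shared
#' allele pool with gene diversity He, the probability that an individual
#' shows `2 * n_loci` distinct peaks is approximately He^n_loci.
#'
#' @param he_locus Gene diversity of the shared pool.
#' @param n_loci Number of loci.
#' @return Expected proportion in `[0, 1]`.
#' @export
expected_multiheterozygote <- function(he_locus, n_loci = 2L) {
  if (he_locus < 0 || he_locus > 1) stop("He must lie in [0, 1]")
  he_locus^n_loci
}

#' Observed proportion of individuals with 2*n_loci distinct peaks
#'
#' @param pop A [population_sample].
#' @param n_loci Number of loci.
#' @return Observed proportion.
#' @export
observed_multiheterozygote <- function(pop, n_loci = 2L) {
  if (!length(pop$genotypes)) stop("empty population")
  mean(vapply(pop$genotypes, length, 0L) == 2L * n_loci)
}

#' Wilcoxon-Mann-Whitney comparison of two allele-size distributions
#'
#' Observations are the counted allele sizes of each population (one per
#' counted peak). Rank-sum statistic with tie-corrected normal
#' approximation and continuity correction.
#'
#' @param a,b [population_sample] objects.
#' @return List with `z`, `p` (two-sided), `n_a`, `n_b`.
#' @export
compare_populations_wmw <- function(a, b) {
  xa <- unlist(a$genotypes); xb <- unlist(b$genotypes)
  if (!length(xa) || !length(xb)) stop("empty sample")
  na <- length(xa); nb <- length(xb); N <- na + nb
  r <- rank(c(xa, xb))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- table(c(xa, xb))
  tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tiecorr)
  if (sigma2 <= 0) return(list(z = 0, p = 1, n_a = na, n_b = nb))
  dev <- W - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  if (dev == 0) z <- 0
  list(z = z, p = min(1, 2 * pnorm(-abs(z))), n_a = na, n_b = nb)
}

#' Read a peak table
#'
#' @param path TSV with columns `individual`, `intron`, `size`.
#' @return Data frame.
#' @export
read_peaks <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "intron", "size") %in% names(tab)))
  tab
}

#' Population-level locus inference report for one intron
#'
#' @param pop A [population_sample].
#' @param n_loci Hypothesized locus number (default from
#'   [min_locus_count]).
#' @return List with allele count A, gene diversity, minimum locus
#'   number, and observed vs expected multi-heterozygote proportions.
#' @export
locus_inference <- function(pop, n_loci = NULL) {
  fr <- allele_frequencies(pop)
  n_counts <- sum(attr(fr, "counts"))
  he <- gene_diversity(as.numeric(fr), n_counts)
  if (is.null(n_loci)) n_loci <- min_locus_count(pop)
  list(population = pop$name, intron = pop$intron,
       A = length(fr), n_counts = n_counts, gene_diversity = he,
       min_loci = min_locus_count(pop),
       observed_multihet = observed_multiheterozygote(pop, n_loci),
       expected_multihet = expected_multiheterozygote(he, n_loci))
}
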