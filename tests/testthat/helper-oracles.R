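# Independent oracle implementations used to cross-check the package.
# These are deliberately written as literal, standalone transcriptions of
# the published formulas (or brute-force enumerations), sharing no code
# with the package internals.

oracle_pairwise_total <- function(mat) {
  n <- nrow(mat); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / (n * (n - 1) / 2)
}

oracle_tajima <- function(mat) {
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k_hat <- oracle_pairwise_total(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_fu_li_star <- function(mat) {
  n <- nrow(mat)
  eta <- 0; eta_s <- 0
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) < 2) next
    eta <- eta + length(tab) - 1
    eta_s <- eta_s + sum(tab == 1)
  }
  if (eta == 0) return(NA_real_)
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vs <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  us <- n / (n - 1) * (an - n / (n - 1)) - vs
  (n / (n - 1) * eta - an * eta_s) / sqrt(us * eta + vs * eta^2)
}

# brute-force minimum number of recombination points: smallest set of
# inter-site gaps stabbing every four-gamete-incompatible site pair
oracle_rm_bruteforce <- function(mat) {
  cols <- which(apply(mat, 2, function(col) length(unique(col)) == 2))
  m <- length(cols)
  if (m < 2) return(0L)
  pairs <- NULL
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    g <- unique(paste(mat[, cols[i]], mat[, cols[j]]))
    if (length(g) == 4) pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) return(0L)
  gaps <- seq_len(m - 1)  # gap g sits between site g and g+1
  for (k in 0:length(gaps)) {
    if (k == 0) next
    for (sel in combn(length(gaps), k, simplify = FALSE)) {
      ok <- all(apply(pairs, 1, function(pr)
        any(sel >= pr[1] & sel < pr[2])))
      if (ok) return(k)
    }
  }
  length(gaps)
}

# permutation two-sided p for the rank-sum statistic
oracle_wmw_perm <- function(x, y, nperm = 4000, seed = 42) {
  set.seed(seed)
  na <- length(x); z <- c(x, y)
  obs <- abs(sum(rank(z)[1:na]) - na * (length(z) + 1) / 2)
  hits <- 0
  for (i in seq_len(nperm)) {
    idx <- sample(length(z), na)
    if (abs(sum(rank(z)[idx]) - na * (length(z) + 1) / 2) >= obs - 1e-9)
      hits <- hits + 1
  }
  hits / nperm
}

# brute-force minimal-event explanation of one individual's clones:
# over all choices of 1..3 observed haplotypes with clone support of at
# least min_support as basics, each clone costs either its Hamming
# distance to the nearest basic (somatic mutations) or, if expressible
# as a one-breakpoint splice of two basics plus residual mismatches,
# 1 recombination + the residuals; returns the minimal total event count
oracle_min_events <- function(mat, min_support = 2) {
  seqs <- apply(mat, 1, paste, collapse = "")
  tab <- table(seqs)
  haps <- names(tab)[tab >= min_support]
  hm <- t(vapply(haps, function(s) strsplit(s, "")[[1]],
                 character(ncol(mat))))
  nh <- nrow(hm); L <- ncol(mat)
  best <- Inf
  for (k in 1:min(3, nh)) {
    for (bset in combn(nh, k, simplify = FALSE)) {
      total <- 0
      for (r in seq_len(nrow(mat))) {
        cl <- mat[r, ]
        cost <- min(vapply(bset, function(b) sum(cl != hm[b, ]), 0))
        if (k >= 2) {
          for (a in bset) for (b in setdiff(bset, a)) {
            for (bp in 1:(L - 1)) {
              spl <- c(hm[a, 1:bp], hm[b, (bp + 1):L])
              cost <- min(cost, 1 + sum(cl != spl))
            }
          }
        }
        total <- total + cost
      }
      best <- min(best, total)
    }
  }
  best
}
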