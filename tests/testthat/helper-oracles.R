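# independent brute-force oracles; deliberately literal, loop-based
# implementations kept separate from the package's vectorized code paths

# HWE exact p by full enumeration of the conditional heterozygote
# distribution via the closed-form multinomial probability
oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * min(n_hom1, n_hom2) + n_het
  if (na == 0) return(1)
  h <- seq(na %% 2, na, by = 2)
  hr <- (na - h) / 2
  hc <- n - h - hr
  logp <- lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
    h * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[h == n_het]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# oracle probabilities of every heterozygote count for one
# (n individuals, minor allele count) family, plus the exact p per count
oracle_hwe_family <- function(n, na) {
  h <- seq(na %% 2, na, by = 2)
  hr <- (na - h) / 2
  hc <- n - h - hr
  logp <- lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
    h * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p <- vapply(seq_along(h), function(i)
    min(1, sum(probs[probs <= probs[i] * (1 + 1e-9)])), numeric(1))
  list(het = h, hom_rare = hr, hom_common = hc, p = p)
}

# window pass/fail and per-marker hit fractions by explicit enumeration
oracle_window_fraction <- function(geno, params) {
  m <- length(geno)
  w <- params$window_snp
  frac <- numeric(m)
  if (m < w) return(frac)
  nw <- m - w + 1
  pass <- logical(nw)
  for (i in seq_len(nw)) {
    win <- geno[i:(i + w - 1)]
    pass[i] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
      sum(is.na(win)) <= params$window_missing
  }
  for (j in seq_len(m)) {
    wins <- max(1, j - w + 1):min(j, nw)
    frac[j] <- mean(pass[wins])
  }
  frac
}

# ROH calling for one sample on one chromosome by greedy run extension
oracle_roh_one <- function(geno, pos, params) {
  frac <- oracle_window_fraction(geno, params)
  elig <- frac >= params$window_threshold - 1e-12
  segs <- NULL
  m <- length(geno)
  i <- 1
  while (i <= m) {
    if (!elig[i]) {
      i <- i + 1
      next
    }
    j <- i
    while (j < m && elig[j + 1] &&
           (pos[j + 1] - pos[j]) <= params$max_gap * 1000) {
      j <- j + 1
    }
    n_snps <- j - i + 1
    kb <- (pos[j] - pos[i] + 1) / 1000
    if (n_snps >= params$min_snp && kb >= params$min_kb &&
        kb / n_snps <= params$max_density + 1e-12) {
      segs <- rbind(segs, data.frame(start = pos[i], end = pos[j], kb = kb,
                                     n_snps = n_snps))
    }
    i <- j + 1
  }
  segs
}

# recessive/private filter by per-record explicit rule evaluation
oracle_recessive_keep <- function(vt, cfg) {
  keep <- logical(nrow(vt$variants))
  for (i in seq_len(nrow(vt$variants))) {
    ok <- TRUE
    for (s in cfg$cases) {
      g <- vt$geno[i, s]
      required <- if (cfg$mode == "snv") !is.na(g) && g == 2 else
        !is.na(g) && g >= 1
      if (!required) ok <- FALSE
    }
    n_het <- 0
    n_hom <- 0
    for (s in cfg$controls) {
      g <- vt$geno[i, s]
      if (!is.na(g) && g == 1) n_het <- n_het + 1
      if (!is.na(g) && g == 2) n_hom <- n_hom + 1
    }
    if (n_het > cfg$max_het_controls || n_hom > cfg$max_hom_controls) {
      ok <- FALSE
    }
    keep[i] <- ok
  }
  keep
}

# point/span-in-region check by linear scan
oracle_in_regions <- function(vt, regions) {
  v <- vt$variants
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    e <- if (v$class[i] %in% c("SV", "MEI") && !is.na(v$end[i]))
      v$end[i] else v$pos[i]
    for (r in seq_len(nrow(regions))) {
      if (v$chrom[i] == regions$chrom[r] && v$pos[i] <= regions$end[r] &&
          e >= regions$start[r]) {
        keep[i] <- TRUE
      }
    }
  }
  keep
}

# random ROH-scan instance for oracle-equivalence property tests
random_roh_instance <- function(max_markers = 500) {
  m <- sample(80:max_markers, 1)
  pos <- sort(sample.int(m * 40000, m))
  het_rate <- runif(1, 0, 0.3)
  mis_rate <- runif(1, 0, 0.1)
  g <- sample(c(0L, 2L), m, replace = TRUE)
  g[runif(m) < het_rate] <- 1L
  g[runif(m) < mis_rate] <- NA_integer_
  params <- roh_params(
    window_snp = sample(5:50, 1),
    window_het = sample(0:2, 1),
    window_missing = sample(0:2, 1),
    window_threshold = runif(1, 0.01, 0.3),
    min_snp = sample(10:80, 1),
    min_kb = runif(1, 100, 2000),
    max_gap = runif(1, 50, 1000),
    max_density = runif(1, 10, 100))
  list(geno = g, pos = pos, params = params)
}
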