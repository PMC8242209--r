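# Independent oracles used to check the package's estimators.

# Brute-force through-origin slope: iteratively refined grid search over the
# residual sum of squares of (ratio - 1) against slope * conc. Never calls
# the package's closed form.
oracle_slope_grid <- function(conc, ratio, lo = -20, hi = 20, iters = 6,
                              npts = 401) {
  y <- ratio - 1
  rss <- function(b) sum((y - b * conc)^2)
  for (i in seq_len(iters)) {
    grid <- seq(lo, hi, length.out = npts)
    vals <- vapply(grid, rss, 0)
    k <- which.min(vals)
    step <- grid[2] - grid[1]
    lo <- grid[k] - 2 * step
    hi <- grid[k] + 2 * step
  }
  grid[k]
}

# Mid-ranks computed by explicit counting (no rank()).
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

# Spearman as Pearson on mid-ranks, from first principles.
oracle_spearman <- function(a, b) {
  ra <- oracle_midranks(a)
  rb <- oracle_midranks(b)
  ca <- ra - mean(ra)
  cb <- rb - mean(rb)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# Kendall tau-b by exhaustive concordant/discordant pair counting.
oracle_kendall <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- sign(a[j] - a[i])
      sb <- sign(b[j] - b[i])
      if (sa != 0 && sb != 0) {
        if (sa == sb) C <- C + 1 else D <- D + 1
      }
    }
  }
  tie_pairs <- function(x) {
    t <- table(x)
    sum(t * (t - 1) / 2)
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tie_pairs(a)) * (n0 - tie_pairs(b)))
}

# Fixed pool of paired vectors (lengths 3-6, ties common) for rank-statistic
# checks: deterministic patterns plus seeded draws from a small value set.
rank_test_vectors <- function() {
  out <- list(
    list(a = c(1, 2, 3), b = c(1, 2, 3)),
    list(a = c(1, 2, 3), b = c(3, 2, 1)),
    list(a = c(1, 1, 2, 3), b = c(2, 1, 1, 3)),
    list(a = c(1, 2, 2, 3, 5), b = c(2, 1, 4, 4, 5)),
    list(a = c(0, 0, 1, 1, 2, 2), b = c(2, 1, 2, 0, 1, 0))
  )
  set.seed(424242)
  for (n in 3:6) {
    for (k in 1:25) {
      repeat {
        a <- sample(1:4, n, replace = TRUE)
        b <- sample(1:4, n, replace = TRUE)
        if (length(unique(a)) > 1 && length(unique(b)) > 1) break
      }
      out[[length(out) + 1]] <- list(a = a, b = b)
    }
  }
  out
}

# Small random ratio curves for estimator checks.
random_curve <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  conc <- sort(c(0, runif(n - 1, 0.05, 3)))
  slope <- runif(1, -2, 2)
  ratio <- 1 + slope * conc + rnorm(n, 0, 0.05)
  ratio[1] <- 1
  structure(tibble::tibble(conc = conc, ratio = ratio,
                           n_rep = rep(3L, n)),
            class = c("solubility_curve", "tbl_df", "tbl", "data.frame"),
            solute = "Trp", solvent = "Gly", s0 = 1, unfittable = FALSE)
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
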