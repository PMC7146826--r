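# Shared fixtures, built once per test run.

# two-shell neonatal-style scheme (cached: the repulsion solve is the
# expensive part)
fix_scheme <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- neonatal_scheme(seed = 1)
    val
  }
})

# small two-shell scheme for quick fits
fix_small_scheme <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- make_gradient_scheme(4, list(c(750, 20), c(2500, 20)),
                                   seed = 2)
    val
  }
})

# straight tube along x with a Gaussian FA ridge peaking on y=8, z=4
tube_spec <- function(center = c(8, 4), grid = c(20, 16, 8), radius = 3,
                      sigma = 1.4, ...) {
  phantom_spec(grid, list(phantom_tract("x", center, radius = radius,
                                        sigma = sigma)), ...)
}

# independent sort-and-interpolate percentile oracle ((n-1)-spacing rule)
quantile_oracle <- function(x, q) {
  s <- sort(x)
  pos <- q * (length(s) - 1)
  lo <- floor(pos) + 1
  hi <- ceiling(pos) + 1
  s[lo] + (pos - floor(pos)) * (s[hi] - s[lo])
}

# explicit Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# cohort where one feature separates the groups by a wide margin
separable_cohort <- function(n_per = 20, margin = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  df <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("term", "preterm"), each = n_per),
    ga_birth = c(runif(n_per, 37, 41), runif(n_per, 24, 32)),
    ga_scan = runif(n, 41.5, 44),
    stringsAsFactors = FALSE)
  for (m in c("psmd", "psfa", "psad", "psrd", "psndi", "psodi"))
    df[[m]] <- rnorm(n, 0.5, 0.05)
  df$psmd <- ifelse(df$group == "preterm", margin, 0) + rnorm(n, 0, 1)
  as_cohort_table(df)
}
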