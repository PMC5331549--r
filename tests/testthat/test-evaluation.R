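# Independent oracle: textbook Kruskal-Wallis from rank sums with the
# tie correction, computed with explicit loops.
kwOracle <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  start <- 0; H <- 0
  for (g in groups) {
    idx <- seq(start + 1, start + length(g))
    Rj <- sum(r[idx])
    H <- H + Rj^2 / length(g)
    start <- start + length(g)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  tie_counts <- table(x)
  corr <- 1 - sum(tie_counts^3 - tie_counts) / (N^3 - N)
  H / corr
}

test_that("agreement ratios divide componentwise with the under/over semantics", {
  v <- c(energy_kJ = 1000, protein_g = 40, vitamin_C_mg = 30)
  expect_equal(agreementRatio(v, v), c(energy_kJ = 1, protein_g = 1,
                                       vitamin_C_mg = 1))
  r <- agreementRatio(c(energy_kJ = 800, protein_g = 40, vitamin_C_mg = 30), v)
  expect_equal(unname(r["energy_kJ"]), 0.8)
  # reference zero -> undefined, others computed
  r0 <- agreementRatio(c(energy_kJ = 800, protein_g = 40, vitamin_C_mg = 10),
                       c(energy_kJ = 1000, protein_g = 40, vitamin_C_mg = 0))
  expect_true(is.na(r0[["vitamin_C_mg"]]))
  expect_equal(unname(r0["protein_g"]), 1)
  expect_error(agreementRatio(c(a = 1), c(b = 1)), "differ")
})

test_that("ratio reciprocity: ratio(a,b) * ratio(b,a) = 1 componentwise", {
  set.seed(5)
  for (i in 1:10) {
    a <- setNames(runif(5, 1, 100), letters[1:5])
    b <- setNames(runif(5, 1, 100), letters[1:5])
    expect_equal(agreementRatio(a, b) * agreementRatio(b, a),
                 setNames(rep(1, 5), letters[1:5]), tolerance = 1e-12)
  }
})

test_that("ratio summaries report n, both mean families, and degenerate n = 1", {
  r1 <- c(energy_kJ = 0.5); r2 <- c(energy_kJ = 2.0)
  s <- summarizeRatios(list(r1, r2))
  expect_equal(s$geo_mean, 1)
  expect_equal(s$mean, 1.25)
  expect_equal(s$n, 2L)
  s1 <- summarizeRatios(list(r1))
  expect_equal(s1$mean, 0.5)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 1L)
  expect_identical(s1$direction, "under-estimation")
  expect_error(summarizeRatios(list()), "no ratios")
  # undefined components excluded pairwise with per-nutrient n
  s2 <- summarizeRatios(list(c(a = 1, b = NA), c(a = 3, b = 2)))
  expect_equal(s2$n, c(2L, 1L))
})

test_that("geometric SD of simulated multiplicative errors recovers e^sigma", {
  set.seed(20)
  sigma <- 0.3
  ratios <- lapply(1:20, function(i)
    c(energy_kJ = rlnorm(1, 0, sigma)))
  s <- summarizeRatios(ratios)
  expect_equal(log(s$geo_sd), sigma, tolerance = 0.35)
  # and tightens with n
  ratios2 <- lapply(1:2000, function(i) c(energy_kJ = rlnorm(1, 0, sigma)))
  expect_equal(log(summarizeRatios(ratios2)$geo_sd), sigma, tolerance = 0.05)
})

test_that("SUS scoring matches the 2.5-scaled adjusted item sum exhaustively", {
  expect_equal(susScore(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(susScore(rep(3, 10)), 50)
  expect_equal(susScore(c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5)), 0)
  expect_error(susScore(rep(3, 9)), "10 items")
  expect_error(susScore(c(rep(3, 9), 6)), "1..5")
  expect_error(susScore(c(rep(3, 9), 2.5)), "1..5")
  # brute force over the coarse grid {1,3,5}^5 x fixed even items, plus
  # {1..5} sweeps per position
  oracle <- function(items) {
    total <- 0
    for (i in 1:10)
      total <- total + if (i %% 2 == 1) items[i] - 1 else 5 - items[i]
    2.5 * total
  }
  grid <- expand.grid(rep(list(c(1, 3, 5)), 5))
  for (k in seq_len(nrow(grid))) {
    items <- rep(3, 10)
    items[c(1, 3, 5, 7, 9)] <- as.numeric(grid[k, ])
    expect_equal(susScore(items), oracle(items))
    items2 <- rep(3, 10)
    items2[c(2, 4, 6, 8, 10)] <- as.numeric(grid[k, ])
    expect_equal(susScore(items2), oracle(items2))
  }
  for (pos in 1:10) for (v in 1:5) {
    items <- rep(2, 10); items[pos] <- v
    expect_equal(susScore(items), oracle(items))
  }
})

test_that("Kruskal-Wallis matches the textbook rank computation, with and without ties", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  got <- kruskalWallis(g)
  expect_equal(got$H, kwOracle(g), tolerance = 1e-12)
  expect_equal(got$df, 1L)
  tied <- list(c(72, 71, 82, 82), c(83, 72, 90), c(71, 71, 95, 83, 72))
  got2 <- kruskalWallis(tied)
  expect_equal(got2$H, kwOracle(tied), tolerance = 1e-12)
  expect_equal(got2$p, stats::pchisq(kwOracle(tied), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # degenerate: identical groups
  expect_equal(kruskalWallis(list(c(5, 5), c(5, 5)))$H, 0)
  expect_equal(kruskalWallis(list(c(1, 2), c(1, 2)))$H, 0, tolerance = 1e-12)
  expect_error(kruskalWallis(list(c(1, 2))), "at least 2")
  expect_error(kruskalWallis(list(c(1, 2), numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis is invariant to within-group permutation and group relabelling", {
  set.seed(3)
  g <- list(runif(6), runif(5), runif(7))
  base <- kruskalWallis(g)
  perm <- lapply(g, sample)
  expect_equal(kruskalWallis(perm)$H, base$H, tolerance = 1e-12)
  expect_equal(kruskalWallis(g[c(3, 1, 2)])$H, base$H, tolerance = 1e-12)
})
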