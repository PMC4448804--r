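test_that("plug-in and Miller-Madow entropy match the defining sums", {
  e <- entropy_plugin(c(5, 5))
  expect_equal(e$value, log(2), tolerance = 1e-12)
  expect_equal(e$m_nonzero, 2L)

  expect_equal(entropy_plugin(c(10, 0))$value, 0)
  expect_equal(entropy_mm(c(10, 0))$value, 0)  # single occupied cell

  expect_equal(entropy_plugin(c(3, 7))$value,
               -0.3 * log(0.3) - 0.7 * log(0.7), tolerance = 1e-12)
  expect_equal(entropy_mm(c(3, 7))$value,
               -0.3 * log(0.3) - 0.7 * log(0.7) + 0.05, tolerance = 1e-12)
  expect_equal(entropy_mm(c(5, 5))$value, log(2) + 1 / 20, tolerance = 1e-12)

  expect_error(entropy_plugin(c(0, 0)), "zero")
  expect_error(entropy_plugin(c(-1, 2)), "non-negative")
})

test_that("mi_mm handles perfect dependence, factorizing tables and the
           published ischemia-by-CFR example", {
  x <- rep(0:1, each = 50)
  expect_equal(as.numeric(mi_mm(x, x)), entropy_mm(c(50, 50))$value,
               tolerance = 1e-12)

  # exactly factorizing 2x2: plug-in MI is 0 and only the MM correction
  # residual -(1/8) remains (2 + 2 - 4 occupied cells over 2n = 8)
  expect_equal(as.numeric(mi_mm(c(0, 0, 1, 1), c(0, 1, 0, 1), min_n = 4)),
               -1 / 8, tolerance = 1e-12)
  expect_equal(as.numeric(mi_mm(c(0, 0, 1, 1), c(0, 1, 0, 1), min_n = 4,
                                estimator = "plugin")), 0, tolerance = 1e-12)

  # 2x2 table reconstructed from the reported cohort cross-tabulation
  tab <- ischemia_cfr_table()
  expect_equal(sum(tab), 4313)
  v <- vectors_from_table(c(tab["no", "no"], tab["yes", "no"],
                            tab["no", "yes"], tab["yes", "yes"]))
  expect_equal(as.numeric(mi_mm(v$x, v$y)), 0.05482154, tolerance = 1e-7)
  expect_equal(as.numeric(mi_mm(v$x, v$y)),
               oracle_mi_mm(c(2645, 249, 903, 516)), tolerance = 1e-12)

  # constant vector: MI 0 with a degeneracy flag
  z <- mi_mm(rep(1, 50), rbinom(50, 1, 0.5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))

  expect_error(mi_mm(c(0, 1, NA), c(1, NA, 0), min_n = 2), "complete pairs")
})

test_that("MM entropy/MI agree with brute-force evaluation on random tables
           and respect symmetry and plug-in bounds", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    v <- vectors_from_table(cells)
    mi_xy <- mi_mm(v$x, v$y, min_n = 1)
    mi_yx <- mi_mm(v$y, v$x, min_n = 1)
    expect_identical(as.numeric(mi_xy), as.numeric(mi_yx))
    if (!attr(mi_xy, "degenerate")) {
      expect_equal(as.numeric(mi_xy), oracle_mi_mm(cells), tolerance = 1e-12)
      plug <- as.numeric(mi_mm(v$x, v$y, min_n = 1, estimator = "plugin"))
      hx <- oracle_h_plugin(c(sum(v$x == 0), sum(v$x == 1)))
      hy <- oracle_h_plugin(c(sum(v$y == 0), sum(v$y == 1)))
      expect_gte(plug, -1e-12)
      expect_lte(plug, min(hx, hy, log(2)) + 1e-12)
    }
  }
})

test_that("pairwise_mi fills a symmetric matrix with MM entropies on the
           diagonal and flags duplicated columns", {
  set.seed(1)
  x <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, 0.6)
  tab <- cbind(a = x, b = y, a_copy = x)
  m <- pairwise_mi(tab)
  expect_identical(m$values, t(m$values))
  expect_equal(m$values["a", "a"], h <- entropy_mm(tabulate(1 + x, 2))$value)
  # duplicated column: off-diagonal equals the diagonal entropy
  expect_equal(m$values["a", "a_copy"], m$values["a", "a"], tolerance = 1e-12)
  expect_equal(as.numeric(m$values["a", "b"]),
               as.numeric(mi_mm(x, y)), tolerance = 1e-15)
})

test_that("hypergeometric permutation replicates match full enumeration of
           all permutations at small n", {
  # under a uniform random permutation of y the joint count a is exactly
  # hypergeometric; verify against enumeration of all n! permutations
  x <- c(1, 1, 1, 0, 0, 0)
  y <- c(1, 1, 0, 0, 0, 0)
  n <- length(y)
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  expect_equal(nrow(perms), factorial(n))
  a_all <- apply(perms, 1, function(p) sum(x == 1 & y[p] == 1))
  enum_freq <- tabulate(a_all + 1, 3) / length(a_all)
  hyper_freq <- stats::dhyper(0:2, sum(x), n - sum(x), sum(y))
  expect_equal(enum_freq, hyper_freq, tolerance = 1e-12)
})

test_that("permutation p-values are reproducible, maximal under perfect
           dependence and 1 for constant input", {
  set.seed(99)
  x <- rbinom(200, 1, 0.5)
  cfg <- perm_config(B = 999, seed = 7)
  p <- permutation_pvalue(x, x, cfg)
  expect_equal(as.numeric(p), 1 / 1000)  # nothing beats the maximal MI
  expect_lte(as.numeric(p), 0.005)
  # determinism + order independence of the estimator's attributes
  p2 <- permutation_pvalue(x, x, cfg)
  expect_identical(as.numeric(p), as.numeric(p2))

  expect_equal(as.numeric(permutation_pvalue(rep(1, 100), rbinom(100, 1, 0.5),
                                             cfg)), 1)

  # empirical estimator can reach 0; add-one cannot
  y <- 1L - x
  pe <- permutation_pvalue(x, y, perm_config(B = 199, seed = 3,
                                             estimator = "empirical"))
  expect_equal(as.numeric(pe), 0)
})

test_that("Bonferroni adjustment multiplies by the pair count and caps at 1", {
  mk <- function(k, p) {
    m <- matrix(p, k, k, dimnames = list(paste0("v", 1:k), paste0("v", 1:k)))
    diag(m) <- NA
    m
  }
  s <- bonferroni_adjust(mk(29, 0.001))
  expect_equal(s$n_tests, 406)
  expect_equal(s$adjusted_p[1, 2], 0.406, tolerance = 1e-12)

  expect_equal(bonferroni_adjust(mk(29, 0.5))$adjusted_p[1, 2], 1)

  s2 <- bonferroni_adjust(mk(17, 1 / 5001))
  expect_equal(s2$n_tests, 136)
  expect_equal(s2$adjusted_p[1, 2], 136 / 5001, tolerance = 1e-12)

  expect_error(bonferroni_adjust(mk(3, 1.5)), "0, 1")
})

test_that("permutation p-values are super-uniform under independence at
           nominal levels", {
  set.seed(2024)
  n <- 400
  reps <- 600
  cfg0 <- perm_config(B = 199, seed = 0)
  pv <- vapply(seq_len(reps), function(r) {
    cfg0$seed <- r
    as.numeric(permutation_pvalue(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), cfg0))
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.10)) {
    tol <- 3 * sqrt(alpha * (1 - alpha) / reps)
    expect_lte(mean(pv < alpha), alpha + tol)
  }
})

test_that("MM correction reduces the downward bias of the plug-in entropy", {
  set.seed(5)
  for (n in c(10, 20, 50)) {
    reps <- 4000
    h_true <- log(2)
    plug <- mm <- numeric(reps)
    for (r in seq_len(reps)) {
      cnt <- tabulate(1 + rbinom(n, 1, 0.5), 2)
      plug[r] <- entropy_plugin(cnt)$value
      mm[r] <- entropy_mm(cnt)$value
    }
    expect_lt(abs(mean(mm) - h_true), abs(mean(plug) - h_true))
    expect_lt(mean(plug), h_true)
  }
})
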