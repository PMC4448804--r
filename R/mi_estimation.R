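#' Plug-in (maximum-likelihood) entropy of a discrete distribution
#'
#' Computes the entropy of the empirical probability distribution from a
#' vector of cell counts, in nats: \eqn{H = -\sum_i (c_i/n) \ln(c_i/n)} over
#' the non-empty cells.
#'
#' @param cell_counts Non-negative integer vector of cell counts; must sum
#'   to at least 1.
#' @return An object of class `entropy_estimate`: a list with `value`
#'   (nats), `n` (sample size) and `m_nonzero` (number of occupied cells).
#' @seealso [entropy_mm()] for the bias-corrected version.
#' @examples
#' entropy_plugin(c(5, 5))   # ln 2
#' entropy_plugin(c(3, 7))
#' @export
entropy_plugin <- function(cell_counts) {
  cell_counts <- check_counts(cell_counts)
  n <- sum(cell_counts)
  nz <- cell_counts[cell_counts > 0]
  p <- nz / n
  structure(
    list(value = -sum(p * log(p)), n = n, m_nonzero = length(nz),
         estimator = "plugin"),
    class = "entropy_estimate"
  )
}

#' Miller-Madow bias-corrected entropy
#'
#' The plug-in entropy underestimates the true entropy at finite sample
#' sizes; the Miller-Madow estimator adds the first-order correction
#' \eqn{(m - 1) / (2n)}, where `m` is the number of occupied cells and `n`
#' the sample size.
#'
#' @inheritParams entropy_plugin
#' @return An `entropy_estimate` (see [entropy_plugin()]); `value` is in
#'   nats.
#' @examples
#' entropy_mm(c(5, 5))  # ln 2 + 1/20
#' @export
entropy_mm <- function(cell_counts) {
  est <- entropy_plugin(cell_counts)
  est$value <- est$value + (est$m_nonzero - 1) / (2 * est$n)
  est$estimator <- "miller-madow"
  est
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("%s entropy: %.6f nats (n = %d, occupied cells = %d)\n",
              x$estimator, x$value, x$n, x$m_nonzero))
  invisible(x)
}

check_counts <- function(cell_counts) {
  if (!is.numeric(cell_counts) || any(is.na(cell_counts)) ||
      any(cell_counts < 0) || any(cell_counts != floor(cell_counts))) {
    stop("cell_counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cell_counts) < 1) stop("all cell counts are zero", call. = FALSE)
  as.integer(cell_counts)
}

# Bare numeric MM entropy of counts (internal fast path).
h_mm_num <- function(cell_counts) {
  n <- sum(cell_counts)
  nz <- cell_counts[cell_counts > 0]
  p <- nz / n
  -sum(p * log(p)) + (length(nz) - 1) / (2 * n)
}

h_plugin_num <- function(cell_counts) {
  n <- sum(cell_counts)
  nz <- cell_counts[cell_counts > 0]
  p <- nz / n
  -sum(p * log(p))
}

# Pairwise-complete 0/1 filtering shared by mi_mm and permutation_pvalue.
complete_binary_pair <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- as.integer(x[keep]); y <- as.integer(y[keep])
  if (any(!x %in% c(0L, 1L)) || any(!y %in% c(0L, 1L))) {
    stop("x and y must be 0/1 vectors (NA allowed)", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop(sprintf("only %d complete pairs; need at least %d", length(x), min_n),
         call. = FALSE)
  }
  list(x = x, y = y)
}

#' Miller-Madow mutual information between two binary vectors
#'
#' Estimates \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)} from the 2x2 contingency
#' table of pairwise-complete observations, with every entropy estimated by
#' the Miller-Madow estimator ([entropy_mm()]).  Because the three bias
#' corrections do not cancel, the MM MI can be slightly negative (or exceed
#' the plug-in bound) for near-independent tables; values are reported as
#' computed.  When either vector is constant the MI is 0 by definition and
#' the result carries a `degenerate` attribute.
#'
#' @param x,y 0/1 vectors of equal length; `NA` entries are dropped
#'   pairwise.
#' @param min_n Minimum number of complete pairs required (default 10).
#' @param estimator `"mm"` (default) or `"plugin"`.
#' @return MI in nats (a bare numeric).  Attribute `degenerate` is `TRUE`
#'   when either margin is constant.
#' @examples
#' x <- rep(0:1, each = 50)
#' mi_mm(x, x)        # equals the MM entropy of x
#' mi_mm(x, rev(x))
#' @export
mi_mm <- function(x, y, min_n = 10, estimator = c("mm", "plugin")) {
  estimator <- match.arg(estimator)
  xy <- complete_binary_pair(x, y, min_n)
  x <- xy$x; y <- xy$y
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(structure(0, degenerate = TRUE))
  }
  h <- if (estimator == "mm") h_mm_num else h_plugin_num
  joint <- tabulate(1L + x + 2L * y, nbins = 4L)
  mi <- h(tabulate(1L + x, 2L)) + h(tabulate(1L + y, 2L)) - h(joint)
  structure(mi, degenerate = FALSE)
}

#' Pairwise Miller-Madow MI matrix
#'
#' Computes the symmetric k x k matrix of pairwise MM mutual information
#' for every pair of columns of a binary patient table.  The diagonal holds
#' each variable's own MM entropy.  Plug-in MI values are stored alongside
#' for bound checks.
#'
#' @param table Numeric matrix with entries in \{0, 1, NA\}, one column per
#'   variable; column names are the variable IDs.
#' @param min_n Minimum complete pairs per entry; pairs below it are set to
#'   `NA` with a warning.
#' @return An object of class `mi_matrix`: list with `variable_ids`,
#'   `values` (MM, nats; diagonal = MM entropy), `plugin` (plug-in MI,
#'   diagonal = plug-in entropy) and `n` (rows of `table`).
#' @export
pairwise_mi <- function(table, min_n = 10) {
  table <- check_binary_table(table)
  k <- ncol(table)
  if (k < 2) stop("need at least 2 variables", call. = FALSE)
  ids <- colnames(table)
  mm <- plug <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    ci <- table[, i][!is.na(table[, i])]
    if (length(ci)) {
      mm[i, i] <- h_mm_num(tabulate(1L + ci, 2L))
      plug[i, i] <- h_plugin_num(tabulate(1L + ci, 2L))
    }
  }
  dropped <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      mi <- tryCatch(mi_mm(table[, i], table[, j], min_n = min_n),
                     error = function(e) NA_real_)
      if (is.na(mi)) dropped <- c(dropped, paste(ids[i], ids[j], sep = "--"))
      mm[i, j] <- mm[j, i] <- as.numeric(mi)
      pl <- tryCatch(
        as.numeric(mi_mm(table[, i], table[, j], min_n = min_n,
                         estimator = "plugin")),
        error = function(e) NA_real_)
      plug[i, j] <- plug[j, i] <- pl
    }
  }
  if (length(dropped)) {
    warning(sprintf("%d pair(s) below min_n were set to NA: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  structure(list(variable_ids = ids, values = mm, plugin = plug,
                 n = nrow(table)),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  k <- length(x$variable_ids)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("MI matrix: %d variables, n = %d; off-diagonal MM MI range [%.4g, %.4g] nats\n",
              k, x$n, min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Permutation test configuration
#'
#' @param B Number of random permutations (default 5000).
#' @param seed Integer root seed.
#' @param estimator p-value estimator: `"add_one"` (default), the valid
#'   Monte Carlo estimator \eqn{(r + 1)/(B + 1)} that never returns 0, or
#'   `"empirical"`, the raw proportion \eqn{r/B}, which can return 0 and is
#'   the only choice under which a Bonferroni threshold below \eqn{1/(B+1)}
#'   is attainable.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(B = 5000, seed = 1, estimator = c("add_one", "empirical")) {
  if (!is.numeric(B) || length(B) != 1 || B < 1) stop("B must be >= 1", call. = FALSE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 estimator = match.arg(estimator)),
            class = "perm_config")
}

# MM MI of the 2x2 table with margins (rx, ry) out of n and joint count a,
# vectorized over a.  Under permutation of y the margins are fixed, so the
# MI of every permuted pair is this function of a alone.
mi_given_margins <- function(a, n, rx, ry) {
  hp <- function(cnt) {
    p <- cnt / n
    out <- p * log(p)
    out[cnt == 0] <- 0
    out
  }
  m_joint <- (a > 0) + (rx - a > 0) + (ry - a > 0) + (n - rx - ry + a > 0)
  h_joint <- -(hp(a) + hp(rx - a) + hp(ry - a) + hp(n - rx - ry + a)) +
    (m_joint - 1) / (2 * n)
  hx <- -(hp(rx) + hp(n - rx)) + ((rx > 0) + (n - rx > 0) - 1) / (2 * n)
  hy <- -(hp(ry) + hp(n - ry)) + ((ry > 0) + (n - ry > 0) - 1) / (2 * n)
  hx + hy - h_joint
}

#' Monte Carlo permutation p-value for the MM MI of a binary pair
#'
#' Compares the observed MM MI with its distribution over `B` uniformly
#' random permutations of `y` (only), counting ties as exceedances.  With
#' the default `"add_one"` estimator, \eqn{p = (r + 1)/(B + 1)} where `r`
#' is the exceedance count; `"empirical"` gives \eqn{r/B}, which can be 0.
#'
#' Permuting `y` leaves both margins of the 2x2 table fixed, so the table
#' -- and hence the MI -- of a permuted pair depends only on the joint
#' count \eqn{a = \#\{x = 1, y = 1\}}, whose exact distribution under a
#' uniformly random permutation is hypergeometric.  Each replicate is
#' therefore realized as one hypergeometric draw, which is equivalent to
#' shuffling `y` but O(1) per permutation.  Seeded and reproducible; at
#' matrix level a per-pair seed is derived from the root seed and the
#' ordered variable names, so results do not depend on evaluation order.
#'
#' @inheritParams mi_mm
#' @param cfg A [perm_config()].
#' @return Raw p-value in \[0, 1\] with attributes `mi` (observed MM MI)
#'   and `n_ge` (exceedance count).
#' @export
permutation_pvalue <- function(x, y, cfg = perm_config(), min_n = 10) {
  stopifnot(inherits(cfg, "perm_config"))
  xy <- complete_binary_pair(x, y, min_n)
  x <- xy$x; y <- xy$y
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    # constant margin: MI is identically 0 under every permutation
    return(structure(1, mi = 0, n_ge = cfg$B))
  }
  n <- length(x)
  rx <- sum(x); ry <- sum(y)
  obs <- mi_given_margins(sum(x == 1L & y == 1L), n, rx, ry)
  set.seed(cfg$seed)
  a_perm <- stats::rhyper(cfg$B, rx, n - rx, ry)
  r <- sum(mi_given_margins(a_perm, n, rx, ry) >= obs - 1e-12)
  p <- if (cfg$estimator == "add_one") (r + 1) / (cfg$B + 1) else r / cfg$B
  structure(p, mi = obs, n_ge = r)
}

# Stable 31-adic string hash into [0, 2^31 - 2]; used to derive per-pair
# and per-variable RNG streams from a root seed.
stable_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

derive_seed <- function(root, ...) {
  as.integer((root + stable_hash(paste(..., sep = "\r"))) %% 2147483647)
}

#' Permutation p-values for every variable pair
#'
#' Runs [permutation_pvalue()] for all k(k-1)/2 column pairs of a binary
#' table and applies the Bonferroni correction via [bonferroni_adjust()].
#'
#' @inheritParams pairwise_mi
#' @param cfg A [perm_config()]; each pair gets its own RNG stream derived
#'   from `cfg$seed` and the pair's variable names.
#' @return A `mi_significance` object (see [bonferroni_adjust()]), with the
#'   permutation settings recorded.
#' @export
mi_significance <- function(table, cfg = perm_config(), min_n = 10) {
  table <- check_binary_table(table)
  ids <- colnames(table)
  k <- ncol(table)
  if (k < 2) stop("need at least 2 variables", call. = FALSE)
  raw <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pair_cfg <- cfg
      pair_cfg$seed <- derive_seed(cfg$seed, ids[i], ids[j])
      p <- tryCatch(
        permutation_pvalue(table[, i], table[, j], pair_cfg, min_n = min_n),
        error = function(e) NA_real_)
      raw[i, j] <- raw[j, i] <- as.numeric(p)
    }
  }
  sig <- bonferroni_adjust(raw)
  sig$B <- cfg$B
  sig$estimator <- cfg$estimator
  sig$seed <- cfg$seed
  sig
}

#' Bonferroni adjustment of a symmetric p-value matrix
#'
#' Multiplies each off-diagonal p-value by the number of tests
#' k(k-1)/2 and caps at 1.
#'
#' @param raw_p Symmetric matrix of raw p-values in (0, 1\] (NA allowed).
#' @return An object of class `mi_significance`: list with `raw_p`,
#'   `adjusted_p` and `n_tests`.
#' @export
bonferroni_adjust <- function(raw_p) {
  if (!is.matrix(raw_p) || nrow(raw_p) != ncol(raw_p)) {
    stop("raw_p must be a square matrix", call. = FALSE)
  }
  off <- raw_p[upper.tri(raw_p)]
  if (any(!is.na(off) & (off < 0 | off > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  k <- nrow(raw_p)
  n_tests <- k * (k - 1) / 2
  adj <- raw_p * n_tests
  adj[!is.na(adj) & adj > 1] <- 1
  diag(adj) <- NA_real_
  structure(list(raw_p = raw_p, adjusted_p = adj, n_tests = n_tests),
            class = "mi_significance")
}

#' @export
print.mi_significance <- function(x, ...) {
  off <- x$adjusted_p[upper.tri(x$adjusted_p)]
  cat(sprintf("Permutation significance: %d tests, %d adjusted p <= 0.05\n",
              x$n_tests, sum(off <= 0.05, na.rm = TRUE)))
  invisible(x)
}

# Shared validation: numeric matrix, entries 0/1/NA, unique column names.
check_binary_table <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table)) stop("table must be a matrix", call. = FALSE)
  if (is.null(colnames(table)) || anyDuplicated(colnames(table))) {
    stop("table must have unique column names (variable IDs)", call. = FALSE)
  }
  vals <- table[!is.na(table)]
  if (any(!vals %in% c(0, 1))) {
    stop("table entries must be 0, 1 or NA", call. = FALSE)
  }
  storage.mode(table) <- "integer"
  table
}

#' Export a square matrix as delimited text with ID header row/column
#'
#' @param m Square matrix with dimnames (e.g. `values` of a `mi_matrix`).
#' @param path Output file.
#' @param sep Field separator (default tab).
#' @export
write_matrix <- function(m, path, sep = "\t") {
  utils::write.table(m, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
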