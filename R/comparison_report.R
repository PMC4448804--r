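#' Default restricted variable panel for the 17-node network
#'
#' The smaller network configuration uses only the variables reported as
#' significant in the reference Cox analysis of the same cohort, plus the
#' endpoint.  The exact panel was defined by that earlier study; this
#' default reconstructs it from the variables the comparison discusses and
#' is configurable wherever it is consumed.
#'
#' @return Character vector of 16 variable IDs (endpoint not included).
#' @export
restricted_variables <- function() {
  c("age", "sex", "diabetes", "hypert", "hyperchol", "smoke", "family",
    "Prev_IM", "Prev_PCI", "LBBB", "RWMA", "CFR", "Rest_vel_LAD",
    "Rest_WMSI", "Isch_SE", "Known_CAD")
}

#' Assemble the per-variable method score table
#'
#' For every non-endpoint variable, collects the three association scores
#' the cross-method comparison uses: the multivariate Cox hazard ratio,
#' the pairwise MM MI with the endpoint, and the shortest inverse-MI
#' network distance to the endpoint.  Variables missing a score (e.g.
#' unreachable in the network, or a failed fit) are flagged unavailable
#' rather than zero-filled.
#'
#' @param fit A multivariate `cox_fit`.
#' @param mi A `mi_matrix`.
#' @param paths A `path_report` targeted at the endpoint.
#' @param endpoint Endpoint variable ID.
#' @return A data.frame of class `method_scores`: `variable`, `hr`,
#'   `mi_to_endpoint`, `min_distance`, `hr_available`, `mi_available`,
#'   `dist_available`.
#' @export
method_scores <- function(fit, mi, paths, endpoint) {
  if (!endpoint %in% mi$variable_ids) {
    stop(sprintf("endpoint '%s' absent from the MI matrix", endpoint), call. = FALSE)
  }
  if (!identical(attr(paths, "target"), endpoint)) {
    stop("path report does not target the endpoint", call. = FALSE)
  }
  vars <- setdiff(mi$variable_ids, endpoint)
  hr <- stats::setNames(fit$coefficients$hr, fit$coefficients$variable)[vars]
  mi_end <- mi$values[vars, endpoint]
  dist <- stats::setNames(paths$distance, paths$variable)[vars]
  out <- data.frame(
    variable = vars,
    hr = unname(hr),
    mi_to_endpoint = unname(mi_end),
    min_distance = unname(dist),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$hr_available <- !is.na(out$hr)
  out$mi_available <- !is.na(out$mi_to_endpoint)
  out$dist_available <- is.finite(out$min_distance)
  out$min_distance[!out$dist_available] <- Inf
  structure(out, class = c("method_scores", "data.frame"), endpoint = endpoint)
}

#' Per-method z-scores of the comparison scores
#'
#' Standardizes each method's scores over the variables where the score is
#' available, using the population standard deviation (divide by n).  By
#' default the network distance is negated before standardization so that
#' a larger z means a stronger association for every method; set
#' `orient_distance = FALSE` to standardize the raw distances instead.
#'
#' @param scores A `method_scores` data.frame.
#' @param orient_distance Negate distances before standardizing (default
#'   `TRUE`).
#' @param log_hr Standardize log HRs instead of raw HRs (default `FALSE`).
#' @return A data.frame: `variable`, `z_hr`, `z_mi`, `z_dist` (NA where a
#'   score is unavailable).  Each finite column has mean 0 and population
#'   sd 1.
#' @export
zscore_table <- function(scores, orient_distance = TRUE, log_hr = FALSE) {
  zstd <- function(v, method) {
    ok <- !is.na(v) & is.finite(v)
    if (sum(ok) < 2) stop(sprintf("fewer than 2 available values for %s", method),
                          call. = FALSE)
    s <- sqrt(mean((v[ok] - mean(v[ok]))^2))
    if (s == 0) stop(sprintf("zero variance for method '%s'", method), call. = FALSE)
    out <- rep(NA_real_, length(v))
    out[ok] <- (v[ok] - mean(v[ok])) / s
    out
  }
  hr <- if (log_hr) log(scores$hr) else scores$hr
  dist <- if (orient_distance) -scores$min_distance else scores$min_distance
  data.frame(
    variable = scores$variable,
    z_hr = zstd(hr, "HR"),
    z_mi = zstd(scores$mi_to_endpoint, "MI"),
    z_dist = zstd(dist, "MIN distance"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Spearman rank concordance between the three methods
#'
#' Rank correlation of each method pair over the variables where both
#' scores are available, after orienting all methods so that larger values
#' mean stronger association (distances are negated).
#'
#' @param scores A `method_scores` data.frame.
#' @return A data.frame: `method_a`, `method_b`, `spearman`, `n`.
#' @export
rank_concordance <- function(scores) {
  vals <- list(hr = scores$hr, mi = scores$mi_to_endpoint,
               dist = -scores$min_distance)
  combos <- utils::combn(names(vals), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- vals[[combos[1, i]]]; b <- vals[[combos[2, i]]]
    ok <- !is.na(a) & !is.na(b) & is.finite(a) & is.finite(b)
    if (sum(ok) < 3) stop("fewer than 3 shared available variables", call. = FALSE)
    data.frame(method_a = combos[1, i], method_b = combos[2, i],
               spearman = stats::cor(a[ok], b[ok], method = "spearman"),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dot chart of the cross-method z-scores
#'
#' Best-effort companion plot: one dot per variable and method, variables
#' ordered by the network-distance z-score.  Layout is not part of any
#' tested contract.
#'
#' @param z A z-score table from [zscore_table()].
#' @export
plot_zscores <- function(z) {
  ord <- order(z$z_dist, na.last = FALSE)
  z <- z[ord, ]
  graphics::dotchart(z$z_hr, labels = z$variable, xlim = range(
    c(z$z_hr, z$z_mi, z$z_dist), na.rm = TRUE), pch = 16,
    xlab = "z-score (larger = stronger association)")
  graphics::points(z$z_mi, seq_len(nrow(z)), pch = 17, col = "firebrick")
  graphics::points(z$z_dist, seq_len(nrow(z)), pch = 15, col = "steelblue")
  graphics::legend("bottomright", legend = c("HR", "MI", "-distance"),
                   pch = c(16, 17, 15),
                   col = c("black", "firebrick", "steelblue"), bty = "n")
  invisible(z)
}

#' Run the full MIN + Cox comparison pipeline
#'
#' Executes cohort generation (or loading + binarization), pairwise MM MI,
#' permutation significance with Bonferroni control, significance and DPI
#' pruning, network assembly, path/centrality/module/edge-class analyses,
#' the Cox baseline (univariate screen + multivariate fit) and the
#' cross-method comparison.  Deterministic given the seeds in `config`.
#'
#' `config` is a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{synthetic}{a `cohort_spec`, or `TRUE` for [default_spec()]
#'     (mutually exclusive with `input`).}
#'   \item{input}{path to a raw delimited patient table; binarized with
#'     [default_rules()].  Requires `survival_input`, a two-column
#'     time/status file, for the Cox stage.}
#'   \item{variables}{optional restriction of the variable panel (the
#'     endpoint is always retained).}
#'   \item{endpoint}{endpoint ID (default `"death"`).}
#'   \item{perm}{a [perm_config()].}
#'   \item{prune}{a [prune_config()].}
#'   \item{min_n}{minimum complete pairs per MI entry (default 10).}
#'   \item{outdir}{optional output directory for report files and the JSON
#'     run manifest.}
#' }
#'
#' If `B` is too small for the Bonferroni threshold to be attainable
#' (i.e. the smallest possible raw p-value exceeds `T / n_tests`), a
#' warning explains that no edge can reach significance.
#'
#' @param config List or JSON path as described above.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `min_pipeline` with elements `cohort`, `mi`,
#'   `sig`, `edges_significant`, `edges_pruned`, `network`, `paths`,
#'   `centrality`, `modules`, `edge_classes`, `cox_multi`, `cox_screen`,
#'   `scores`, `zscores`, `concordance`, `manifest`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  endpoint <- config$endpoint %||% "death"
  perm <- config$perm %||% perm_config()
  prune <- config$prune %||% prune_config()
  min_n <- config$min_n %||% 10
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say(name, "done in %.2fs", proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- NULL
  if (!is.null(config$input)) {
    table <- stage("binarize", {
      raw <- load_raw_table(config$input)
      binarize(raw, default_rules())
    })
    surv <- NULL
    if (!is.null(config$survival_input)) {
      sv <- utils::read.csv(config$survival_input)
      surv <- data.frame(time = sv$time, status = sv$status)
    }
  } else {
    spec <- if (isTRUE(config$synthetic) || is.null(config$synthetic)) {
      default_spec()
    } else {
      config$synthetic
    }
    cohort <- stage("simulate", generate_cohort(spec))
    table <- cohort$table
    surv <- cohort$survival
  }
  if (!is.null(config$variables)) {
    keep <- union(config$variables, endpoint)
    table <- table[, intersect(colnames(table), keep), drop = FALSE]
  }
  if (!endpoint %in% colnames(table)) {
    stop(sprintf("endpoint '%s' missing from the table", endpoint), call. = FALSE)
  }
  k <- ncol(table)
  n_tests <- k * (k - 1) / 2
  min_p <- if (perm$estimator == "add_one") 1 / (perm$B + 1) else 0
  if (min_p * n_tests > prune$T) {
    warning(sprintf(paste0(
      "B = %d cannot resolve the Bonferroni threshold %.3g/%d: the smallest ",
      "attainable adjusted p is %.3g, so no edge can be significant; ",
      "use B >= %d or estimator = 'empirical'"),
      perm$B, prune$T, n_tests, min_p * n_tests,
      ceiling(n_tests / prune$T)), call. = FALSE)
  }

  mi <- stage("mi", pairwise_mi(table, min_n = min_n))
  sig <- stage("significance", mi_significance(table, perm, min_n = min_n))
  edges_sig <- stage("filter", significant_edges(mi, sig, prune))
  edges_pruned <- stage("dpi", dpi_prune(edges_sig, prune$epsilon))
  say("dpi", "%d candidate -> %d significant -> %d after DPI",
      n_tests, nrow(edges_sig), nrow(edges_pruned))
  net <- stage("network", build_network(edges_pruned, variables = colnames(table)))
  paths <- stage("paths", shortest_paths_to(net, endpoint))
  centr <- stage("centrality", centralities(net))
  modules <- if (igraph::ecount(net) > 0) {
    stage("modules", detect_modules(net, seed = perm$seed))
  } else NULL
  classes <- if (igraph::ecount(net) > 0) {
    stage("edge-classes", classify_edge_strength(net))
  } else NULL

  cox_multi <- cox_scr <- scores <- zs <- conc <- NULL
  if (!is.null(surv)) {
    records <- as_surv_records(surv$time, surv$status,
                               table[, setdiff(colnames(table), endpoint),
                                     drop = FALSE])
    cox_scr <- stage("cox-screen", univariate_screen(records))
    cox_multi <- stage("cox-multi", {
      # drop constants and binary covariates with no events in one arm
      # (monotone partial likelihood); they keep their univariate entry
      ok <- apply(records$X, 2, function(v) {
        length(unique(v)) > 1 &&
          all(tapply(records$status, v, sum, default = 0) > 0)
      })
      if (any(!ok)) say("cox-multi", "excluded from multivariate fit: %s",
                        paste(colnames(records$X)[!ok], collapse = ", "))
      fit_cox(records, covariates = colnames(records$X)[ok])
    })
    scores <- stage("compare", method_scores(cox_multi, mi, paths, endpoint))
    zs <- tryCatch(zscore_table(scores), error = function(e) NULL)
    conc <- tryCatch(rank_concordance(scores), error = function(e) NULL)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("minprog")),
    endpoint = endpoint,
    n_patients = nrow(table),
    n_variables = k,
    n_tests = n_tests,
    perm = unclass(perm),
    prune = unclass(prune),
    counts = list(candidate_pairs = n_tests,
                  significant_edges = nrow(edges_sig),
                  pruned_edges = nrow(edges_pruned),
                  modules = if (!is.null(modules)) modules$n_modules else 0),
    seeds = list(root = perm$seed,
                 cohort = if (!is.null(cohort)) cohort$spec$seed else NULL)
  )

  bundle <- structure(
    list(cohort = cohort, table = table, mi = mi, sig = sig,
         edges_significant = edges_sig, edges_pruned = edges_pruned,
         network = net, paths = paths, centrality = centr, modules = modules,
         edge_classes = classes, cox_multi = cox_multi, cox_screen = cox_scr,
         scores = scores, zscores = zs, concordance = conc,
         manifest = manifest),
    class = "min_pipeline"
  )
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all pipeline report files
#'
#' Emits the MI and adjusted-p matrices, edge lists (pre/post DPI), the
#' GraphML network (with strength classes when available), per-node
#' centralities and modules, path, HR, score, z-score and concordance
#' tables, and a JSON run manifest.
#'
#' @param bundle A `min_pipeline` result.
#' @param dir Output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix(bundle$mi$values, fp("mi_matrix.tsv"))
  write_matrix(bundle$sig$adjusted_p, fp("adjusted_p.tsv"))
  utils::write.table(bundle$edges_significant, fp("edges_significant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$edges_pruned, fp("edges_pruned.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- bundle$network
  if (!is.null(bundle$edge_classes)) {
    igraph::E(net)$strength_class <- bundle$edge_classes$class
  }
  export_network(net, fp("network.graphml"), format = "graphml")
  export_network(net, fp("network_edges.tsv"), format = "edgelist")
  utils::write.table(bundle$paths, fp("paths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  centr <- bundle$centrality
  if (!is.null(bundle$modules)) {
    centr$module <- bundle$modules$membership[centr$variable]
  }
  utils::write.table(centr, fp("centrality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$cox_screen)) {
    write_hr_table(bundle$cox_screen, fp("cox_univariate.tsv"))
  }
  if (!is.null(bundle$cox_multi)) {
    write_hr_table(bundle$cox_multi, fp("cox_multivariate.tsv"))
  }
  if (!is.null(bundle$scores)) {
    utils::write.table(bundle$scores, fp("method_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$zscores)) {
    utils::write.table(bundle$zscores, fp("zscores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$concordance)) {
    utils::write.table(bundle$concordance, fp("concordance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.min_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("MIN pipeline: %d patients, %d variables (endpoint '%s')\n",
              m$n_patients, m$n_variables, m$endpoint))
  cat(sprintf("  edges: %d candidates -> %d significant -> %d after DPI; %d modules\n",
              m$counts$candidate_pairs, m$counts$significant_edges,
              m$counts$pruned_edges, m$counts$modules))
  invisible(x)
}
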