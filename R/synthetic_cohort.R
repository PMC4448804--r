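#' Reference dictionary of the CAD cohort's clinical variables
#'
#' The study population behind this package is a prospective multicentre
#' stress-echocardiography cohort of 4313 patients with known or suspected
#' coronary artery disease, followed up with all-cause death as the only
#' endpoint.  This table lists the 29 binary indicators used throughout:
#' variable ID, full name, the number of positives among the 4313 patients,
#' and the rule that defines a positive (see [default_rules()]).
#'
#' @return A data.frame with columns `id`, `full_name`, `n_positive`,
#'   `source_column`, `comparator` (one of `ge`, `le`, `eq`, `in`) and
#'   `threshold` (character; for `in`, comma-separated levels).
#' @export
clinical_variables <- function() {
  df <- data.frame(
    id = c("age", "sex", "Prev_IM", "Prev_rev", "Prev_CABG", "Prev_PCI",
           "Known_CAD", "LBBB", "family", "diabetes", "hypert", "hyperchol",
           "smoke", "therapy", "BB", "CCB", "nitrates", "LM", "RWMA", "CFR",
           "N.vessels", "Rest_vel_LAD", "Isch_SE", "Rest_WMSI", "Peak_WMSI",
           "Delta_WMSI", "ECG_SE", "Angor_SE", "death"),
    full_name = c(
      "age", "gender", "prior myocardial infarction",
      "prior coronary revascularization",
      "prior coronary artery bypass grafting",
      "prior percutaneous coronary intervention",
      "known coronary artery disease", "left bundle branch block",
      "family history of CAD", "diabetes", "arterial hypertension",
      "hypercholesterolemia", "smoking habit",
      "cardioactive medical therapy at stress test time", "beta blockers",
      "calcium channel blockers", "nitrates", "left main disease",
      "resting wall motion abnormality", "coronary flow reserve",
      "number of diseased vessels at angiography",
      "resting velocity on LAD (cm/s)", "ischemia at stress echo",
      "rest wall motion score index", "peak wall motion score index",
      "delta wall motion score index", "ECG changes during stress echo",
      "angina during stress echo", "death"),
    n_positive = c(2301L, 2532L, 1114L, 1234L, 270L, 990L, 1547L, 310L,
                   1108L, 979L, 2891L, 2364L, 1311L, 1798L, 1353L, 755L,
                   465L, 55L, 1379L, 1421L, 1092L, 2212L, 765L, 461L, 526L,
                   108L, 613L, 448L, 146L),
    comparator = c("ge", "eq", rep("eq", 15), "ge", "eq", "le", "in", "ge",
                   "eq", "ge", "ge", "ge", "eq", "eq", "eq"),
    threshold = c("66", "male", rep("yes", 15), "50", "yes", "2.0", "1,2,3",
                  "30", "yes", "1.6", "1.6", "0.4", "yes", "yes", "yes"),
    stringsAsFactors = FALSE
  )
  df$source_column <- df$id
  df[, c("id", "full_name", "n_positive", "source_column", "comparator",
         "threshold")]
}

#' Total size of the reference cohort
#' @keywords internal
#' @noRd
REF_COHORT_N <- 4313L

#' Specify a synthetic binary clinical cohort
#'
#' A cohort spec declares the sample size, variable list, target marginal
#' prevalences, a directed acyclic dependency structure with per-edge
#' log-odds effects, and an exponential proportional-hazards survival model
#' for the endpoint.  [generate_cohort()] samples from it reproducibly.
#'
#' Edges whose child is the endpoint (e.g. `"death"`) are realized through
#' the hazard model (their effect sizes are log hazard ratios held in
#' `survival$coefficients`), not through a logistic draw; all other
#' variables are drawn in topological order from logistic models whose
#' intercepts are calibrated by bisection so each marginal matches its
#' target prevalence.
#'
#' @param n_patients Number of patients (>= 2).
#' @param variables Character vector of variable IDs; must include
#'   `endpoint`.
#' @param prevalences Named numeric vector of target marginal probabilities
#'   in (0, 1), one per variable.
#' @param dependency_dag Data.frame with columns `from`, `to`, `log_odds`;
#'   must be acyclic and reference declared variables only.
#' @param survival List with `baseline_hazard` (events per month),
#'   `coefficients` (named log hazard ratios; names must be declared
#'   variables), `horizon` (administrative censoring time in months).
#' @param endpoint Endpoint variable ID (default `"death"`).
#' @param seed Integer root seed.
#' @return A validated object of class `cohort_spec`.
#' @seealso [default_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_patients, variables, prevalences, dependency_dag,
                        survival, endpoint = "death", seed = 101L) {
  spec <- structure(
    list(n_patients = as.integer(n_patients), variables = variables,
         prevalences = prevalences, dependency_dag = dependency_dag,
         survival = survival, endpoint = endpoint, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
    if (anyDuplicated(variables)) stop("duplicate variable IDs", call. = FALSE)
    if (!endpoint %in% variables) stop("endpoint not among variables", call. = FALSE)
    if (!setequal(names(prevalences), variables)) {
      stop("prevalences must be named for exactly the declared variables",
           call. = FALSE)
    }
    if (any(prevalences <= 0 | prevalences >= 1)) {
      stop("every prevalence must lie strictly in (0, 1)", call. = FALSE)
    }
    dag <- dependency_dag
    if (nrow(dag)) {
      if (!all(c(dag$from, dag$to) %in% variables)) {
        stop("dependency edge references an undeclared variable", call. = FALSE)
      }
      if (endpoint %in% dag$from) {
        stop("endpoint cannot be a parent", call. = FALSE)
      }
      topo_sort(variables, dag)  # errors on a cycle
    }
    cf <- survival$coefficients
    if (length(cf) && !all(names(cf) %in% setdiff(variables, endpoint))) {
      stop("survival coefficients must name declared non-endpoint variables",
           call. = FALSE)
    }
    if (survival$baseline_hazard <= 0 || survival$horizon <= 0) {
      stop("baseline_hazard and horizon must be positive", call. = FALSE)
    }
  })
  invisible(spec)
}

# Kahn topological sort; errors if the edge list has a cycle.
topo_sort <- function(nodes, dag) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in dag$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order <- c(order, v)
    for (w in dag$to[dag$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(order) != length(nodes)) {
    stop("dependency_dag contains a cycle", call. = FALSE)
  }
  order
}

#' Default synthetic cohort specification
#'
#' Emulates the reference CAD cohort: 4313 patients, the 29 indicators of
#' [clinical_variables()] with prevalences equal to the reported positive
#' counts over 4313, a 20-edge dependency DAG connecting clinically grouped
#' variables (prior history, risk factors, therapy, stress-test outputs,
#' endpoint), and an exponential proportional-hazards death process
#' calibrated so the expected event fraction matches 146/4313 over a
#' 19-month administrative censoring horizon.
#'
#' The baseline hazard 6.115555e-4 events/month was obtained once by exact
#' enumeration over the joint distribution of the (mutually independent)
#' hazard covariates and is fixed here, not re-fit at generation time.
#'
#' @param n_patients Cohort size (default 4313).
#' @param seed Root seed (default 101).
#' @param empty_dag If `TRUE`, drop all planted dependencies and hazard
#'   coefficients (a global-null cohort for calibration checks).
#' @return A `cohort_spec`.
#' @export
default_spec <- function(n_patients = 4313, seed = 101L, empty_dag = FALSE) {
  ref <- clinical_variables()
  prev <- stats::setNames(ref$n_positive / REF_COHORT_N, ref$id)
  dag <- data.frame(
    from = c("Known_CAD", "Known_CAD", "Prev_rev", "Prev_rev",
             "age", "hypert",
             "therapy", "therapy", "therapy",
             "N.vessels", "RWMA", "Rest_WMSI", "Peak_WMSI",
             "Isch_SE", "Isch_SE", "CFR",
             # endpoint edges, realized through the hazard model
             "age", "LBBB", "CFR", "Isch_SE"),
    to = c("Prev_IM", "Prev_rev", "Prev_PCI", "Prev_CABG",
           "hypert", "hyperchol",
           "BB", "CCB", "nitrates",
           "Isch_SE", "Rest_WMSI", "Peak_WMSI", "Delta_WMSI",
           "Angor_SE", "ECG_SE", "Rest_vel_LAD",
           "death", "death", "death", "death"),
    log_odds = c(2.0, 2.0, 2.0, 2.0,
                 1.5, 1.5,
                 2.0, 2.0, 2.0,
                 2.0, 2.5, 2.5, 2.5,
                 2.0, 2.0, 1.5,
                 log(2), log(2.5), log(2.2), log(2.5)),
    stringsAsFactors = FALSE
  )
  surv <- list(
    baseline_hazard = 6.115555e-4,
    coefficients = c(age = log(2), LBBB = log(2.5), CFR = log(2.2),
                     Isch_SE = log(2.5)),
    horizon = 19
  )
  if (empty_dag) {
    dag <- dag[0, ]
    surv$coefficients <- stats::setNames(numeric(0), character(0))
  }
  cohort_spec(n_patients = n_patients, variables = ref$id,
              prevalences = prev, dependency_dag = dag, survival = surv,
              endpoint = "death", seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, %d variables, %d dependency edges, seed %d\n",
              x$n_patients, length(x$variables), nrow(x$dependency_dag), x$seed))
  cat(sprintf("  endpoint '%s': baseline hazard %.3g/month, horizon %g months, %d hazard covariates\n",
              x$endpoint, x$survival$baseline_hazard, x$survival$horizon,
              length(x$survival$coefficients)))
  invisible(x)
}

# Solve the logistic intercept so that mean(plogis(b + lp)) == target,
# marginalizing over the realized parent linear predictors.  Monotone in b,
# so plain bisection converges; tolerance 1e-6 on the mean.
calibrate_intercept <- function(lp, target, tol = 1e-6) {
  f <- function(b) mean(stats::plogis(b + lp)) - target
  lo <- -40; hi <- 40
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val) < tol) break
    if (val > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Generate a synthetic cohort from a spec
#'
#' Samples the binary variables in topological order of the dependency DAG.
#' Each non-endpoint variable follows a logistic model: parent
#' contributions are the per-edge log-odds, and the intercept is calibrated
#' by bisection (tolerance 1e-6) so the marginal probability, averaged over
#' the realized parent configurations, equals the target prevalence.  The
#' endpoint is derived from an exponential proportional-hazards survival
#' time with linear predictor \eqn{\sum_v \beta_v X_v}, administratively
#' censored at the horizon; the endpoint column equals the event indicator.
#'
#' Each variable draws from its own RNG stream (derived from the root seed
#' and the variable name by a stable hash), so adding or removing one
#' variable does not perturb the others; identical spec + seed gives
#' bit-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param continuous If `TRUE`, also emit continuous `age_years` and
#'   `CFR_ratio` columns consistent with their binary indicators (to
#'   exercise [binarize()]).
#' @return A list of class `synthetic_cohort`: `table` (n x k 0/1 matrix),
#'   `survival` (data.frame `time`, `status`), `truth` (list with
#'   `direct_edges`, a two-column matrix of unordered planted pairs, and
#'   `survival_coefficients`), `continuous` (NULL or data.frame) and
#'   `spec`.
#' @export
generate_cohort <- function(spec, continuous = FALSE) {
  validate_spec(spec)
  n <- spec$n_patients
  dag <- spec$dependency_dag
  endpoint <- spec$endpoint
  order <- topo_sort(spec$variables, dag)
  X <- matrix(NA_integer_, n, length(spec$variables),
              dimnames = list(NULL, spec$variables))
  for (v in setdiff(order, endpoint)) {
    par_edges <- dag[dag$to == v & dag$from != endpoint, , drop = FALSE]
    lp <- rep(0, n)
    for (e in seq_len(nrow(par_edges))) {
      lp <- lp + par_edges$log_odds[e] * X[, par_edges$from[e]]
    }
    b <- calibrate_intercept(lp, spec$prevalences[[v]])
    set.seed(derive_seed(spec$seed, "var", v))
    X[, v] <- stats::rbinom(n, 1L, stats::plogis(b + lp))
  }
  # endpoint: exponential PH survival, administrative censoring
  cf <- spec$survival$coefficients
  lp_s <- rep(0, n)
  for (v in names(cf)) lp_s <- lp_s + cf[[v]] * X[, v]
  set.seed(derive_seed(spec$seed, "survival"))
  t_event <- stats::rexp(n, rate = spec$survival$baseline_hazard * exp(lp_s))
  status <- as.integer(t_event <= spec$survival$horizon)
  time <- pmin(t_event, spec$survival$horizon)
  X[, endpoint] <- status

  cont <- NULL
  if (continuous) {
    # continuous columns consistent with the binary indicators, for binarize()
    set.seed(derive_seed(spec$seed, "continuous"))
    age_years <- ifelse(X[, "age"] == 1L, stats::runif(n, 66, 92),
                        stats::runif(n, 35, 65.99))
    cfr_ratio <- ifelse(X[, "CFR"] == 1L, stats::runif(n, 1.0, 2.0),
                        stats::runif(n, 2.0000001, 4.5))
    cont <- data.frame(age_years = age_years, CFR_ratio = cfr_ratio)
  }

  direct_edges <- if (nrow(dag)) {
    t(apply(as.matrix(dag[, c("from", "to")]), 1, sort))
  } else {
    matrix(character(0), 0, 2)
  }
  colnames(direct_edges) <- c("a", "b")
  structure(
    list(table = X,
         survival = data.frame(time = time, status = status),
         truth = list(direct_edges = direct_edges,
                      survival_coefficients = cf),
         continuous = cont,
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients x %d variables; %d events (%.2f%%), %d planted edges\n",
              nrow(x$table), ncol(x$table), sum(x$survival$status),
              100 * mean(x$survival$status), nrow(x$truth$direct_edges)))
  invisible(x)
}

#' Write a cohort to delimited text
#'
#' Writes the binary table (`cohort.csv`), the survival records
#' (`survival.csv`) and the planted ground-truth edge list (`truth_edges.csv`)
#' into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$truth$direct_edges),
                   file.path(dir, "truth_edges.csv"), row.names = FALSE)
  invisible(dir)
}

#' Serialize / read a cohort spec as JSON
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `read_spec` returns a validated `cohort_spec`.
#' @export
write_spec <- function(spec, path) {
  obj <- unclass(spec)
  # named vectors must become objects, not bare arrays, to keep their names
  obj$prevalences <- as.list(spec$prevalences)
  obj$survival$coefficients <- as.list(spec$survival$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  surv <- obj$survival
  surv$coefficients <- unlist(surv$coefficients)
  if (is.null(surv$coefficients)) {
    surv$coefficients <- stats::setNames(numeric(0), character(0))
  }
  dag <- as.data.frame(obj$dependency_dag, stringsAsFactors = FALSE)
  if (!nrow(dag)) dag <- data.frame(from = character(0), to = character(0),
                                    log_odds = numeric(0))
  cohort_spec(n_patients = obj$n_patients, variables = obj$variables,
              prevalences = unlist(obj$prevalences), dependency_dag = dag,
              survival = surv, endpoint = obj$endpoint, seed = obj$seed)
}
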