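#' Define a confusion-matrix sampling scenario
#'
#' The generative model matches the one-margin-fixed assumption of the test:
#' the row margins `n1`, `n2` (examples per true class) are fixed, and the
#' reference-column count of row i is drawn as `z_i ~ Binomial(n_i, p_i)`.
#' Under independence (H0) the rows share one probability (`p1 == p2`); under
#' dependence (H1) they differ. A scenario may instead carry a fixed `matrix`,
#' in which case every replicate is that matrix — this lets deterministic
#' textbook cases flow through the same reporting path as simulations.
#'
#' @param n1,n2 Row margins (class sizes), positive integers.
#' @param p1,p2 Per-row reference-column probabilities in \[0, 1\].
#' @param n_reps Number of replicate matrices.
#' @param seed Scenario RNG seed (non-negative integer).
#' @param matrix Optional fixed 2x2 matrix; when given, `n1`/`n2`/`p1`/`p2`
#'   are ignored and replicates are deterministic.
#' @param name Optional scenario label used in reports.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(n1 = NULL, n2 = NULL, p1 = NULL, p2 = NULL,
                                n_reps = 1L, seed = 0L, matrix = NULL,
                                name = NULL) {
  assert_count(n_reps, "n_reps", min = 1)
  assert_count(seed, "seed")
  if (!is.null(matrix)) {
    cm <- confusion_matrix(matrix)
    sc <- list(fixed = cm, n_reps = as.integer(n_reps), seed = as.integer(seed),
               name = name %||% "fixed")
  } else {
    assert_count(n1, "n1", min = 1); assert_count(n2, "n2", min = 1)
    if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1) || length(p1) != 1L ||
        length(p2) != 1L || anyNA(c(p1, p2)))
      stop("p1 and p2 must be probabilities in [0, 1]", call. = FALSE)
    sc <- list(n1 = as.integer(n1), n2 = as.integer(n2), p1 = p1, p2 = p2,
               n_reps = as.integer(n_reps), seed = as.integer(seed),
               name = name %||% sprintf("bin(%d,%g)x(%d,%g)", n1, p1, n2, p2))
  }
  structure(sc, class = "sim_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counter-based stream: mix (seed, scenario, rep) into [0, 2^31) so replicate
# draws are independent of execution order.
derive_seed <- function(seed, scenario_index, rep_index) {
  h <- (as.numeric(seed) * 2654435761 + as.numeric(scenario_index) * 97561 +
          as.numeric(rep_index) * 7919 + 11) %% 2147483647
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one replicate confusion matrix from a scenario
#'
#' Deterministic given `(seed, scenario_index, rep_index)`; replicates can be
#' generated in any order.
#'
#' @param sc A [simulation_scenario()].
#' @param rep_index Replicate number (1-based).
#' @param scenario_index Position of the scenario in a batch (1-based); part
#'   of the stream key so batches don't share streams.
#' @return A [confusion_matrix()] object.
#' @export
sample_matrix <- function(sc, rep_index = 1L, scenario_index = 1L) {
  stopifnot(inherits(sc, "sim_scenario"))
  assert_count(rep_index, "rep_index", min = 1)
  if (!is.null(sc$fixed)) return(sc$fixed)
  zs <- with_local_seed(derive_seed(sc$seed, scenario_index, rep_index), {
    c(stats::rbinom(1L, sc$n1, sc$p1), stats::rbinom(1L, sc$n2, sc$p2))
  })
  confusion_matrix(matrix(c(zs[1L], sc$n1 - zs[1L],
                            zs[2L], sc$n2 - zs[2L]), 2L, 2L, byrow = TRUE))
}

#' Run the metrics-versus-evidence comparison over scenarios
#'
#' For every scenario and replicate, records all standard metrics together
#' with the conservative min log Bayes factor and its evidence label, then
#' summarises each scenario (means, median and quartiles of log B10, and the
#' fraction of replicates per evidence band). Deterministic scenarios (fixed
#' matrices) reproduce the textbook metric-comparison tables through the same
#' path.
#'
#' @param scenarios A list of [simulation_scenario()] objects (a single
#'   scenario is accepted).
#' @param t_max Concentration grid bound passed to [min_log_bayes_factor()].
#' @param positive Positive-class row for the convention-dependent metrics.
#' @param ref_column Reference column for the Bayes factor.
#' @return A list with `replicates` (one row per scenario x replicate) and
#'   `summary` (one row per scenario) data frames.
#' @export
run_comparison <- function(scenarios, t_max = NULL, positive = 2L,
                           ref_column = 1L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "sim_scenario")))
  bands <- c("negative", "bare_mention", "positive", "strong", "decisive")
  rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    for (r in seq_len(sc$n_reps)) {
      cm <- sample_matrix(sc, r, s)
      met <- metric_report(cm, positive)
      bf <- min_log_bayes_factor(cm, t_max = t_max, ref_column = ref_column)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, scenario_index = s, rep = r,
        z11 = cm$z[1, 1], z12 = cm$z[1, 2], z21 = cm$z[2, 1], z22 = cm$z[2, 2],
        pa = met$pa, mcc = met$mcc, f1 = met$f1, kappa = met$kappa,
        youden_j = met$youden_j,
        log_b10_min = bf$log_b10_min, evidence = bf$evidence,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$scenario_index), function(d) {
    frac <- vapply(bands, function(b) mean(d$evidence == b), numeric(1))
    cbind(data.frame(scenario = d$scenario[1L], n_reps = nrow(d),
                     mean_log_b10 = mean(d$log_b10_min),
                     median_log_b10 = stats::median(d$log_b10_min),
                     q25_log_b10 = unname(stats::quantile(d$log_b10_min, 0.25)),
                     q75_log_b10 = unname(stats::quantile(d$log_b10_min, 0.75)),
                     mean_pa = mean(d$pa),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(frac, paste0("frac_", bands)))))
  }))
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

#' Read a scenario batch from JSON
#'
#' The file is a JSON array of objects, each either
#' `{n1, n2, p1, p2, n_reps, seed, name}` or
#' `{matrix: [[..],[..]], n_reps, seed, name}`.
#'
#' @param path Path to the JSON scenario file.
#' @return A list of [simulation_scenario()] objects (possibly empty).
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(o)
    simulation_scenario(n1 = o$n1, n2 = o$n2, p1 = o$p1, p2 = o$p2,
                        n_reps = o$n_reps %||% 1L, seed = o$seed %||% 0L,
                        matrix = if (is.list(o$matrix))
                          do.call(rbind, o$matrix) else o$matrix,
                        name = o$name))
}
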