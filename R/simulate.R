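#' Configuration for the synthetic connectome cohort generator
#'
#' The generator emulates the study design downstream code expects: a healthy
#' control cohort (default 41 subjects) and a patient cohort (default 21),
#' each subject contributing a structural (streamline-count) and a functional
#' (correlation) matrix over a shared atlas. Structural edge counts are
#' log-normal around fixed per-edge log-means (heavy right tail, zeros
#' permitted); functional matrices are correlation matrices sampled around one
#' low-rank-plus-noise population covariance by Wishart perturbation, which
#' gives the between-subject variance structure the exclusion step ranks.
#'
#' @param n_regions atlas size (default 379; other sizes use
#'   [synthetic_atlas()]).
#' @param n_controls number of control subjects (>= 3; default 41).
#' @param n_patients number of patient subjects (default 21).
#' @param seed integer seed; identical configuration => bit-identical cohorts.
#' @param sc_log_mean_range range the fixed per-edge log-count means are drawn
#'   from, uniformly (default `c(0, 6)`: ~ 300k streamlines per brain spread
#'   over the edges with a heavy right tail).
#' @param sc_log_sd between-subject standard deviation of log counts (> 0;
#'   default 0.25).
#' @param fc_base_rank number of latent factors shaping the population
#'   correlation matrix (default 10).
#' @param fc_sample_df Wishart degrees of freedom for subject-level covariance
#'   sampling (>= `n_regions`; default `5 * n_regions`).
#' @param timepoints rows for optional time-series emission (default 200).
#' @param atlas optional `conn_atlas`; defaults to [default_atlas()] when
#'   `n_regions == 379`, else [synthetic_atlas()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 379, n_controls = 41, n_patients = 21,
                       seed = 1, sc_log_mean_range = c(0, 6),
                       sc_log_sd = 0.25, fc_base_rank = 10,
                       fc_sample_df = 5 * n_regions, timepoints = 200,
                       atlas = NULL) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (n_controls < 3) stop("n_controls must be >= 3")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(sc_log_mean_range) != 2 ||
      sc_log_mean_range[1] > sc_log_mean_range[2])
    stop("sc_log_mean_range must be an increasing pair")
  if (sc_log_sd <= 0) stop("sc_log_sd must be > 0")
  if (fc_sample_df < n_regions)
    stop("fc_sample_df must be >= n_regions so sampled covariances are full rank")
  if (timepoints < 2) stop("timepoints must be >= 2")
  if (is.null(atlas))
    atlas <- if (n_regions == 379) default_atlas() else synthetic_atlas(n_regions)
  if (n_regions(atlas) != n_regions)
    stop("atlas size ", n_regions(atlas), " does not match n_regions ", n_regions)
  structure(list(n_regions = n_regions, n_controls = n_controls,
                 n_patients = n_patients, seed = as.integer(seed),
                 sc_log_mean_range = sc_log_mean_range, sc_log_sd = sc_log_sd,
                 fc_base_rank = fc_base_rank, fc_sample_df = fc_sample_df,
                 timepoints = timepoints, atlas = atlas),
            class = "sim_config")
}

# Population-level generative parameters, a deterministic function of the seed.
sim_population <- function(config) {
  set.seed(config$seed)
  n <- config$n_regions
  ne <- n_edges(n)
  sc_log_mean <- stats::runif(ne, config$sc_log_mean_range[1],
                              config$sc_log_mean_range[2])
  W <- matrix(stats::rnorm(n * config$fc_base_rank,
                           sd = 1 / sqrt(config$fc_base_rank)),
              n, config$fc_base_rank)
  d <- stats::runif(n, 0.5, 1)
  fc_pop <- stats::cov2cor(tcrossprod(W) + diag(d))
  list(sc_log_mean = sc_log_mean, fc_pop = fc_pop)
}

# Shared subject sampler: controls and patients use this single code path;
# effect injection happens afterwards.
sim_subjects <- function(config, pop, n_subjects, prefix, stream_seed) {
  set.seed(stream_seed)
  n <- config$n_regions
  names <- config$atlas$regions$name
  lapply(seq_len(n_subjects), function(s) {
    id <- sprintf("%s%02d", prefix, s)
    counts <- round(stats::rlnorm(length(pop$sc_log_mean),
                                  meanlog = pop$sc_log_mean,
                                  sdlog = config$sc_log_sd))
    sc <- edges_to_matrix(counts, n)
    dimnames(sc) <- list(names, names)
    S <- stats::rWishart(1, config$fc_sample_df,
                         pop$fc_pop / config$fc_sample_df)[, , 1]
    fc <- stats::cov2cor(S)
    dimnames(fc) <- list(names, names)
    list(id = id,
         structural = conn_matrix(sc, "structural", id, config$atlas),
         functional = conn_matrix(fc, "functional", id, config$atlas))
  })
}

#' Simulate a healthy control cohort
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: one element per subject with `id`,
#'   `structural` and `functional` `conn_matrix` objects. Identical `config`
#'   (including seed) gives bit-identical output.
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pop <- sim_population(config)
  subjects <- sim_subjects(config, pop, config$n_controls, "control",
                           config$seed + 1L)
  structure(subjects, class = "sim_cohort", role = "control")
}

#' Describe planted edge-level effects for the patient generator
#'
#' Planted structural edges have their streamline counts multiplied by
#' `sc_multiplier` (a value in (0, 1\] encodes fewer tractography fibers than
#' controls); planted functional edges are shifted additively by
#' `fc_shift_sigmas` control-model standard deviations of the sampled
#' correlation (approximated as \eqn{(1 - \rho^2)/\sqrt{df}}).
#'
#' @param edges two-column matrix or data frame of region-name pairs.
#' @param sc_multiplier multiplier in (0, 1\] (default 0.3).
#' @param fc_shift_sigmas signed shift in sigma units (default 4).
#' @param carriers character vector of patient ids carrying the effects;
#'   `NULL` (default) = all patients.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(edges, sc_multiplier = 0.3, fc_shift_sigmas = 4,
                         carriers = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns (region_a, region_b)")
  key <- apply(edges, 1, function(r) paste(sort(r), collapse = "|"))
  if (anyDuplicated(key)) stop("planted edges must be distinct")
  if (any(edges[, 1] == edges[, 2])) stop("planted self-edges are undefined")
  if (sc_multiplier <= 0 || sc_multiplier > 1)
    stop("sc_multiplier must be in (0, 1]")
  structure(list(edges = edges, sc_multiplier = sc_multiplier,
                 fc_shift_sigmas = fc_shift_sigmas, carriers = carriers),
            class = "anomaly_spec")
}

#' Simulate a patient cohort with planted edge effects
#'
#' Patients are drawn from the same generative model (and code path) as
#' controls; planted effects are injected afterwards, so the ground-truth
#' table lists exactly the modified (subject, edge) pairs. With
#' `sc_multiplier = 1` and `fc_shift_sigmas = 0` the injection is the
#' identity and patients are statistically indistinguishable from controls.
#'
#' @param config a [sim_config()].
#' @param spec an [anomaly_spec()]; `NULL` plants nothing.
#' @return list with `subjects` (a `sim_cohort`) and `ground_truth` (data
#'   frame: `subject`, `region_a`, `region_b`, `modality`, `effect`).
#' @export
simulate_patients <- function(config, spec = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pop <- sim_population(config)
  subjects <- sim_subjects(config, pop, config$n_patients, "patient",
                           config$seed + 2L)
  gt <- data.frame(subject = character(), region_a = character(),
                   region_b = character(), modality = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "anomaly_spec"))
    idx_a <- atlas_lookup(config$atlas, spec$edges[, 1])
    idx_b <- atlas_lookup(config$atlas, spec$edges[, 2])
    carriers <- spec$carriers
    if (is.null(carriers))
      carriers <- vapply(subjects, function(s) s$id, "")
    unknown <- setdiff(carriers, vapply(subjects, function(s) s$id, ""))
    if (length(unknown) > 0)
      stop("carriers not in patient cohort: ", paste(unknown, collapse = ", "))
    for (s in seq_along(subjects)) {
      if (!(subjects[[s]]$id %in% carriers)) next
      sc <- subjects[[s]]$structural$values
      fc <- subjects[[s]]$functional$values
      for (e in seq_len(nrow(spec$edges))) {
        i <- idx_a[e]; j <- idx_b[e]
        sc[i, j] <- sc[j, i] <- round(sc[i, j] * spec$sc_multiplier)
        rho <- pop$fc_pop[i, j]
        sig <- (1 - rho^2) / sqrt(config$fc_sample_df)
        shifted <- fc[i, j] + spec$fc_shift_sigmas * sig
        fc[i, j] <- fc[j, i] <- max(-0.999, min(0.999, shifted))
        gt[nrow(gt) + 1L, ] <- list(subjects[[s]]$id,
                                    spec$edges[e, 1], spec$edges[e, 2],
                                    "structural", spec$sc_multiplier)
        gt[nrow(gt) + 1L, ] <- list(subjects[[s]]$id,
                                    spec$edges[e, 1], spec$edges[e, 2],
                                    "functional", spec$fc_shift_sigmas)
      }
      id <- subjects[[s]]$id
      subjects[[s]]$structural <- conn_matrix(sc, "structural", id, config$atlas)
      subjects[[s]]$functional <- conn_matrix(fc, "functional", id, config$atlas)
    }
  }
  list(subjects = structure(subjects, class = "sim_cohort", role = "patient"),
       ground_truth = gt)
}

#' Emit a synthetic regional time series for one subject
#'
#' Draws `config$timepoints` multivariate-Gaussian samples with the given
#' covariance; the sample correlation of the series converges to the
#' covariance's correlation as the number of time points grows.
#'
#' @param config a [sim_config()].
#' @param covariance the subject's functional covariance (or correlation)
#'   matrix.
#' @param seed seed for this draw (default `config$seed`).
#' @return numeric matrix, time x region, with region column names.
#' @export
emit_timeseries <- function(config, covariance, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$timepoints < 2) stop("timepoints must be >= 2")
  set.seed(seed)
  ts <- MASS::mvrnorm(config$timepoints, mu = rep(0, nrow(covariance)),
                      Sigma = covariance)
  colnames(ts) <- rownames(covariance)
  ts
}

#' Pick planted edges among detectable candidates
#'
#' Planted effects on an edge the variance mask excludes (or whose normative
#' sigma is zero) are unobservable by construction: excluded edges are never
#' scored. This helper samples planted edges uniformly among the retained,
#' non-degenerate edges of a control-fitted reference whose normative mean is
#' above the retained median — i.e., edges with enough streamlines for a
#' multiplicative loss to be visible.
#'
#' @param reference a structural `normative_reference` fitted on controls.
#' @param n number of edges to pick.
#' @param seed seed for the draw.
#' @return two-column character matrix of region-name pairs.
#' @export
choose_planted_edges <- function(reference, n = 10, seed = 1) {
  stopifnot(inherits(reference, "normative_reference"))
  ok <- !reference$excluded & !reference$degenerate
  ok <- ok & reference$mu >= stats::median(reference$mu[ok])
  cand <- which(ok)
  if (length(cand) < n)
    stop("only ", length(cand), " candidate edges available, need ", n)
  set.seed(seed)
  picked <- sample(cand, n)
  cbind(reference$region_names[reference$edge_i[picked]],
        reference$region_names[reference$edge_j[picked]])
}
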