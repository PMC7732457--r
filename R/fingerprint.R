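# Which statuses count as flagged under a direction filter. Structural burden
# defaults to the low side (fiber loss); functional to both sides.
flagged_statuses <- function(direction) {
  switch(direction,
         low = "anomaly_low",
         high = "anomaly_high",
         both = c("anomaly_low", "anomaly_high"),
         stop("direction must be 'low', 'high' or 'both'"))
}

default_direction <- function(modality)
  if (modality == "structural") "low" else "both"

#' Round half away from zero
#'
#' Plain decimal rounding with halves rounded up, matching how the burden
#' tables print percentages (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Burden-table arithmetic for one region
#'
#' The deterministic arithmetic behind each burden row: the total potential
#' anomaly count is the number of retained (low-variance) connections times
#' the number of subjects, and the percentage is the observed anomaly count
#' as a share of that total, displayed to 2 decimals (half-up).
#'
#' @param n_anomalies flagged (subject, edge) incidences for the region.
#' @param n_low_variance retained edges incident to the region.
#' @param n_subjects subjects pooled.
#' @return data frame with `total_potential` and `percentage` (vectorized).
#' @export
burden_arithmetic <- function(n_anomalies, n_low_variance, n_subjects) {
  total <- n_low_variance * n_subjects
  pct <- ifelse(total > 0, 100 * n_anomalies / total, 0)
  data.frame(total_potential = total,
             percentage = round_half_up(pct, 2))
}

#' Per-region anomaly burden table
#'
#' Pools a cohort's anomaly matrices into one row per region: every flagged
#' (subject, edge) pair increments both endpoint regions once; a region's
#' retained-connection count is its number of incident non-excluded,
#' non-degenerate edges; the total potential is retained connections times
#' subjects. Rows are sorted by percentage descending (full precision), ties
#' by anomaly count descending then region name.
#'
#' @param anomalies list of `anomaly_matrix` objects sharing one reference.
#' @param atlas the `conn_atlas` the matrices are aligned to.
#' @param reference the `normative_reference` used for detection.
#' @param direction which anomaly direction counts: `"low"`, `"high"` or
#'   `"both"`; `NULL` uses the modality default (structural: low-side only,
#'   i.e. fiber loss; functional: both).
#' @return data frame with columns `region`, `n_anomalies`,
#'   `n_subjects_with_anomaly`, `n_low_variance`, `total_potential`,
#'   `percentage` (full precision; see [round_half_up()] for display).
#' @export
burden_table <- function(anomalies, atlas, reference, direction = NULL) {
  check_anomaly_list(anomalies)
  if (length(unique(vapply(anomalies, function(a) a$modality, ""))) != 1)
    stop("anomaly matrices mix modalities")
  if (anomalies[[1]]$modality != reference$modality ||
      !identical(anomalies[[1]]$region_names, reference$region_names))
    stop("anomaly matrices do not match the reference")
  if (is.null(direction)) direction <- default_direction(reference$modality)
  flag <- flagged_statuses(direction)

  n <- reference$n_regions
  names <- reference$region_names
  retained <- !reference$excluded & !reference$degenerate
  n_low_variance <- tabulate(c(reference$edge_i[retained],
                               reference$edge_j[retained]), nbins = n)
  n_subjects <- length(anomalies)

  n_anom <- integer(n)
  subj_hit <- matrix(FALSE, n_subjects, n)
  for (s in seq_len(n_subjects)) {
    am <- anomalies[[s]]
    hit <- am$status %in% flag
    inc <- c(am$edge_i[hit], am$edge_j[hit])
    n_anom <- n_anom + tabulate(inc, nbins = n)
    subj_hit[s, unique(inc)] <- TRUE
  }
  arith <- burden_arithmetic(n_anom, n_low_variance, n_subjects)
  pct_full <- ifelse(arith$total_potential > 0,
                     100 * n_anom / arith$total_potential, 0)
  out <- data.frame(region = names, n_anomalies = n_anom,
                    n_subjects_with_anomaly = colSums(subj_hit),
                    n_low_variance = n_low_variance,
                    total_potential = arith$total_potential,
                    percentage = pct_full, stringsAsFactors = FALSE)
  out[order(-out$percentage, -out$n_anomalies, out$region), , drop = FALSE]
}

#' Cross-subject edge-frequency table
#'
#' One row per edge flagged anomalous in at least one subject, counting the
#' subjects flagged, annotated with each endpoint's network affiliation and
#' the edge's hemisphere/relationship classification. Rows are sorted by
#' subject count descending, then region names ascending.
#'
#' @param anomalies non-empty list of `anomaly_matrix` objects.
#' @param atlas the `conn_atlas` (supplies networks and edge classes).
#' @param direction `"low"`, `"high"`, `"both"` or `NULL` (modality default).
#' @return data frame with columns `n_patients`, `affiliation_a`, `region_a`,
#'   `region_b`, `affiliation_b`, `hemisphere_relation`, `relationship`.
#' @export
edge_frequency_table <- function(anomalies, atlas, direction = NULL) {
  check_anomaly_list(anomalies)
  if (is.null(direction))
    direction <- default_direction(anomalies[[1]]$modality)
  flag <- flagged_statuses(direction)
  counts <- Reduce(`+`, lapply(anomalies, function(am) am$status %in% flag))
  keep <- which(counts > 0)
  am1 <- anomalies[[1]]
  if (length(keep) == 0)
    return(data.frame(n_patients = integer(), affiliation_a = character(),
                      region_a = character(), region_b = character(),
                      affiliation_b = character(),
                      hemisphere_relation = character(),
                      relationship = character(), stringsAsFactors = FALSE))
  ra <- am1$region_names[am1$edge_i[keep]]
  rb <- am1$region_names[am1$edge_j[keep]]
  net <- stats::setNames(atlas$regions$network, atlas$regions$name)
  cls <- mapply(function(a, b) unlist(classify_edge(atlas, a, b)), ra, rb)
  out <- data.frame(n_patients = counts[keep],
                    affiliation_a = unname(net[ra]), region_a = ra,
                    region_b = rb, affiliation_b = unname(net[rb]),
                    hemisphere_relation = cls["hemisphere_relation", ],
                    relationship = cls["relationship", ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients, out$region_a, out$region_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anomaly submatrix restricted to one brain network
#'
#' Rows and columns are the network's member regions in atlas order; entries
#' are the per-edge statuses, so anomalies are distinguishable from normal and
#' excluded (high-variance) edges, which render as the background state in the
#' figures. The diagonal is `"excluded"` (self-edges are never assessed).
#'
#' @param anomaly one `anomaly_matrix`.
#' @param atlas the `conn_atlas`.
#' @param network a network label with at least 2 member regions.
#' @return character matrix of statuses over the network members.
#' @export
network_submatrix <- function(anomaly, atlas, network) {
  members <- network_members(atlas, network)
  if (length(members) < 2)
    stop("network '", network, "' has fewer than 2 members")
  status_matrix(anomaly)[members, members]
}

check_anomaly_list <- function(anomalies) {
  if (!is.list(anomalies) || length(anomalies) == 0)
    stop("anomalies must be a non-empty list of anomaly_matrix objects")
  if (!all(vapply(anomalies, inherits, TRUE, "anomaly_matrix")))
    stop("anomalies must be anomaly_matrix objects")
  rn <- lapply(anomalies, function(a) a$region_names)
  if (!all(vapply(rn, identical, TRUE, rn[[1]])))
    stop("anomaly matrices are aligned to different atlases")
  invisible(TRUE)
}

#' Plain-text bar profile of regional burden percentages
#'
#' A console analogue of the burden bar-graph figure: one bar per region,
#' scaled to the maximum percentage.
#'
#' @param burden a [burden_table()] result.
#' @param top how many regions to show (default 25).
#' @param width bar width in characters.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
burden_profile <- function(burden, top = 25, width = 50) {
  b <- utils::head(burden, top)
  mx <- max(b$percentage, 1e-12)
  lines <- sprintf("%-14s %6.2f%% |%s", b$region,
                   round_half_up(b$percentage, 2),
                   vapply(b$percentage,
                          function(p) paste(rep("#", round(width * p / mx)),
                                            collapse = ""), ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
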