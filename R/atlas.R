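#' Load a brain-atlas metadata table
#'
#' Reads region metadata from a delimited text file (one header line, tab
#' separated by default) with columns `name`, `hemisphere`, `kind`,
#' `subcortical_class`, `lobe` and `network`, and returns an atlas object.
#' Region order in the file is the canonical order: every connectivity matrix
#' in a run must be aligned to it.
#'
#' The bundled default atlas (see [default_atlas()]) has 379 regions: 180
#' cortical parcels per hemisphere plus 19 subcortical structures, with the
#' brain stem as the only midline region. Lobe and network affiliations in the
#' bundled table are package configuration, not ground truth.
#'
#' @param path path to the metadata file.
#' @param sep field separator (default tab).
#' @return an object of class `conn_atlas`: a list with `regions` (data frame
#'   in file order) and `index` (named integer vector, name -> position).
#' @export
load_atlas <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("atlas metadata file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  required <- c("name", "hemisphere", "kind", "subcortical_class", "lobe", "network")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("atlas metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup) > 0) {
    line <- which(duplicated(tab$name))[1] + 1L   # +1 for the header line
    stop("duplicate region name '", dup[1], "' at line ", line)
  }
  check_enum <- function(col, allowed) {
    bad <- which(!(tab[[col]] %in% allowed))
    if (length(bad) > 0)
      stop("unknown ", col, " value '", tab[[col]][bad[1]], "' at line ", bad[1] + 1L)
  }
  check_enum("hemisphere", c("left", "right", "midline"))
  check_enum("kind", c("cortical", "subcortical"))
  check_enum("subcortical_class",
             c("none", "basal_ganglia", "thalamus", "hippocampus", "amygdala",
               "diencephalon", "cerebellum", "brainstem", "accumbens"))
  if (any(tab$kind == "cortical" & tab$subcortical_class != "none"))
    stop("cortical regions must have subcortical_class 'none'")
  if (any(tab$kind == "cortical" & tab$hemisphere == "midline"))
    stop("cortical regions must be left or right hemisphere")
  if (nrow(tab) == 379) {
    # the default atlas layout is validated strictly
    n_cort <- sum(tab$kind == "cortical")
    if (n_cort != 360)
      stop("a 379-region atlas must have 360 cortical regions, found ", n_cort)
    if (sum(tab$kind == "cortical" & tab$hemisphere == "left") != 180 ||
        sum(tab$kind == "cortical" & tab$hemisphere == "right") != 180)
      stop("a 379-region atlas must have 180 cortical regions per hemisphere")
  }
  structure(list(regions = tab,
                 index = stats::setNames(seq_len(nrow(tab)), tab$name)),
            class = "conn_atlas")
}

#' The bundled 379-region atlas
#'
#' 360 HCP-MMP1-style cortical parcels (180 per hemisphere, `L_`/`R_`
#' prefixed) plus 9 subcortical structures per hemisphere and the brain stem.
#'
#' @return a `conn_atlas` with 379 regions.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_379_metadata.tsv", package = "normconn",
                      mustWork = TRUE)
  load_atlas(path)
}

#' Construct a synthetic atlas for simulation and testing
#'
#' Builds a schematic atlas of `n_regions` regions: the first
#' `n_regions - n_subcortical` are cortical, split left/right alternately, with
#' lobes and networks assigned round-robin; the remainder are subcortical with
#' classes cycled over the basal ganglia, thalamus and hippocampus.
#'
#' @param n_regions total number of regions (>= 2).
#' @param n_subcortical how many trailing regions are subcortical (default 0).
#' @return a `conn_atlas`.
#' @export
synthetic_atlas <- function(n_regions, n_subcortical = 0) {
  stopifnot(n_regions >= 2, n_subcortical >= 0, n_subcortical < n_regions)
  n_cort <- n_regions - n_subcortical
  hemi <- rep(c("left", "right"), length.out = n_cort)
  pref <- ifelse(hemi == "left", "L", "R")
  lobes <- c("Frontal", "Parietal", "Temporal", "Occipital")
  nets <- c("DMN", "CEN", "Salience", "Visual", "Sensorimotor")
  tab <- data.frame(
    name = sprintf("%s_r%03d", pref, seq_len(n_cort)),
    hemisphere = hemi, kind = "cortical", subcortical_class = "none",
    lobe = rep(lobes, length.out = n_cort),
    network = rep(nets, length.out = n_cort),
    stringsAsFactors = FALSE)
  if (n_subcortical > 0) {
    cls <- rep(c("basal_ganglia", "thalamus", "hippocampus"),
               length.out = n_subcortical)
    sh <- rep(c("left", "right"), length.out = n_subcortical)
    tab <- rbind(tab, data.frame(
      name = sprintf("%s_sub%02d", ifelse(sh == "left", "L", "R"),
                     seq_len(n_subcortical)),
      hemisphere = sh, kind = "subcortical", subcortical_class = cls,
      lobe = "Subcortical", network = "Subcortical",
      stringsAsFactors = FALSE))
  }
  structure(list(regions = tab,
                 index = stats::setNames(seq_len(nrow(tab)), tab$name)),
            class = "conn_atlas")
}

#' @export
print.conn_atlas <- function(x, ...) {
  cat("Brain atlas:", nrow(x$regions), "regions (",
      sum(x$regions$kind == "cortical"), "cortical,",
      sum(x$regions$kind == "subcortical"), "subcortical )\n")
  cat("Networks:", paste(sort(unique(x$regions$network)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas a `conn_atlas`.
#' @return integer region count.
#' @export
n_regions <- function(atlas) nrow(atlas$regions)

atlas_lookup <- function(atlas, name) {
  pos <- atlas$index[name]
  if (any(is.na(pos)))
    stop("unknown region name(s): ",
         paste(name[is.na(pos)], collapse = ", "))
  unname(pos)
}

#' Classify an edge by hemisphere relation and anatomical relationship
#'
#' The hemisphere relation is `left` or `right` when both endpoints share that
#' hemisphere, `bilateral` when they differ, and `midline_involved` when either
#' endpoint is a midline structure (brain stem). The anatomical relationship is
#' decided in a fixed priority order: any basal-ganglia or accumbens endpoint
#' makes the edge `corticobasal`; otherwise a thalamic endpoint makes it
#' `corticothalamic`; then a hippocampal endpoint `corticohippocampal`; any
#' other subcortical endpoint gives `cortico_subcortical_other`
#' (`subcortico_subcortical` when both endpoints are subcortical); among
#' cortico-cortical edges, differing hemispheres give `interhemispheric`, a
#' shared lobe `intralobar`, and the rest `long_range`. Subcortical classes
#' take priority over hemisphere so that, e.g., a corticobasal edge is labelled
#' corticobasal in either hemisphere.
#'
#' @param atlas a `conn_atlas`.
#' @param a,b region names; must differ (self-edges are undefined).
#' @return a list with `hemisphere_relation` and `relationship`.
#' @export
classify_edge <- function(atlas, a, b) {
  if (identical(a, b)) stop("self-edge (", a, ", ", b, ") is undefined")
  ia <- atlas_lookup(atlas, a); ib <- atlas_lookup(atlas, b)
  ra <- atlas$regions[ia, ]; rb <- atlas$regions[ib, ]
  hemis <- c(ra$hemisphere, rb$hemisphere)
  hemisphere_relation <-
    if (any(hemis == "midline")) "midline_involved"
    else if (hemis[1] == hemis[2]) hemis[1]
    else "bilateral"
  cls <- c(ra$subcortical_class, rb$subcortical_class)
  both_sub <- all(c(ra$kind, rb$kind) == "subcortical")
  relationship <-
    if (any(cls %in% c("basal_ganglia", "accumbens"))) "corticobasal"
    else if (any(cls == "thalamus")) "corticothalamic"
    else if (any(cls == "hippocampus")) "corticohippocampal"
    else if (any(cls != "none")) {
      if (both_sub) "subcortico_subcortical" else "cortico_subcortical_other"
    }
    else if (ra$hemisphere != rb$hemisphere) "interhemispheric"
    else if (ra$lobe == rb$lobe) "intralobar"
    else "long_range"
  list(hemisphere_relation = hemisphere_relation, relationship = relationship)
}

#' Regions affiliated with a large-scale brain network
#'
#' @param atlas a `conn_atlas`.
#' @param network a network label present in the atlas metadata.
#' @return character vector of member region names, in atlas order.
#' @export
network_members <- function(atlas, network) {
  available <- unique(atlas$regions$network)
  if (!(network %in% available))
    stop("unknown network label '", network, "'; available: ",
         paste(sort(available), collapse = ", "))
  atlas$regions$name[atlas$regions$network == network]
}

# Canonical edge enumeration: unordered off-diagonal pairs (i < j) in
# column-major upper-triangle order, shared by every module.
edge_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

n_edges <- function(n) n * (n - 1L) / 2L

# Extract the edge vector of a symmetric matrix in canonical order.
edge_values <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (given diagonal) from an edge vector.
edges_to_matrix <- function(v, n, diag_value = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}
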