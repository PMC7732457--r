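#' Per-voxel connectivity feature vectors from streamline endpoints
#'
#' Counts, for each voxel, the streamlines terminating in each atlas target
#' region, yielding the connectivity fingerprint used to classify voxels into
#' parcels.
#'
#' @param endpoints data frame with columns `voxel_id` (integer) and `target`
#'   (region name).
#' @param atlas the `conn_atlas` defining the target regions.
#' @param voxel_ids optional integer vector of voxels to emit (rows are zero
#'   vectors for voxels with no endpoints); defaults to the ids present.
#' @return numeric matrix, voxels x regions, with voxel ids as row names and
#'   region names as column names.
#' @export
build_voxel_features <- function(endpoints, atlas, voxel_ids = NULL) {
  stopifnot(is.data.frame(endpoints),
            all(c("voxel_id", "target") %in% names(endpoints)))
  unknown <- setdiff(unique(endpoints$target), atlas$regions$name)
  if (length(unknown) > 0)
    stop("unknown target region(s): ", paste(unknown, collapse = ", "))
  if (is.null(voxel_ids)) voxel_ids <- sort(unique(endpoints$voxel_id))
  feats <- matrix(0, length(voxel_ids), n_regions(atlas),
                  dimnames = list(voxel_ids, atlas$regions$name))
  if (nrow(endpoints) > 0) {
    tab <- table(factor(endpoints$voxel_id, levels = voxel_ids),
                 factor(endpoints$target, levels = atlas$regions$name))
    feats <- feats + unclass(tab)
  }
  feats
}

#' Train a centroid-constrained voxel parcellation classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost, multiclass
#' softprob) on labeled voxel connectivity fingerprints and records each
#' parcel's centroid (the mean coordinate of its training voxels). At
#' assignment time candidate parcels are restricted to those whose centroid
#' lies within `radius` of the voxel.
#'
#' @param features numeric matrix, voxels x target regions.
#' @param coords numeric matrix, voxels x 3 (grid units).
#' @param labels character vector of parcel names (>= 2 distinct).
#' @param radius constraint distance in grid units; `NULL` (default) uses
#'   twice the mean within-parcel distance of training voxels to their
#'   centroid, and logs the value.
#' @param nrounds,max_depth,eta xgboost hyperparameters (fixed defaults:
#'   60 rounds, depth 4, learning rate 0.3).
#' @param seed seed for the tree ensemble.
#' @param verbose report training accuracy (default `TRUE`).
#' @return an object of class `parcellation_model`.
#' @export
train_parcellation_model <- function(features, coords, labels, radius = NULL,
                                     nrounds = 60, max_depth = 4, eta = 0.3,
                                     seed = 1, verbose = TRUE) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            is.matrix(coords), ncol(coords) == 3,
            nrow(coords) == nrow(features))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("training requires at least 2 distinct labels, got ", length(classes))
  y <- match(labels, classes) - 1L
  centroids <- t(vapply(classes,
                        function(cl) colMeans(coords[labels == cl, , drop = FALSE]),
                        numeric(3)))
  if (is.null(radius)) {
    spread <- vapply(classes, function(cl) {
      d <- sweep(coords[labels == cl, , drop = FALSE], 2, centroids[cl, ])
      mean(sqrt(rowSums(d^2)))
    }, 0)
    radius <- 2 * mean(spread)
    if (verbose) message("centroid-constraint radius set to ",
                         format(radius, digits = 4), " grid units")
  }
  if (radius <= 0) stop("radius must be positive")
  dtrain <- xgboost::xgb.DMatrix(features, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = max_depth, eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  prob <- predict_prob(booster, features, length(classes))
  acc <- mean(classes[max.col(prob, ties.method = "first")] == labels)
  if (verbose) message("training accuracy: ", format(acc, digits = 4))
  structure(list(booster = booster, classes = classes, centroids = centroids,
                 radius = radius, n_features = ncol(features),
                 training_accuracy = acc,
                 hyperparameters = list(nrounds = nrounds,
                                        max_depth = max_depth, eta = eta,
                                        seed = seed)),
            class = "parcellation_model")
}

predict_prob <- function(booster, features, n_class) {
  p <- stats::predict(booster, xgboost::xgb.DMatrix(features))
  if (is.null(dim(p))) p <- matrix(p, ncol = n_class, byrow = TRUE)
  p
}

#' @export
print.parcellation_model <- function(x, ...) {
  cat("Centroid-constrained parcellation classifier:",
      length(x$classes), "parcels,", x$n_features, "features\n")
  cat("  radius:", format(x$radius, digits = 4),
      " training accuracy:", format(x$training_accuracy, digits = 4), "\n")
  invisible(x)
}

#' Assign voxels to parcels under the centroid constraint
#'
#' Candidate parcels for a voxel are those whose training centroid lies within
#' the model's radius of the voxel's coordinates; the classifier's
#' highest-scoring candidate wins. A voxel with no candidate in range is left
#' unassigned (`NA`).
#'
#' @param model a `parcellation_model`.
#' @param features numeric matrix, voxels x target regions (same width as the
#'   training features).
#' @param coords numeric matrix, voxels x 3.
#' @return character vector of parcel names, `NA` for unassigned voxels.
#' @export
assign_voxels <- function(model, features, coords) {
  stopifnot(inherits(model, "parcellation_model"), is.matrix(features),
            is.matrix(coords), nrow(features) == nrow(coords))
  if (ncol(features) != model$n_features)
    stop("feature length ", ncol(features), " does not match model (",
         model$n_features, ")")
  prob <- predict_prob(model$booster, features, length(model$classes))
  out <- rep(NA_character_, nrow(features))
  for (v in seq_len(nrow(features))) {
    d <- sqrt(colSums((t(model$centroids) - coords[v, ])^2))
    cand <- which(d <= model$radius)
    if (length(cand) == 0) next
    out[v] <- model$classes[cand[which.max(prob[v, cand])]]
  }
  out
}

#' Simulate a synthetic voxel grid with planted parcels
#'
#' Plants `n_parcels` parcels at the corners of a cube grid. Each parcel has a
#' distinctive connectivity signature: a parcel-specific subset of target
#' regions with elevated Poisson rates against a low background, with
#' `noise` controlling the overlap between signatures. Voxel coordinates
#' scatter around the parcel centroid.
#'
#' @param n_parcels number of planted parcels (default 8, a 2x2x2 grid).
#' @param voxels_per_parcel voxels per parcel (default 500).
#' @param n_targets length of the connectivity feature vector (default 40).
#' @param signal mean termination count on a parcel's signature targets
#'   (default 12).
#' @param noise background mean count on all targets (default 1.5).
#' @param spread coordinate scatter (sd, grid units; default 1).
#' @param spacing centroid grid spacing (grid units; default 10).
#' @param seed seed.
#' @return list with `features`, `coords`, `labels`, `centroids`.
#' @export
simulate_parcellation_grid <- function(n_parcels = 8, voxels_per_parcel = 500,
                                       n_targets = 40, signal = 12,
                                       noise = 1.5, spread = 1, spacing = 10,
                                       seed = 1) {
  stopifnot(n_parcels >= 2, voxels_per_parcel >= 1, n_targets >= n_parcels)
  set.seed(seed)
  side <- ceiling(n_parcels^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_parcels), ] * spacing
  parcel_names <- sprintf("parcel_%02d", seq_len(n_parcels))
  rownames(grid) <- parcel_names
  # each parcel's signature: a distinct block of targets
  block <- split(seq_len(n_targets),
                 rep(seq_len(n_parcels), length.out = n_targets))
  n_vox <- n_parcels * voxels_per_parcel
  labels <- rep(parcel_names, each = voxels_per_parcel)
  coords <- grid[labels, ] +
    matrix(stats::rnorm(3 * n_vox, sd = spread), n_vox, 3)
  rate <- matrix(noise, n_vox, n_targets)
  for (p in seq_len(n_parcels))
    rate[labels == parcel_names[p], block[[p]]] <- signal
  features <- matrix(stats::rpois(n_vox * n_targets, rate), n_vox, n_targets)
  colnames(features) <- sprintf("target_%02d", seq_len(n_targets))
  list(features = features, coords = unname(coords), labels = labels,
       centroids = grid)
}
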