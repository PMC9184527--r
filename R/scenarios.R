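#' Environmental records for field experiments
#'
#' One row per experiment: per phenological phase (vegetative, flowering,
#' grain filling) the cumulated intercepted light (MJ m-2) and the mean
#' daily minimum/maximum temperatures (deg C), plus the mean soil water
#' potential over the vegetative + flowering phases (`psi`, MPa, <= 0).
#'
#' @param experiment experiment identifiers (unique).
#' @param light_veg,light_flo,light_gf cumulated intercepted light per phase.
#' @param tmin_veg,tmin_flo,tmin_gf mean daily minimum temperature per phase.
#' @param tmax_veg,tmax_flo,tmax_gf mean daily maximum temperature per phase.
#' @param psi mean soil water potential (MPa, non-positive).
#' @return A data frame of class `env_records`.
#' @export
env_records <- function(experiment, light_veg, light_flo, light_gf,
                        tmin_veg, tmin_flo, tmin_gf,
                        tmax_veg, tmax_flo, tmax_gf, psi) {
  out <- data.frame(experiment = as.character(experiment),
                    light_veg = light_veg, light_flo = light_flo,
                    light_gf = light_gf,
                    tmin_veg = tmin_veg, tmin_flo = tmin_flo,
                    tmin_gf = tmin_gf,
                    tmax_veg = tmax_veg, tmax_flo = tmax_flo,
                    tmax_gf = tmax_gf, psi = psi,
                    stringsAsFactors = FALSE)
  .assert(!anyDuplicated(out$experiment), "experiment ids must be unique")
  .assert(all(out$tmin_veg <= out$tmax_veg) &&
            all(out$tmin_flo <= out$tmax_flo) &&
            all(out$tmin_gf <= out$tmax_gf), "Tmin must not exceed Tmax")
  .assert(all(out[, grep("^light", names(out))] >= 0), "light must be >= 0")
  .assert(all(out$psi <= 0), "soil water potential must be <= 0")
  class(out) <- c("env_records", class(out))
  out
}

.env_covariate_cols <- c("light_veg", "light_flo", "light_gf",
                         "tmin_veg", "tmin_flo", "tmin_gf",
                         "tmax_veg", "tmax_flo", "tmax_gf")

#' Temperature-scenario clustering of experiments
#'
#' Standardises the nine phase-wise light/temperature covariates, projects
#' them onto principal components retaining at least 90% of the variance,
#' and partitions the experiments with PAM (k-medoids, BUILD + SWAP,
#' Euclidean distance). Clusters are renamed `cool`, `warm`, `hot` by
#' ascending mean maximum temperature over phases (for k = 3; otherwise
#' `T1..Tk` in the same order).
#'
#' @param envs an [env_records()] table.
#' @param k number of temperature classes (default 3).
#' @param seed unused (PAM BUILD+SWAP is deterministic); kept in the
#'   signature for interface uniformity.
#' @param var_retained minimum PCA variance retained (default 0.9).
#' @return List of class `temp_clustering`: `labels` (named factor),
#'   `medoids` (rows of the PC-space matrix), `basis` (centre/scale/rotation),
#'   `pam` (the cluster::pam fit), `class_names`.
#' @export
cluster_temperature <- function(envs, k = 3, seed = 1, var_retained = 0.9) {
  stopifnot(inherits(envs, "env_records"))
  n <- nrow(envs)
  .assert(k >= 1 && k <= n, "k must be between 1 and the number of experiments")
  X <- as.matrix(envs[, .env_covariate_cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- min(which(cum >= var_retained))
  Z <- pc$x[, seq_len(ncomp), drop = FALSE]
  if (k == n) {
    # degenerate: every experiment its own medoid, zero cost
    fit <- list(clustering = seq_len(n), id.med = seq_len(n))
  } else {
    fit <- cluster::pam(Z, k = k, metric = "euclidean", pamonce = 0)
  }
  lab <- fit$clustering
  # order clusters by mean Tmax across phases
  tmax_mean <- rowMeans(envs[, c("tmax_veg", "tmax_flo", "tmax_gf")])
  cl_tmax <- vapply(seq_len(k), function(cl) mean(tmax_mean[lab == cl]),
                    numeric(1))
  ord <- order(cl_tmax)
  class_names <- if (k == 3) c("cool", "warm", "hot") else sprintf("T%d", 1:k)
  renamed <- class_names[match(lab, ord)]
  labels <- factor(renamed, levels = class_names)
  names(labels) <- envs$experiment
  medoids <- Z[fit$id.med[ord], , drop = FALSE]
  rownames(medoids) <- class_names
  structure(list(labels = labels, medoids = medoids,
                 basis = list(center = ctr, scale = scl,
                              rotation = pc$rotation[, seq_len(ncomp),
                                                     drop = FALSE]),
                 pam = fit, class_names = class_names,
                 train_range = apply(X, 2, range)),
            class = "temp_clustering")
}

#' Water-scenario classification
#'
#' Well-watered (WW) requires a mean soil water potential strictly above
#' -0.1 MPa over the vegetative and flowering phases; otherwise the
#' experiment is classed as water deficit (WD). The boundary value
#' -0.1 MPa itself is WD.
#'
#' @param psi mean soil water potential (MPa), vectorised.
#' @return Factor with levels `WW`, `WD`.
#' @export
classify_water <- function(psi) {
  .assert(all(is.finite(psi)), "psi must be finite")
  factor(ifelse(psi > -0.1, "WW", "WD"), levels = c("WW", "WD"))
}

#' Assign environmental scenarios to (new) experiments
#'
#' Projects each record onto the stored PCA basis, takes the temperature
#' class of the nearest medoid, and combines it with the water class from
#' [classify_water()]. Records far outside the training covariate range
#' (beyond 10x the training span) are still assigned, with a warning.
#'
#' @param envs an [env_records()] table.
#' @param clustering a [cluster_temperature()] fit.
#' @return Data frame with columns `experiment`, `temp_class`,
#'   `water_class`, `scenario` (e.g. `"hot_WD"`).
#' @export
assign_scenario <- function(envs, clustering) {
  stopifnot(inherits(envs, "env_records"),
            inherits(clustering, "temp_clustering"))
  X <- as.matrix(envs[, .env_covariate_cols])
  rng <- clustering$train_range
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  lo <- rng[1, ] - 10 * span
  hi <- rng[2, ] + 10 * span
  if (any(t(X) < lo | t(X) > hi)) {
    warning("covariates outside 10x the training range; assigning anyway")
  }
  b <- clustering$basis
  Z <- sweep(sweep(X, 2, b$center), 2, b$scale, "/") %*% b$rotation
  M <- clustering$medoids
  d2 <- outer(rowSums(Z^2), rowSums(M^2), "+") - 2 * Z %*% t(M)
  temp <- clustering$class_names[max.col(-d2, ties.method = "first")]
  water <- classify_water(envs$psi)
  data.frame(experiment = envs$experiment,
             temp_class = factor(temp, levels = clustering$class_names),
             water_class = water,
             scenario = paste(temp, water, sep = "_"),
             stringsAsFactors = FALSE)
}

#' Serialise / restore a temperature clustering as JSON
#'
#' @param clustering a [cluster_temperature()] fit.
#' @param path JSON file path.
#' @return `path` invisibly (`write_clustering`); a `temp_clustering`
#'   (`read_clustering`; the `pam` element is not restored).
#' @export
write_clustering <- function(clustering, path) {
  stopifnot(inherits(clustering, "temp_clustering"))
  obj <- list(medoids = clustering$medoids,
              center = clustering$basis$center,
              scale = clustering$basis$scale,
              rotation = clustering$basis$rotation,
              class_names = clustering$class_names,
              train_range = clustering$train_range)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_clustering
#' @export
read_clustering <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  medoids <- as.matrix(obj$medoids)
  rotation <- as.matrix(obj$rotation)
  rownames(medoids) <- obj$class_names
  structure(list(labels = NULL, medoids = medoids,
                 basis = list(center = unlist(obj$center),
                              scale = unlist(obj$scale),
                              rotation = rotation),
                 pam = NULL, class_names = obj$class_names,
                 train_range = as.matrix(obj$train_range)),
            class = "temp_clustering")
}
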