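# PC-space heterogeneity over time and embedding-fidelity diagnostics.

#' Fit the morphometrics PC space
#'
#' Z-scales each feature (constant features are dropped with a warning) and
#' fits the top principal components. Distances downstream are computed in
#' this space. When the analysis population is a subset (e.g. untreated
#' wells only), fit on the full table first and subset afterwards so the
#' numerical space is preserved.
#'
#' @param table Morphometrics tibble (id columns + feature columns).
#' @param n_components Number of components (default 20).
#' @param feature_cols Feature column names; default: all numeric columns
#'   except `loop`.
#' @return Object of class `pc_space` with the scaler, rotation and
#'   explained-variance fractions.
#' @export
fit_pc_space <- function(table, n_components = 20L, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    num <- vapply(table, is.numeric, logical(1))
    feature_cols <- setdiff(names(table)[num], c("loop"))
  }
  X <- as.matrix(table[, feature_cols])
  if (anyNA(X)) stop("missing values in feature columns")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped: ",
            paste(utils::head(feature_cols[!keep], 5), collapse = ", "))
  }
  X <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sd[keep])
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  structure(list(center = mu[keep], scale = sd[keep],
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
                 feature_cols = feature_cols[keep],
                 n_components = n_components),
            class = "pc_space")
}

#' Project rows into a fitted PC space
#' @param space A `pc_space`.
#' @param table Morphometrics tibble containing the fitted feature columns.
#' @return Tibble: id columns (any non-feature columns of `table`) plus
#'   `PC1..PCk`.
#' @export
project_pc_space <- function(space, table) {
  stopifnot(inherits(space, "pc_space"))
  X <- as.matrix(table[, space$feature_cols])
  Z <- scale(X, center = space$center, scale = space$scale)
  P <- Z %*% space$rotation
  colnames(P) <- paste0("PC", seq_len(ncol(P)))
  dplyr::bind_cols(table[, setdiff(names(table), space$feature_cols),
                         drop = FALSE],
                   tibble::as_tibble(P))
}

pc_matrix <- function(pcs) {
  as.matrix(pcs[, grep("^PC[0-9]+$", names(pcs)), drop = FALSE])
}

#' Mean pairwise inter-organoid distance per loop
#'
#' Euclidean distance in PC space between all organoid pairs present at
#' each loop, averaged over unordered pairs.
#'
#' @param pcs Projected tibble with `experiment_id`, `well_id`, `loop` and
#'   PC columns.
#' @return Tibble `loop`, `n`, `mean_distance`.
#' @export
inter_organoid_distance <- function(pcs) {
  dplyr::group_by(pcs, .data$loop) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) stop("need >= 2 organoids at loop ", key$loop)
      tibble::tibble(n = nrow(d),
                     mean_distance = mean(stats::dist(pc_matrix(d))))
    }) |>
    dplyr::ungroup()
}

#' Per-loop intra-organoid change with quantile capping
#'
#' Euclidean distance between each organoid's consecutive PC vectors (loop
#' n vs n+1); pairs across a gap in accepted loops are skipped. The pooled
#' series is winsorized at the stated percentiles before aggregation, and
#' mean +/- SEM per loop is reported (SEM = sd/sqrt(n) over organoids).
#'
#' @param pcs Projected tibble.
#' @param cap_lo,cap_hi Winsorization percentiles (defaults 0.025 / 0.975).
#' @return List with `steps` (per organoid-step capped distances) and
#'   `per_loop` (loop, n, mean_change, sem).
#' @export
intra_organoid_change <- function(pcs, cap_lo = 0.025, cap_hi = 0.975) {
  steps <- dplyr::group_by(pcs, .data$experiment_id, .data$well_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$loop), ]
      if (nrow(d) < 2) return(tibble::tibble())
      M <- pc_matrix(d)
      consec <- diff(d$loop) == 1L
      if (!any(consec)) return(tibble::tibble())
      dd <- sqrt(rowSums((M[-1, , drop = FALSE] -
                          M[-nrow(M), , drop = FALSE])^2))
      tibble::tibble(loop = d$loop[-nrow(d)][consec],
                     change = dd[consec])
    }) |>
    dplyr::ungroup()
  if (nrow(steps) == 0) stop("no organoid has >= 2 consecutive loops")
  caps <- stats::quantile(steps$change, c(cap_lo, cap_hi), names = FALSE)
  steps$change_capped <- pmin(pmax(steps$change, caps[1]), caps[2])
  per_loop <- dplyr::group_by(steps, .data$loop) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_change = mean(.data$change_capped),
                     sem = stats::sd(.data$change_capped) / sqrt(dplyr::n()),
                     .groups = "drop")
  list(steps = steps, per_loop = per_loop)
}

# k-nearest-neighbour index matrix (self excluded, ties broken by index)
knn_indices <- function(X, k) {
  n <- nrow(X)
  stopifnot(k < n)
  D <- as.matrix(stats::dist(X))
  t(vapply(seq_len(n), function(i) {
    o <- order(D[i, ], seq_len(n))   # deterministic tie-break by index
    o[o != i][seq_len(k)]
  }, integer(k)))
}

#' Neighbour-preservation Jaccard index
#'
#' For each point, the Jaccard index between its k nearest neighbours in
#' the high-dimensional space and in the embedding (self excluded);
#' quantifies how faithfully a 2-D embedding preserves local structure.
#'
#' @param high Matrix or tibble of high-dimensional coordinates.
#' @param embedded Matrix or tibble of embedding coordinates (same rows).
#' @param k Neighbourhood size (default 30).
#' @return Numeric vector of per-point Jaccard indices.
#' @export
neighbor_preservation_jaccard <- function(high, embedded, k = 30L) {
  H <- as.matrix(high); E <- as.matrix(embedded)
  stopifnot(nrow(H) == nrow(E), nrow(H) >= k + 1L)
  nh <- knn_indices(H, k)
  ne <- knn_indices(E, k)
  vapply(seq_len(nrow(H)), function(i) {
    a <- nh[i, ]; b <- ne[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
}

#' Fraction of nearest neighbours from the same organoid
#'
#' Pools rows across loops and organoids, finds each row's k nearest
#' neighbours, and reports the fraction that carry the same organoid label.
#'
#' @param X Matrix or tibble of coordinates.
#' @param organoid Organoid label per row.
#' @param k Neighbourhood size (default 30).
#' @return Numeric vector of per-row fractions.
#' @export
same_organoid_neighbor_fraction <- function(X, organoid, k = 30L) {
  X <- as.matrix(X)
  stopifnot(length(organoid) == nrow(X), nrow(X) >= k + 1L)
  nn <- knn_indices(X, k)
  vapply(seq_len(nrow(X)), function(i)
    mean(organoid[nn[i, ]] == organoid[i]), numeric(1))
}
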