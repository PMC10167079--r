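#' Fit xDAWN spatial filters
#'
#' xDAWN enhances the evoked response of each class by maximising the ratio
#' of evoked-signal power to total signal-plus-noise power. For class `c`
#' with class-average evoked `E_c` (channels x samples), the signal
#' covariance is `S_c = E_c E_c' / n_samples` and the total covariance is
#' the trial average `T = mean_i X_i X_i' / n_samples`. Filters are the
#' leading generalized eigenvectors `w` of `(S_c, T)`, i.e. maximisers of
#' the Rayleigh quotient `w'S_c w / w'T w`.
#'
#' Numerically, `T` receives a diagonal shrinkage of
#' `1e-10 * trace(T) / n_channels`, is Cholesky-whitened, and an ordinary
#' symmetric eigendecomposition is performed in whitened space. Filter rows
#' are unit-norm with the first non-zero coefficient made positive;
#' forward patterns are `T w`, normalised.
#'
#' @param epochs an [epoch_set()] (training data only).
#' @param labels per-trial class labels; defaults to the epoch condition
#'   labels.
#' @param n_components number of filters per class (default 5); must not
#'   exceed the channel count.
#' @return A `SpatialFilterSet`: list with `filters` and `patterns`
#'   (per-class `n_components x n_channels` matrices), `eigenvalues`
#'   (per-class, descending), `class_labels`, `n_components`.
#' @export
xdawn_fit <- function(epochs, labels = NULL, n_components = 5) {
  labels <- factor(labels %||% epochs$trial_labels)
  nc <- n_channels(epochs)
  ns <- n_samples(epochs)
  if (n_components > nc)
    stop("`n_components` must not exceed the number of channels")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 trials")

  # total covariance over all trials, via one unfolded crossproduct
  M <- matrix(aperm(epochs$data, c(2, 3, 1)), nc)
  Tcov <- tcrossprod(M) / (n_trials(epochs) * ns)
  eps <- 1e-10 * sum(diag(Tcov)) / nc
  Tcov <- Tcov + diag(eps, nc)

  # whitening: T = L L'
  L <- t(chol(Tcov))
  Linv <- forwardsolve(L, diag(nc))

  filters <- list(); patterns <- list(); eigenvalues <- list()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    E <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
    S <- tcrossprod(E) / ns
    M <- Linv %*% S %*% t(Linv)
    M <- (M + t(M)) / 2
    eg <- eigen(M, symmetric = TRUE)
    W <- t(Linv) %*% eg$vectors[, seq_len(n_components), drop = FALSE]
    W <- apply(W, 2, function(w) {
      w <- w / sqrt(sum(w^2))
      j <- which(abs(w) > 1e-12)[1]
      if (!is.na(j) && w[j] < 0) w <- -w
      w
    })
    filters[[cl]] <- t(W)                       # n_components x n_channels
    P <- Tcov %*% W
    patterns[[cl]] <- t(apply(P, 2, function(p) p / sqrt(sum(p^2))))
    eigenvalues[[cl]] <- eg$values[seq_len(n_components)]
  }
  structure(
    list(filters = filters, patterns = patterns, eigenvalues = eigenvalues,
         class_labels = levels(labels), n_components = n_components,
         n_channels = nc),
    class = "SpatialFilterSet")
}

#' @export
print.SpatialFilterSet <- function(x, ...) {
  cat(sprintf("<SpatialFilterSet> %d components x %d classes (%s), %d channels\n",
              x$n_components, length(x$class_labels),
              paste(x$class_labels, collapse = ", "), x$n_channels))
  for (cl in x$class_labels)
    cat(sprintf("  %s: eigenvalues %s\n", cl,
                paste(signif(x$eigenvalues[[cl]], 3), collapse = ", ")))
  invisible(x)
}

#' Apply xDAWN filters to epochs
#'
#' Projects each trial onto the fitted filters, yielding
#' `n_classes x n_components` virtual channels per trial (per-class filter
#' blocks concatenated in class-label order). The time axis is unchanged.
#'
#' @param filterset a `SpatialFilterSet` from [xdawn_fit()].
#' @param epochs an [epoch_set()] with the same channel count as at fit
#'   time.
#' @return An `EpochSet` of virtual channels.
#' @export
xdawn_transform <- function(filterset, epochs) {
  if (n_channels(epochs) != filterset$n_channels)
    stop("channel count differs from the fitted filter set")
  W <- do.call(rbind, filterset$filters[filterset$class_labels])
  nv <- nrow(W)
  ntr <- n_trials(epochs)
  ns <- n_samples(epochs)
  # multiply all trials at once on the channels-unfolded data
  M <- W %*% matrix(aperm(epochs$data, c(2, 3, 1)), filterset$n_channels)
  out <- aperm(array(M, c(nv, ns, ntr)), c(3, 1, 2))
  vnames <- unlist(lapply(filterset$class_labels, function(cl)
    sprintf("xd_%s_%d", cl, seq_len(filterset$n_components))))
  epoch_set(out, epochs$sfreq, epochs$times, epochs$trial_labels,
            epochs$correctness, epochs$rt, epochs$participant_id,
            epochs$group_label, channel_names = vnames)
}

#' Serialize / restore a SpatialFilterSet as JSON
#'
#' Matrices are stored row-major with shape metadata for audit and reuse.
#'
#' @param filterset a `SpatialFilterSet`.
#' @param path file path.
#' @return `xdawn_to_json` returns `path` invisibly; `xdawn_from_json`
#'   returns the restored `SpatialFilterSet`.
#' @export
xdawn_to_json <- function(filterset, path) {
  ser <- function(m) list(shape = dim(m), data = as.vector(t(m)))
  obj <- list(class_labels = filterset$class_labels,
              n_components = filterset$n_components,
              n_channels = filterset$n_channels,
              filters = lapply(filterset$filters, ser),
              patterns = lapply(filterset$patterns, ser),
              eigenvalues = filterset$eigenvalues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname xdawn_to_json
#' @export
xdawn_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- function(s) matrix(s$data, nrow = s$shape[1], byrow = TRUE)
  structure(
    list(filters = lapply(obj$filters, des),
         patterns = lapply(obj$patterns, des),
         eigenvalues = obj$eigenvalues,
         class_labels = obj$class_labels,
         n_components = obj$n_components, n_channels = obj$n_channels),
    class = "SpatialFilterSet")
}
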