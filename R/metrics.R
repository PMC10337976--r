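# Similarity and validation statistics: masked normalized cross-correlation,
# nearest-injection pairing, permutation tests, Dice overlap, and landmark
# displacement reports.

#' Masked normalized cross-correlation
#'
#' Zero-mean, unit-variance Pearson correlation of two co-registered volumes
#' over a mask (default: the union of their nonzero support), the similarity
#' measure used between tracer images.
#'
#' @param a,b [voxel_grid]s (or plain arrays) on the same grid.
#' @param mask Optional mask [voxel_grid] / logical array selecting voxels.
#' @return Scalar in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "voxel_grid")) a$data else a
  bv <- if (inherits(b, "voxel_grid")) b$data else b
  if (!identical(dim(av), dim(bv))) stop("grids do not match")
  m <- if (is.null(mask)) {
    (av != 0) | (bv != 0)
  } else {
    (if (inherits(mask, "voxel_grid")) mask$data else mask) > 0
  }
  x <- av[m]
  y <- bv[m]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate NCC: fewer than 2 masked voxels or zero variance")
  }
  stats::cor(x, y)
}

#' Pair injection sites by centroid distance
#'
#' Pairs each site in `sites_a` with the nearest-centroid site in `sites_b`
#' (Euclidean distance in a common space), the rule used to match
#' anterograde and retrograde injections. Ties break toward the earlier
#' identifier.
#'
#' @param sites_a,sites_b Non-empty lists of `injection_site` objects (or
#'   anything with a `centroid` field), optionally named.
#' @return Data frame with columns `a`, `b`, `distance` (micrometers).
#' @export
pair_by_injection_distance <- function(sites_a, sites_b) {
  if (length(sites_a) == 0 || length(sites_b) == 0) stop("empty site list")
  ca <- do.call(rbind, lapply(sites_a, function(s) s$centroid))
  cb <- do.call(rbind, lapply(sites_b, function(s) s$centroid))
  ids_a <- names(sites_a) %||% as.character(seq_along(sites_a))
  ids_b <- names(sites_b) %||% as.character(seq_along(sites_b))
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  j <- max.col(-d2, ties.method = "first")
  data.frame(
    a = ids_a, b = ids_b[j],
    distance = sqrt(pmax(0, d2[cbind(seq_along(j), j)]))
  )
}

#' Pairwise NCC similarity matrix
#'
#' @param items Named list of [voxel_grid]s (e.g. flat stacks of tracer
#'   signal) on one grid.
#' @param mask Optional shared mask (default: union of nonzero support of
#'   each pair).
#' @param items_b Optional second list; omitted means `items` vs itself
#'   (symmetric with unit diagonal).
#' @return A matrix with `NA` for degenerate entries; attribute
#'   `symmetric` set accordingly.
#' @export
similarity_matrix <- function(items, mask = NULL, items_b = NULL) {
  sym <- is.null(items_b)
  if (sym) items_b <- items
  n1 <- length(items)
  n2 <- length(items_b)
  M <- matrix(NA_real_, n1, n2)
  rownames(M) <- names(items) %||% as.character(seq_len(n1))
  colnames(M) <- names(items_b) %||% as.character(seq_len(n2))
  for (i in seq_len(n1)) {
    jmax <- if (sym) i else n2
    for (j in seq_len(jmax)) {
      v <- tryCatch(ncc(items[[i]], items_b[[j]], mask), error = function(e) NA_real_)
      M[i, j] <- v
      if (sym) M[j, i] <- v
    }
  }
  if (sym) diag(M) <- 1
  attr(M, "symmetric") <- sym
  M
}

#' Correlation permutation test
#'
#' Tests the correlation between two vectors (or the strict upper triangles
#' of two symmetric matrices) against a permutation null, with the add-one
#' correction `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_reps)` so a p-value
#' of 0 is never reported (at one million repetitions a maximally extreme
#' statistic reports p < 1e-6).
#'
#' @param x,y Numeric vectors of equal length (>= 3), or `NULL` when
#'   `matrices` is given.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_reps Number of permutations.
#' @param seed Integer RNG seed.
#' @param matrices Optional list of two same-size symmetric matrices whose
#'   strict upper triangles supply `x` and `y`.
#' @return A `permutation_result`: `observed`, `p_value`, `n_reps`,
#'   `method`, `seed`.
#' @export
corr_perm_test <- function(x = NULL, y = NULL,
                           method = c("pearson", "spearman"),
                           n_reps = 10000L, seed = 1, matrices = NULL) {
  method <- match.arg(method)
  if (!is.null(matrices)) {
    ut <- upper.tri(matrices[[1]])
    x <- matrices[[1]][ut]
    y <- matrices[[2]][ut]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  obs <- sum(zx * zy) / (n - 1)
  set.seed(seed)
  # permuted correlations as one matrix product over permutation columns
  P <- matrix(0, n, n_reps)
  for (r in seq_len(n_reps)) P[, r] <- zy[sample.int(n)]
  rp <- as.numeric(zx %*% P) / (n - 1)
  p <- (1 + sum(abs(rp) >= abs(obs) - 1e-12)) / (1 + n_reps)
  structure(
    list(
      observed = obs, p_value = p, n_reps = n_reps, method = method,
      seed = seed
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s r = %.4f, p = %.3g (%d reps)\n",
    x$method, x$observed, x$p_value, x$n_reps
  ))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' perfectly overlapping (Dice 1, with a message).
#'
#' @param m1,m2 Mask [voxel_grid]s on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(m1, m2) {
  if (!identical(dim(m1$data), dim(m2$data))) stop("mask grids do not match")
  a <- m1$data > 0
  b <- m2$data > 0
  if (!any(a) && !any(b)) {
    message("dice: both masks empty; defined as 1")
    return(1)
  }
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Landmark displacement report
#'
#' Compares two displacement populations per landmark: group 1, the
#' displacements between the same landmark placed by different human
#' experts; group 2, expert vs automatically mapped landmark. Reports
#' per-landmark/subject medians and the fraction of cells where the
#' automation agrees with the experts more closely than the experts agree
#' among themselves (ties count as manual wins).
#'
#' @param manual List (per subject) of lists (per expert) of named numeric
#'   landmark matrices (rows = landmarks, 3 columns, world micrometers).
#' @param auto List (per subject) of named landmark matrices from the
#'   automatic mapping.
#' @return A `displacement_report`: `per_cell` data frame (subject,
#'   landmark, median group-1 and group-2 displacement), `auto_closer_frac`,
#'   `n_excluded` (landmarks missing from some set).
#' @export
landmark_report <- function(manual, auto) {
  stopifnot(length(manual) == length(auto))
  rows <- list()
  n_excluded <- 0L
  for (s in seq_along(manual)) {
    experts <- manual[[s]]
    if (length(experts) < 2) stop("need at least 2 experts per subject")
    lms <- Reduce(intersect, lapply(experts, rownames))
    lms_all <- Reduce(union, lapply(experts, rownames))
    miss <- setdiff(union(lms_all, rownames(auto[[s]])), intersect(lms, rownames(auto[[s]])))
    n_excluded <- n_excluded + length(miss)
    lms <- intersect(lms, rownames(auto[[s]]))
    for (lm in lms) {
      pts <- lapply(experts, function(e) e[lm, ])
      g1 <- c()
      for (i in seq_along(pts)) {
        for (j in seq_len(i - 1)) {
          g1 <- c(g1, sqrt(sum((pts[[i]] - pts[[j]])^2)))
        }
      }
      g2 <- vapply(pts, function(p) sqrt(sum((p - auto[[s]][lm, ])^2)), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, landmark = lm,
        median_manual = stats::median(g1), median_auto = stats::median(g2)
      )
    }
  }
  per_cell <- do.call(rbind, rows)
  structure(
    list(
      per_cell = per_cell,
      auto_closer_frac = mean(per_cell$median_auto < per_cell$median_manual),
      n_excluded = n_excluded
    ),
    class = "displacement_report"
  )
}

#' @export
print.displacement_report <- function(x, ...) {
  cat(sprintf(
    "<displacement_report> %d landmark/subject cells; automation closer in %.1f%% (%d excluded)\n",
    nrow(x$per_cell), 100 * x$auto_closer_frac, x$n_excluded
  ))
  invisible(x)
}
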