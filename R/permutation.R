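#' Within-participant paired shuffle test with Z calibration
#'
#' The observed statistic is the mean over subjects of the paired
#' difference a - b. A permutation null is built by independently
#' swapping each subject's pair (a sign flip of the difference) on every
#' iteration; the observed statistic is converted to a standard Z value
#' against the null's mean and standard deviation and then to a
#' two-sided normal p value.
#'
#' @param values_a,values_b Paired per-subject values (equal length >= 2).
#' @param n_iter Number of shuffle iterations (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `permutation_result`: `observed_stat`,
#'   `null_mean`, `null_sd`, `z_value`, `p_value`, `n_iterations`,
#'   `seed`, `degenerate` (all differences zero: Z = 0, p = 1).
#' @export
paired_shuffle_test <- function(values_a, values_b, n_iter = 1000L,
                                seed = NULL) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2,
            n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- values_a - values_b
  n <- length(d)
  obs <- mean(d)
  flips <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
  null <- as.vector(flips %*% d) / n
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) 0 else (obs - null_mean) / null_sd
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  structure(
    list(observed_stat = obs, null_mean = null_mean, null_sd = null_sd,
         z_value = z, p_value = p, n_iterations = as.integer(n_iter),
         seed = seed, degenerate = degenerate),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("shuffle test: obs = %.4f, Z = %.3f, p = %.4g (%d iterations)%s\n",
              x$observed_stat, x$z_value, x$p_value, x$n_iterations,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Spatial cluster-based permutation test over electrodes
#'
#' Per electrode, the paired shuffle test of [paired_shuffle_test()] is
#' computed (one shared flip matrix re-used across electrodes for the
#' null moments). Electrodes whose Z value exceeds the two-sided
#' `alpha_thresh` threshold are clustered by montage adjacency,
#' separately for positive and negative signs; each cluster's mass is the
#' sum of its members' Z values. The null distribution records, per
#' iteration, the largest absolute cluster mass after applying one
#' subject-wise flip vector identically across electrodes (preserving the
#' spatial correlation structure) and re-standardizing against the
#' precomputed per-electrode null moments. Cluster p values are
#' `(1 + #null >= |mass|) / (1 + n_iter)`.
#'
#' @param values_a,values_b Subjects x electrodes matrices (equal
#'   dimensions; columns ordered as `montage$labels`).
#' @param montage An `electrode_montage`.
#' @param alpha_thresh A priori two-sided electrode threshold (default
#'   0.05).
#' @param n_iter Number of iterations (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `cluster_set`; each element is a
#'   `cluster_result` with `members` (electrode labels), `sign`, `mass`
#'   and `p_value`. The per-electrode Z map, threshold, seed and null
#'   distribution are attached as attributes. No supra-threshold
#'   electrode yields an empty list.
#' @export
spatial_cluster_test <- function(values_a, values_b, montage,
                                 alpha_thresh = 0.05, n_iter = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(montage, "electrode_montage"),
            is.matrix(values_a), is.matrix(values_b),
            all(dim(values_a) == dim(values_b)),
            ncol(values_a) == length(montage$labels),
            nrow(values_a) >= 2)
  if (!is.null(seed)) set.seed(seed)
  d <- values_a - values_b
  n <- nrow(d)
  n_el <- ncol(d)
  obs <- colMeans(d)

  flips <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
  null_m <- flips %*% d / n                       # n_iter x electrodes
  null_mu <- colMeans(null_m)
  null_sd <- sqrt(colMeans(null_m^2) - null_mu^2) *
    sqrt(n_iter / (n_iter - 1))
  ok <- is.finite(null_sd) & null_sd > 0
  z_obs <- numeric(n_el)
  z_obs[ok] <- (obs[ok] - null_mu[ok]) / null_sd[ok]

  zcrit <- stats::qnorm(1 - alpha_thresh / 2)
  nbr <- apply(montage$adjacency, 1L, which, simplify = FALSE)

  obs_clusters <- c(
    adjacency_clusters(which(z_obs > zcrit), nbr, z_obs, "positive"),
    adjacency_clusters(which(z_obs < -zcrit), nbr, z_obs, "negative")
  )

  null_max <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    zi <- numeric(n_el)
    zi[ok] <- (null_m[i, ok] - null_mu[ok]) / null_sd[ok]
    cl <- c(adjacency_clusters(which(zi > zcrit), nbr, zi, "positive"),
            adjacency_clusters(which(zi < -zcrit), nbr, zi, "negative"))
    null_max[i] <- if (length(cl)) max(abs(vapply(cl, `[[`, 0, "mass"))) else 0
  }

  out <- lapply(obs_clusters, function(cl) {
    structure(
      list(members = montage$labels[cl$members],
           sign = cl$sign,
           mass = cl$mass,
           p_value = (1 + sum(null_max >= abs(cl$mass))) / (1 + n_iter),
           n_iterations = as.integer(n_iter),
           seed = seed),
      class = "cluster_result"
    )
  })
  out <- out[order(vapply(out, function(cl) -abs(cl$mass), 0))]
  attr(out, "z_map") <- stats::setNames(z_obs, montage$labels)
  attr(out, "z_threshold") <- zcrit
  attr(out, "null_max_mass") <- null_max
  class(out) <- "cluster_set"
  out
}

# connected components of `idx` (vertex indices) over neighbour lists,
# restricted to idx; returns list(members, mass, sign)
adjacency_clusters <- function(idx, nbr, z, sign) {
  if (!length(idx)) return(list())
  in_set <- logical(length(z))
  in_set[idx] <- TRUE
  seen <- logical(length(z))
  out <- list()
  for (v in idx) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, u)
      nb <- nbr[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[[length(out) + 1L]] <- list(members = sort(comp),
                                    mass = sum(z[comp]), sign = sign)
  }
  out
}

#' Temporal cluster-based permutation test against a baseline
#'
#' Per timepoint, each subject's trace value is compared with that
#' subject's scalar baseline (mean over the baseline window) via the
#' paired shuffle test, using one shared flip matrix. Contiguous
#' same-sign supra-threshold runs of at least `min_run` timepoints form
#' clusters. Separate null distributions of the largest positive and
#' largest negative cluster mass are built per iteration, and each
#' observed cluster is tested against its own sign's null.
#'
#' @param baseline_values Per-subject scalar baseline (length n).
#' @param trace_values Subjects x timepoints matrix.
#' @param min_run Minimum cluster length in timepoints (default 20).
#' @param alpha_thresh A priori two-sided threshold (default 0.05).
#' @param n_iter Number of iterations (default 1000).
#' @param seed Optional integer seed.
#' @return List of class `temporal_cluster_set` with elements `positive`
#'   and `negative`, each a list of `cluster_result`s whose `members` are
#'   time indices (also reported as `interval = c(first, last)`).
#'   The per-timepoint Z map and the two null distributions are attached
#'   as attributes.
#' @export
temporal_cluster_test <- function(baseline_values, trace_values,
                                  min_run = 20L, alpha_thresh = 0.05,
                                  n_iter = 1000L, seed = NULL) {
  stopifnot(is.matrix(trace_values),
            length(baseline_values) == nrow(trace_values),
            nrow(trace_values) >= 2)
  if (ncol(trace_values) < min_run) {
    stop("trace has fewer timepoints than min_run", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- trace_values - baseline_values
  n <- nrow(d)
  nt <- ncol(d)
  obs <- colMeans(d)

  flips <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
  null_m <- flips %*% d / n
  null_mu <- colMeans(null_m)
  null_sd <- sqrt(colMeans(null_m^2) - null_mu^2) *
    sqrt(n_iter / (n_iter - 1))
  ok <- is.finite(null_sd) & null_sd > 0
  z_obs <- numeric(nt)
  z_obs[ok] <- (obs[ok] - null_mu[ok]) / null_sd[ok]
  zcrit <- stats::qnorm(1 - alpha_thresh / 2)

  obs_pos <- run_clusters(z_obs, zcrit, min_run, "positive")
  obs_neg <- run_clusters(z_obs, zcrit, min_run, "negative")

  null_pos <- numeric(n_iter)
  null_neg <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    zi <- numeric(nt)
    zi[ok] <- (null_m[i, ok] - null_mu[ok]) / null_sd[ok]
    cp <- run_clusters(zi, zcrit, min_run, "positive")
    cn <- run_clusters(zi, zcrit, min_run, "negative")
    null_pos[i] <- if (length(cp)) max(vapply(cp, `[[`, 0, "mass")) else 0
    null_neg[i] <- if (length(cn)) min(vapply(cn, `[[`, 0, "mass")) else 0
  }

  wrap <- function(cl, null_dist, greater) {
    lapply(cl, function(x) {
      p <- if (greater) {
        (1 + sum(null_dist >= x$mass)) / (1 + n_iter)
      } else {
        (1 + sum(null_dist <= x$mass)) / (1 + n_iter)
      }
      structure(
        list(members = x$members,
             interval = c(x$members[1L], x$members[length(x$members)]),
             sign = x$sign, mass = x$mass, p_value = p,
             n_iterations = as.integer(n_iter), seed = seed),
        class = "cluster_result"
      )
    })
  }
  out <- list(positive = wrap(obs_pos, null_pos, TRUE),
              negative = wrap(obs_neg, null_neg, FALSE))
  attr(out, "z_map") <- z_obs
  attr(out, "z_threshold") <- zcrit
  attr(out, "null_max_pos") <- null_pos
  attr(out, "null_max_neg") <- null_neg
  class(out) <- "temporal_cluster_set"
  out
}

# contiguous same-sign supra-threshold runs of length >= min_run
run_clusters <- function(z, zcrit, min_run, sign) {
  supra <- if (sign == "positive") z > zcrit else z < -zcrit
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  lapply(keep, function(k) {
    members <- starts[k]:ends[k]
    list(members = members, mass = sum(z[members]), sign = sign)
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("%s cluster: %d members, mass %.2f, p = %.4g\n",
              x$sign, length(x$members), x$mass, x$p_value))
  invisible(x)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", length(x)))
  for (cl in x) print(cl)
  invisible(x)
}

#' @export
print.temporal_cluster_set <- function(x, ...) {
  cat(sprintf("<temporal_cluster_set> %d positive, %d negative\n",
              length(x$positive), length(x$negative)))
  for (cl in c(x$positive, x$negative)) print(cl)
  invisible(x)
}

#' Export cluster results as JSON
#'
#' @param clusters A `cluster_set` or `temporal_cluster_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clusters, path) {
  flat <- if (inherits(clusters, "temporal_cluster_set")) {
    c(clusters$positive, clusters$negative)
  } else {
    unclass(clusters)
  }
  payload <- lapply(flat, function(cl) {
    list(members = cl$members, sign = cl$sign, mass = cl$mass,
         p_value = cl$p_value, n_iterations = cl$n_iterations,
         seed = cl$seed)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
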