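# Mass-univariate statistics: one-sample and paired cluster-mass permutation
# tests over sensors or time, t_max reporting, and global field power.

# ---------------------------------------------------------------------------
# Adjacency

#' Sensor adjacency from montage coordinates
#'
#' Connects every pair of channels closer than `threshold` (in the units of
#' the coordinates). The result is symmetric, has no self-neighbors, and
#' lists every channel.
#'
#' @param coords data.frame with columns `channel`, `x`, `y` (and optionally
#'   `z`).
#' @param threshold Distance threshold.
#' @return A named list of neighbor index vectors (class `sensor_adjacency`).
#' @export
montage_adjacency <- function(coords, threshold) {
  xyz <- as.matrix(coords[, intersect(c("x", "y", "z"), names(coords))])
  d <- as.matrix(stats::dist(xyz))
  adj <- lapply(seq_len(nrow(d)), function(i)
    which(d[i, ] <= threshold & seq_len(ncol(d)) != i))
  names(adj) <- coords$channel
  structure(adj, class = "sensor_adjacency")
}

#' Adjacency from an explicit edge list
#'
#' @param edges Two-column matrix/data.frame of channel indices or names.
#' @param channels Channel names (defines the channel order and count).
#' @return A named list of neighbor index vectors (class `sensor_adjacency`).
#' @export
edge_adjacency <- function(edges, channels) {
  n <- length(channels)
  e <- as.matrix(edges)
  if (is.character(e)) e <- matrix(match(e, channels), ncol = 2)
  if (anyNA(e)) stopf("edge list names unknown channels")
  adj <- lapply(seq_len(n), function(i)
    sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))))
  names(adj) <- channels
  structure(adj, class = "sensor_adjacency")
}

#' Chain adjacency over time samples
#'
#' Temporal clustering adjacency: each sample neighbors its predecessor and
#' successor.
#'
#' @param n Number of samples.
#' @return A `sensor_adjacency` list.
#' @export
chain_adjacency <- function(n) {
  adj <- lapply(seq_len(n), function(i)
    c(if (i > 1L) i - 1L, if (i < n) i + 1L))
  structure(adj, class = "sensor_adjacency")
}

check_adjacency <- function(adj, n) {
  if (length(adj) != n) stopf("adjacency covers %d channels, data has %d",
                              length(adj), n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (any(nb == i)) stopf("self-neighbor at channel %d", i)
    if (any(vapply(nb, function(j) !(i %in% adj[[j]]), logical(1)))) {
      stopf("adjacency is not symmetric at channel %d", i)
    }
  }
  invisible(TRUE)
}

# connected components of supra-threshold entries (observed data)
find_clusters <- function(t_vals, thr, adj, tail) {
  n <- length(t_vals)
  out <- list()
  for (sgn in if (tail == "greater") 1 else c(1, -1)) {
    supra <- which(sgn * t_vals >= thr)
    seen <- logical(n)
    for (c0 in supra) {
      if (seen[c0]) next
      members <- integer(0)
      stack <- c0
      seen[c0] <- TRUE
      while (length(stack)) {
        c <- stack[length(stack)]; stack <- stack[-length(stack)]
        members <- c(members, c)
        for (k in adj[[c]]) {
          if (!seen[k] && sgn * t_vals[k] >= thr) {
            seen[k] <- TRUE; stack <- c(stack, k)
          }
        }
      }
      out[[length(out) + 1L]] <- list(members = sort(members),
                                      mass = sum(t_vals[members]),
                                      sign = sgn)
    }
  }
  out
}

one_sample_t <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  m / (s / sqrt(n))
}

sign_flip_matrix <- function(n_subjects, n_perm, seed) {
  if (2^n_subjects <= n_perm) {
    codes <- 0:(2^n_subjects - 1)
    flips <- t(vapply(codes, function(k)
      1 - 2 * as.integer(intToBits(k)[seq_len(n_subjects)]),
      numeric(n_subjects)))
    list(flips = flips, complete = TRUE)
  } else {
    flips <- with_seed(seed, matrix(sample(c(-1, 1),
                                           n_perm * n_subjects,
                                           replace = TRUE),
                                    n_perm, n_subjects))
    flips[1, ] <- 1 # the identity permutation is always in the null set
    list(flips = flips, complete = FALSE)
  }
}

cluster_result <- function(clusters, t_vals, null_max, thr, complete, tail) {
  res <- lapply(clusters, function(cl) {
    obs <- abs(cl$mass)
    list(members = cl$members,
         mass = cl$mass,
         p = mean(null_max >= obs - 1e-12),
         t_max = max(abs(t_vals[cl$members])),
         sign = cl$sign)
  })
  structure(list(clusters = res, t = t_vals, threshold = thr,
                 n_perm = length(null_max), complete_enumeration = complete,
                 tail = tail),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations%s\n",
              length(x$clusters), x$n_perm,
              if (x$complete_enumeration) " (complete enumeration)" else ""))
  for (cl in x$clusters) {
    cat(sprintf("  %d members, mass = %.2f, t_max = %.2f, p = %.4g\n",
                length(cl$members), cl$mass, cl$t_max, cl$p))
  }
  invisible(x)
}

#' Cluster table as a data.frame
#'
#' @param x A `cluster_result`.
#' @return data.frame with one row per cluster: `n_members`, `members`
#'   (comma-separated), `mass`, `t_max`, `p`.
#' @export
cluster_table <- function(x) {
  if (!length(x$clusters)) {
    return(data.frame(n_members = integer(0), members = character(0),
                      mass = numeric(0), t_max = numeric(0), p = numeric(0)))
  }
  data.frame(
    n_members = vapply(x$clusters, function(c) length(c$members), integer(1)),
    members = vapply(x$clusters, function(c)
      paste(c$members, collapse = ","), character(1)),
    mass = vapply(x$clusters, function(c) c$mass, numeric(1)),
    t_max = vapply(x$clusters, function(c) c$t_max, numeric(1)),
    p = vapply(x$clusters, function(c) c$p, numeric(1)))
}

# ---------------------------------------------------------------------------
# Tests

#' One-sample cluster-mass permutation test
#'
#' Mass-univariate one-sample t test against zero at each channel, using the
#' t value equivalent to uncorrected `p <= alpha_form` as the cluster-forming
#' threshold. Supra-threshold channels are clustered by adjacency and each
#' cluster's mass (sum of member t values) is compared against the null
#' distribution of the maximum cluster mass over whole-subject sign flips.
#' When `2^n_subjects <= n_perm` the complete set of sign flips is enumerated
#' (deterministic and seed-independent); otherwise `n_perm` random flips are
#' drawn, always including the identity, so p > 0.
#'
#' @param values Subject x channel matrix (e.g. per-subject delta-z).
#' @param adjacency A `sensor_adjacency` covering the channels.
#' @param tail `"greater"` (one-sided, default) or `"two-sided"`.
#' @param alpha_form Cluster-forming uncorrected alpha (default 0.05).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for random sign flips.
#' @return A `cluster_result`; empty cluster list if nothing is
#'   supra-threshold.
#' @export
cluster_test_one_sample <- function(values, adjacency,
                                    tail = c("greater", "two-sided"),
                                    alpha_form = 0.05, n_perm = 10000,
                                    seed = NULL) {
  tail <- match.arg(tail)
  values <- as.matrix(values)
  n_sub <- nrow(values)
  if (n_sub < 2L) stopf("need at least 2 subjects")
  check_adjacency(adjacency, ncol(values))
  df <- n_sub - 1L
  thr <- if (tail == "greater") stats::qt(1 - alpha_form, df) else
    stats::qt(1 - alpha_form / 2, df)

  t_obs <- one_sample_t(values)
  clusters <- find_clusters(t_obs, thr, adjacency, tail)

  sf <- sign_flip_matrix(n_sub, n_perm, seed)
  # sign flips leave per-channel sums of squares unchanged, so the permuted
  # t statistics follow from the flipped means alone
  m <- (sf$flips %*% values) / n_sub
  ssq <- matrix(colSums(values^2), nrow(sf$flips), ncol(values), byrow = TRUE)
  sd_p <- sqrt(pmax(ssq - n_sub * m^2, 0) / df)
  t_perm <- m / (sd_p / sqrt(n_sub))
  null_max <- max_cluster_mass_cpp(t_perm, thr, unclass(adjacency),
                                   tail == "two-sided")
  cluster_result(clusters, t_obs, null_max, thr, sf$complete, tail)
}

#' Paired cluster-mass permutation test over time
#'
#' Paired t test per time sample on the condition difference, clustering
#' contiguous supra-threshold samples (two-sided by default), with a
#' sign-flip null on the subject differences — used to compare mTRF global
#' field power between task conditions.
#'
#' @param cond_a,cond_b Subject x time matrices on the same axis.
#' @param adjacency Optional temporal adjacency (default: chain).
#' @param tail `"two-sided"` (default) or `"greater"`.
#' @inheritParams cluster_test_one_sample
#' @return A `cluster_result` over time samples.
#' @export
cluster_test_paired <- function(cond_a, cond_b, adjacency = NULL,
                                tail = c("two-sided", "greater"),
                                alpha_form = 0.05, n_perm = 10000,
                                seed = NULL) {
  tail <- match.arg(tail)
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  if (!identical(dim(cond_a), dim(cond_b))) {
    stopf("paired conditions must have identical subject x time shape")
  }
  adjacency <- adjacency %||% chain_adjacency(ncol(cond_a))
  cluster_test_one_sample(cond_a - cond_b, adjacency, tail = tail,
                          alpha_form = alpha_form, n_perm = n_perm,
                          seed = seed)
}

# ---------------------------------------------------------------------------
# Global field power

#' Global field power of a response over an ROI
#'
#' The across-channel standard deviation (population form, divisor `n`) of
#' the kernel values at each lag, over a region of interest. Invariant to a
#' common offset across channels; for two channels at `+a` and `-a` the GFP
#' is exactly `a`.
#'
#' @param kernel Channel x lag matrix, a `1 x lag x channel` array as stored
#'   in `trf_cv$trf`, or an `effective_rf`.
#' @param roi Channel indices (default: all channels).
#' @param mode `"sd"` (classic GFP, default) or `"rms"`.
#' @return Numeric vector over lags, >= 0.
#' @export
gfp <- function(kernel, roi = NULL, mode = c("sd", "rms")) {
  mode <- match.arg(mode)
  if (inherits(kernel, "effective_rf")) kernel <- kernel$kernel
  K <- as_kernel_matrix(kernel)
  roi <- roi %||% seq_len(nrow(K))
  if (!length(roi)) stopf("ROI must be a nonempty channel subset")
  K <- K[roi, , drop = FALSE]
  if (mode == "rms") {
    sqrt(colMeans(K^2))
  } else {
    sqrt(colMeans(K^2) - colMeans(K)^2)
  }
}
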