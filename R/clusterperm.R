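# Cluster-based permutation Spearman correlation tests on time-frequency
# maps: pixelwise Spearman rho between a per-subject scalar and the
# per-subject maps, p < alpha thresholding, 4-neighbour spectral-temporal
# clustering with separate positive and negative clusters, cluster mass
# = sum |rho|, and a max-cluster permutation null whose 97.5th percentile
# is the significance threshold.

.rank_scale <- function(m) {
  # column-wise average ranks, centred and scaled so crossprod gives rho
  r <- apply(m, 2, rank)
  r <- scale(r)
  r[is.nan(r)] <- NA  # zero-variance columns
  r
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Pixelwise Spearman correlation map
#'
#' Spearman rank correlation (average ranks for ties) between a
#' per-subject scalar and each pixel of the per-subject maps. Two-sided
#' p-values come from the exact permutation distribution of rho when
#' `n <= 9` subjects, and from the t approximation otherwise. Pixels with
#' zero variance are returned as `NA`.
#'
#' @param x Numeric vector, one scalar per subject (`length(x) >= 5`).
#' @param Y Numeric array `subjects x freqs x times` (or a matrix
#'   `subjects x pixels`).
#' @return Object of class `correlation_map`: `rho` and `p` matrices
#'   (freqs x times), `n`, and the map dimensions.
#' @export
spearman_map <- function(x, Y) {
  if (is.matrix(Y)) dim(Y) <- c(nrow(Y), ncol(Y), 1L)
  stopifnot(length(dim(Y)) == 3L, length(x) == dim(Y)[1])
  n <- length(x)
  if (n < 5) stop("at least 5 subjects are required")
  if (stats::sd(x) == 0) stop("x has zero variance")
  npx <- prod(dim(Y)[2:3])
  Ym <- matrix(Y, nrow = n, ncol = npx)
  Rs <- .rank_scale(Ym)
  rx <- as.numeric(scale(rank(x)))
  rho <- as.numeric(crossprod(rx, replace(Rs, is.na(Rs), 0))) / (n - 1)
  rho[colSums(is.na(Rs)) > 0] <- NA
  rho <- pmin(pmax(rho, -1), 1)
  if (n <= 9) {
    perms <- .all_permutations(n)
    P <- matrix(rx[perms], nrow = nrow(perms))  # permutations x n
    null_rho <- (P %*% replace(Rs, is.na(Rs), 0)) / (n - 1)
    p <- vapply(seq_len(npx), function(j) {
      mean(abs(null_rho[, j]) >= abs(rho[j]) - 1e-12)
    }, numeric(1))
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  p[is.na(rho)] <- NA
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  structure(list(rho = matrix(rho, dim(Y)[2], dim(Y)[3]),
                 p = matrix(p, dim(Y)[2], dim(Y)[3]), n = n),
            class = "correlation_map")
}

# connected components of a logical matrix under 4-neighbour adjacency;
# returns an integer label matrix (0 = background)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        lab[i, j] <- cur
        while (length(stack)) {
          px <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            a <- px[1] + d[1]; b <- px[2] + d[2]
            if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
                mask[a, b] && lab[a, b] == 0L) {
              lab[a, b] <- cur
              stack[[length(stack) + 1L]] <- c(a, b)
            }
          }
        }
      }
    }
  }
  lab
}

# observed clusters of a correlation map; mass = sum of |stat| over members
.find_clusters <- function(map, alpha, stat = NULL) {
  stat_m <- if (is.null(stat)) abs(map$rho) else abs(stat)
  supra <- !is.na(map$p) & map$p < alpha
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- supra & !is.na(map$rho) & (sign(map$rho) == sgn)
    lab <- .label_components(mask)
    if (max(lab) > 0) {
      for (k in seq_len(max(lab))) {
        members <- which(lab == k, arr.ind = TRUE)
        clusters[[length(clusters) + 1L]] <- list(
          pixels = members, sign = sgn,
          mass = sum(stat_m[members]))
      }
    }
  }
  clusters
}

#' Threshold a correlation map into spectral-temporal clusters
#'
#' Supra-threshold pixels (`p < alpha`) are partitioned into connected
#' components under 4-neighbour adjacency (one step along the frequency or
#' the time axis; no diagonal joins); positive-rho and negative-rho pixels
#' are never joined. Cluster mass is the sum of `|rho|` over members.
#'
#' @param map A [spearman_map()] result.
#' @param alpha Pixel threshold (default 0.05).
#' @return Object of class `cluster_result` holding the observed clusters
#'   (an empty list if no pixel is supra-threshold).
#' @export
threshold_clusters <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "correlation_map"), alpha > 0, alpha < 1)
  structure(list(clusters = .find_clusters(map, alpha),
                 alpha = alpha, null_distribution = NULL,
                 threshold = NA_real_, significant = logical(0)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), alpha = %g\n",
              length(x$clusters), x$alpha))
  if (length(x$clusters)) {
    m <- vapply(x$clusters, `[[`, numeric(1), "mass")
    s <- vapply(x$clusters, `[[`, numeric(1), "sign")
    sig <- if (length(x$significant)) x$significant else rep(NA, length(m))
    for (i in seq_along(m)) {
      cat(sprintf("  cluster %d: sign %+d, mass %.3f, significant: %s\n",
                  i, s[i], m[i], sig[i]))
    }
  }
  if (!is.na(x$threshold)) {
    cat(sprintf("  null 97.5th percentile: %.3f (%d permutations)\n",
                x$threshold, length(x$null_distribution)))
  }
  invisible(x)
}

#' Cluster-based permutation correlation test
#'
#' Each iteration randomly permutes the subject-to-scalar assignment,
#' recomputes the Spearman map and its clusters, and records the largest
#' cluster mass (0 when no cluster forms). Observed clusters of either
#' sign are significant when their mass exceeds the 97.5th percentile of
#' this max-mass null distribution (one null pooled across signs).
#'
#' @inheritParams spearman_map
#' @param alpha Pixel-level threshold (default 0.05).
#' @param n_permutations Number of permutations (default 1000, minimum 100).
#' @param seed Integer seed; the test is fully reproducible.
#' @return A `cluster_result` with observed clusters, `null_distribution`,
#'   `threshold` (97.5th percentile), `significant` flags and per-cluster
#'   Monte-Carlo `p_rank`.
#' @export
permutation_cluster_test <- function(x, Y, alpha = 0.05,
                                     n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) stop("use at least 100 permutations")
  if (is.matrix(Y)) dim(Y) <- c(nrow(Y), ncol(Y), 1L)
  n <- length(x)
  obs_map <- spearman_map(x, Y)
  observed <- .find_clusters(obs_map, alpha)
  # precompute pixel ranks once; only x is re-permuted
  npx <- prod(dim(Y)[2:3])
  Rs <- .rank_scale(matrix(Y, nrow = n, ncol = npx))
  Rs0 <- replace(Rs, is.na(Rs), 0)
  na_px <- colSums(is.na(Rs)) > 0
  rx <- as.numeric(scale(rank(x)))
  # p-value rule must match spearman_map: exact enumeration for n <= 9
  exact <- n <= 9
  if (exact) {
    pm_idx <- .all_permutations(n)
    P <- matrix(rx[pm_idx], nrow = nrow(pm_idx))
    null_abs <- abs(P %*% Rs0) / (n - 1)
    n_fact <- nrow(null_abs)
  }
  pixel_p <- function(rho) {
    if (exact) {
      vapply(seq_along(rho), function(j) {
        if (is.na(rho[j])) return(NA_real_)
        sum(null_abs[, j] >= abs(rho[j]) - 1e-12) / n_fact
      }, numeric(1))
    } else {
      tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      rp <- rx[sample.int(n)]
      rho <- as.numeric(crossprod(rp, Rs0)) / (n - 1)
      rho[na_px] <- NA
      rho <- pmin(pmax(rho, -1), 1)
      p <- pixel_p(rho)
      pm <- structure(list(rho = matrix(rho, dim(Y)[2], dim(Y)[3]),
                           p = matrix(p, dim(Y)[2], dim(Y)[3]), n = n),
                      class = "correlation_map")
      cl <- .find_clusters(pm, alpha)
      if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
    }, numeric(1))
  })
  threshold <- stats::quantile(null, 0.975, names = FALSE)
  masses <- vapply(observed, `[[`, numeric(1), "mass")
  significant <- masses > threshold
  p_rank <- vapply(masses, function(m) {
    (1 + sum(null >= m)) / (1 + n_permutations)
  }, numeric(1))
  structure(list(clusters = observed, alpha = alpha,
                 null_distribution = null, threshold = threshold,
                 significant = significant, p_rank = p_rank,
                 seed = seed, n_permutations = n_permutations,
                 map = obs_map),
            class = "cluster_result")
}

#' Run the full factorial battery of cluster-correlation tests
#'
#' One [permutation_cluster_test()] per (movement period, region,
#' intensity, block pair): the scalar is the subject's trial-averaged
#' pre-stimulation endogenous-exogenous frequency difference for that
#' period/region/intensity, the maps are the subjects' percent-change
#' event-related power between the block pair's time points. Cells missing
#' from either input are skipped with a log entry.
#'
#' @param scalars Data frame with columns `subject`, `period`, `region`,
#'   `intensity`, `value`.
#' @param maps Nested named list,
#'   `maps[[period]][[region]][[intensity]][[block_pair]]`, each element an
#'   array `subjects x freqs x times` with subject dimnames.
#' @param alpha,n_permutations As in [permutation_cluster_test()].
#' @param seed Master seed; each cell uses a derived substream.
#' @return List with `results` (named `cluster_result` list, keys
#'   `period/region/intensity/block_pair`) and a `summary` data frame.
#' @export
run_cluster_analysis <- function(scalars, maps, alpha = 0.05,
                                 n_permutations = 1000, seed = 1) {
  results <- list()
  summary_rows <- list()
  counter <- 0L
  for (period in names(maps)) {
    for (region in names(maps[[period]])) {
      for (intensity in names(maps[[period]][[region]])) {
        cell <- maps[[period]][[region]][[intensity]]
        sc <- scalars[scalars$period == period & scalars$region == region &
                        scalars$intensity == intensity, ]
        for (bp in names(cell)) {
          counter <- counter + 1L
          Y <- cell[[bp]]
          subj <- dimnames(Y)[[1]]
          if (is.null(subj) || !nrow(sc) ||
              !all(subj %in% sc$subject)) {
            tb_log("skipping cell ", period, "/", region, "/", intensity,
                   "/", bp, ": missing subjects or scalars")
            next
          }
          xv <- sc$value[match(subj, sc$subject)]
          res <- permutation_cluster_test(xv, Y, alpha, n_permutations,
                                          seed = derive_seed(seed, counter))
          key <- paste(period, region, intensity, bp, sep = "/")
          results[[key]] <- res
          summary_rows[[key]] <- data.frame(
            period = period, region = region, intensity = intensity,
            block_pair = bp, n_clusters = length(res$clusters),
            n_significant = sum(res$significant),
            max_mass = if (length(res$clusters))
              max(vapply(res$clusters, `[[`, numeric(1), "mass")) else 0,
            threshold = res$threshold, stringsAsFactors = FALSE)
        }
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  if (!is.null(summary)) rownames(summary) <- NULL
  list(results = results, summary = summary)
}
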