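#' Equal-cardinality (balanced) k-means
#'
#' k-means clustering under the constraint that every cluster contains
#' exactly `n / k` members, keeping clusters as spatially cohesive as the
#' constraint allows. Lloyd-style alternation where the assignment step is
#' not nearest-centroid but an *exact* balanced transportation solve: each
#' cluster has capacity `n / k` and the cost of assigning a point to a
#' cluster is its squared Euclidean distance to the centroid. Centroids are
#' then recomputed as cluster means and the two steps alternate until the
#' assignment is stable. The within-cluster sum of squares never increases
#' across iterations, so the algorithm terminates; the best of `n_restarts`
#' seeded k-means++ initializations is returned.
#'
#' The computation runs in a canonical row order (rows sorted by feature
#' values, then id), so the returned partition is invariant to permutations
#' of the input rows for a given `seed`, and distance ties resolve to the
#' lowest-sorting point.
#'
#' @param X Numeric feature matrix (e.g. from [standardize_features()]),
#'   one row per walker; row names are used as ids. A data frame of numeric
#'   columns is accepted.
#' @param k Number of clusters (default 5). `nrow(X)` must be divisible by
#'   `k`; otherwise an error asks the caller to trim or pad.
#' @param n_restarts Independent k-means++ initializations (default 32).
#' @param seed Integer seed making the whole run deterministic (default 1).
#' @param max_iter Iteration cap per restart (default 100; convergence is
#'   normally reached in far fewer).
#' @return An object of class `balanced_kmeans`: a list with `cluster`
#'   (named integer vector in input order, values `1..k`), `centers`
#'   (`k x p` matrix), `withinss` (per cluster), `tot_withinss` (the
#'   objective), `size`, `iter`, `restart` (index of the winning restart),
#'   `k`, `n`. Use [tidy()] / [glance()] for tibble views.
#' @examples
#' X <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 6), 4))
#' balanced_kmeans(X, k = 2, seed = 1)$size
#' @export
balanced_kmeans <- function(X, k = 5, n_restarts = 32, seed = 1,
                            max_iter = 100) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("X must not contain NA", class = "varietywalk_validation_error")
  n <- nrow(X)
  if (n %% k != 0L) {
    abort(paste0("n = ", n, " is not divisible by k = ", k,
                 "; trim or pad the cohort to equal group sizes"),
          class = "varietywalk_validation_error")
  }
  cap <- n %/% k
  ids <- rownames(X) %||% as.character(seq_len(n))
  ord <- do.call(order, c(unname(as.data.frame(X)), list(ids)))
  Xo <- X[ord, , drop = FALSE]

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(Xo, k)
    labels <- rep(0L, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      cost <- sq_dist_to_centers(Xo, centers)
      new_labels <- balanced_assignment_cpp(cost, rep(cap, k))
      centers <- update_centers(Xo, new_labels, k)
      if (identical(new_labels, labels) || iter >= max_iter) {
        labels <- new_labels
        break
      }
      labels <- new_labels
    }
    obj <- sum(sq_dist_to_centers(Xo, centers)[cbind(seq_len(n), labels)])
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(obj = obj, labels = labels, centers = centers,
                   iter = iter, restart = r)
    }
  }

  # canonical cluster numbering: by first appearance in canonical order
  new_of_old <- integer(k)
  new_of_old[unique(best$labels)] <- seq_len(k)
  labels_canon <- new_of_old[best$labels]
  centers <- update_centers(Xo, labels_canon, k)
  rownames(centers) <- seq_len(k)

  cluster <- integer(n)
  cluster[ord] <- labels_canon
  names(cluster) <- ids
  withinss <- vapply(seq_len(k), function(j) {
    d <- sweep(X[cluster == j, , drop = FALSE], 2L, centers[j, ], "-")
    sum(d^2)
  }, numeric(1))
  structure(list(cluster = cluster, centers = centers,
                 withinss = withinss, tot_withinss = sum(withinss),
                 size = as.integer(table(factor(cluster, levels = seq_len(k)))),
                 iter = best$iter, restart = best$restart, k = k, n = n),
            class = "balanced_kmeans")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  if (k > 1L) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
    }
  }
  centers
}

sq_dist_to_centers <- function(X, centers) {
  cross <- X %*% t(centers)
  sweep(sweep(-2 * cross, 1L, rowSums(X^2), "+"), 2L, rowSums(centers^2), "+")
}

update_centers <- function(X, labels, k) {
  centers <- matrix(0, k, ncol(X))
  for (j in seq_len(k)) {
    centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  centers
}

#' @export
print.balanced_kmeans <- function(x, ...) {
  cat(sprintf("<balanced_kmeans>  k = %d, n = %d (%d per cluster), WSS = %.4f\n",
              x$k, x$n, x$n %/% x$k, x$tot_withinss))
  invisible(x)
}

#' @rdname balanced_kmeans
#' @param x A `balanced_kmeans` object.
#' @param ... Unused.
#' @export
tidy.balanced_kmeans <- function(x, ...) {
  tibble(session_id = names(x$cluster), cluster = unname(x$cluster))
}

#' @rdname balanced_kmeans
#' @export
glance.balanced_kmeans <- function(x, ...) {
  tibble(k = x$k, n = x$n, tot_withinss = x$tot_withinss,
         iter = x$iter, restart = x$restart)
}

#' Split sessions into the clustered groups
#'
#' @param assignment A [balanced_kmeans()] result whose `cluster` names match
#'   the session ids.
#' @param sessions A list of [walk_session()] objects (or a tibble with
#'   `session` list column); every clustered id must be present.
#' @return A list of `k` lists of sessions, each of size `n / k`, ready for
#'   [build_infant_course()].
#' @export
cluster_to_groups <- function(assignment, sessions) {
  stopifnot(inherits(assignment, "balanced_kmeans"))
  if (is.data.frame(sessions) && "session" %in% names(sessions)) {
    sessions <- sessions$session
  }
  ids <- purrr::map_chr(sessions, function(s) attr(s, "session_id") %||% NA_character_)
  names(sessions) <- ids
  missing_ids <- setdiff(names(assignment$cluster), ids)
  if (length(missing_ids) > 0L) {
    abort(paste0("sessions missing for clustered id(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "varietywalk_validation_error")
  }
  lapply(seq_len(assignment$k), function(j) {
    unname(sessions[names(assignment$cluster)[assignment$cluster == j]])
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return A single number (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
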