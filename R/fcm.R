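# Fuzzy c-means clustering of standardised temporal expression profiles.
#
# The soft partition follows the classic Bezdek updates: membership of gene g
# in cluster k is proportional to (1/d^2(g,k))^(1/(m-1)), centers are
# membership^m-weighted means, and the objective sum(u^m d^2) is
# non-increasing across iterations.

#' Fuzzy c-means clustering
#'
#' @param profiles genes x stages numeric matrix, typically z-scored with
#'   [standardize_profiles()].
#' @param c number of clusters (default 4, the reference time-course design).
#' @param m fuzzifier (> 1, default 1.25).
#' @param seed RNG seed for center initialisation.
#' @param max_iter,tol convergence controls: stop when the largest center
#'   coordinate shift drops below `tol`.
#' @param n_init number of random restarts (derived deterministically from
#'   `seed`); the run with the lowest final objective is returned. Restarts
#'   guard against the local optima of the non-convex objective.
#' @return Object of class `angio_fcm`: `membership` (genes x c, rows sum to
#'   1), `centers` (c x stages), `hard_label` (argmax cluster per gene),
#'   `objective` (per-iteration values), `m`, `c`, `iterations`, `converged`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
#' fit <- fuzzy_cmeans(x, c = 2, seed = 1)
#' table(fit$hard_label)
#' @export
fuzzy_cmeans <- function(profiles, c = 4L, m = 1.25, seed = 1L,
                         max_iter = 200L, tol = 1e-8, n_init = 8L) {
  x <- as.matrix(profiles)
  stopifnot(c >= 2, m > 1, nrow(x) >= c, n_init >= 1)
  run <- function(seed_i) fcm_once(x, c, m, seed_i, max_iter, tol)
  final_obj <- function(f) f$objective[f$iterations]
  is_empty <- function(f) any(tabulate(f$hard_label, nbins = c) == 0)
  fits <- lapply(seed + seq_len(n_init) - 1L, run)
  full <- Filter(Negate(is_empty), fits)
  pool <- if (length(full)) full else fits
  fit <- pool[[which.min(vapply(pool, final_obj, numeric(1)))]]
  if (is_empty(fit)) {
    # empty cluster in every restart: re-seed once more, then warn
    fit2 <- run(seed + n_init)
    if (!is_empty(fit2)) return(fit2)
    warn("empty cluster after re-seeding")
  }
  fit
}

fcm_once <- function(x, c, m, seed, max_iter, tol) {
  n <- nrow(x)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  centers <- x[sample.int(n, c), , drop = FALSE]
  obj <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, centers)
    u <- memberships_from_d2(d2, m)
    um <- u^m
    new_centers <- (t(um) %*% x) / colSums(um)
    obj <- c(obj, sum(um * d2))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  rownames(centers) <- paste0("cluster", seq_len(c))
  rownames(u) <- rownames(x)
  structure(list(membership = u, centers = centers,
                 hard_label = max.col(u, ties.method = "first"),
                 objective = obj, m = m, c = c,
                 iterations = length(obj), converged = converged),
            class = "angio_fcm")
}

sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, m) {
  n <- nrow(d2)
  u <- matrix(0, n, ncol(d2))
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
    u[!hit, ] <- w / rowSums(w)
  }
  u
}

#' Label clusters by their peak stage
#'
#' Each cluster is named after the stage at which its center is maximal,
#' matching the convention of calling a cluster "H-0 specific" when its
#' profile peaks at H-0.
#'
#' @param fit an `angio_fcm`.
#' @return Character vector (length `c`): peak stage per cluster.
#' @export
cluster_peak_stage <- function(fit) {
  stages <- colnames(fit$centers)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(fit$centers)))
  stages[max.col(fit$centers, ties.method = "first")]
}

#' @export
print.angio_fcm <- function(x, ...) {
  cat(sprintf("<angio_fcm> %d genes, c = %d, m = %.2f, %d iteration(s)%s\n",
              nrow(x$membership), x$c, x$m, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Tidy a fuzzy c-means fit
#'
#' @param x an `angio_fcm`.
#' @param ... unused.
#' @return Long tibble: `gene`, `cluster`, `membership`, `hard` (is this the
#'   argmax cluster).
#' @method tidy angio_fcm
#' @export
tidy.angio_fcm <- function(x, ...) {
  genes <- rownames(x$membership)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x$membership)))
  out <- as_tibble(x$membership, .name_repair = ~ paste0("cluster", seq_along(.x)))
  out$gene <- genes
  out <- tidyr::pivot_longer(out, -"gene", names_to = "cluster",
                             values_to = "membership")
  out$cluster <- as.integer(sub("cluster", "", out$cluster))
  out$hard <- out$cluster == x$hard_label[match(out$gene, genes)]
  out
}

#' One-row summary of a fuzzy c-means fit
#'
#' @param x an `angio_fcm`.
#' @param ... unused.
#' @return Tibble with `c`, `m`, `iterations`, `converged`, final `objective`
#'   and mean maximal membership (partition crispness).
#' @method glance angio_fcm
#' @export
glance.angio_fcm <- function(x, ...) {
  tibble(c = x$c, m = x$m, iterations = x$iterations,
         converged = x$converged,
         objective = x$objective[length(x$objective)],
         mean_max_membership = mean(apply(x$membership, 1, max)))
}
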