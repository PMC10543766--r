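#' Electrode adjacency from template distances
#'
#' Neighbours are electrode pairs closer than the given quantile of all
#' pairwise distances on the spherical template. The default quantile gives
#' a median neighbour count of about 4-8 on the 23-channel analysis montage
#' and a connected graph.
#'
#' @param layout An `sbc_layout`.
#' @param distance_quantile Quantile of pairwise distances used as the
#'   neighbourhood radius.
#' @return An `sbc_adjacency`: named list, label -> character vector of
#'   neighbour labels (symmetric, no self-loops).
#' @export
build_adjacency <- function(layout, distance_quantile = 0.25) {
  if (nrow(layout) < 2) stop("need at least 2 electrodes")
  pos <- layout_matrix(layout)
  D <- as.matrix(stats::dist(pos))
  thr <- stats::quantile(D[upper.tri(D)], distance_quantile)
  nb <- lapply(seq_len(nrow(D)), function(i) {
    rownames(D)[which(D[i, ] <= thr & seq_len(ncol(D)) != i)]
  })
  names(nb) <- rownames(D)
  if (any(lengths(nb) == 0))
    warning("adjacency threshold leaves isolated electrode(s): ",
            paste(names(nb)[lengths(nb) == 0], collapse = ", "))
  structure(nb, class = "sbc_adjacency")
}

#' Dependent-samples t-map
#'
#' Per-cell paired t-statistics on per-subject differences `a - b` over an
#' electrodes x frequencies grid. Cells with zero difference variance are
#' clamped to `sign * 1e6`.
#'
#' @param a,b Numeric arrays, subjects x channels x bins (a matrix is read
#'   as a single-bin array). Channel dimnames are carried through.
#' @return An `sbc_tmap`: list with `t` (channels x bins) and `df`
#'   (`n_subjects - 1`).
#' @export
paired_tmap <- function(a, b) {
  a <- as_subj_array(a); b <- as_subj_array(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have the same shape")
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  d <- a - b
  dm <- matrix(d, nrow = n)
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), sign(m) * 1e6)
  tm <- matrix(t, dim(a)[2], dim(a)[3],
               dimnames = list(dimnames(a)[[2]], NULL))
  structure(list(t = tm, df = n - 1), class = "sbc_tmap")
}

as_subj_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L),
                               dimnames = c(dimnames(x), list(NULL)))
  if (length(dim(x)) != 3) stop("expected subjects x channels x bins")
  x
}

# neighbour index list over the cell grid (channels x bins)
cell_neighbours <- function(labels, n_bins, adj, freq_adjacent) {
  nch <- length(labels)
  adj_idx <- lapply(labels, function(l) match(adj[[l]], labels))
  adj_idx <- lapply(adj_idx, function(v) v[!is.na(v)])
  function(cell) {
    ch <- (cell - 1L) %% nch + 1L
    b <- (cell - 1L) %/% nch + 1L
    nb <- adj_idx[[ch]] + (b - 1L) * nch
    if (freq_adjacent) {
      if (b > 1L) nb <- c(nb, ch + (b - 2L) * nch)
      if (b < n_bins) nb <- c(nb, ch + b * nch)
    }
    nb
  }
}

#' Find supra-threshold clusters in a t-map
#'
#' Cells with `|t|` above the two-tailed critical value at
#' `threshold_alpha` are joined into connected components of equal sign;
#' connectivity is spatial neighbourhood at the same frequency bin plus
#' (optionally) the same electrode at adjacent bins. The cluster statistic
#' is the sum of member t-values ("mass").
#'
#' @param tmap An `sbc_tmap`.
#' @param adj An `sbc_adjacency` covering the map's channels.
#' @param threshold_alpha Cluster-forming alpha (two-tailed).
#' @param freq_adjacent Join adjacent frequency bins of one electrode.
#' @return List of clusters: each a list with `members` (data frame
#'   `channel`, `bin`), `mass` and `sign`. Empty list if no cell is
#'   supra-threshold.
#' @export
find_clusters <- function(tmap, adj, threshold_alpha = 0.05,
                          freq_adjacent = TRUE) {
  stopifnot(threshold_alpha > 0, threshold_alpha < 1)
  t <- tmap$t
  tcrit <- stats::qt(1 - threshold_alpha / 2, tmap$df)
  nch <- nrow(t); nb_fun <- cell_neighbours(rownames(t), ncol(t), adj,
                                            freq_adjacent)
  supra <- which(abs(t) > tcrit)
  if (length(supra) == 0) return(list())
  lab <- integer(length(t))
  lab[supra] <- -1L  # unvisited supra-threshold
  clusters <- list()
  cid <- 0L
  for (s in supra) {
    if (lab[s] != -1L) next
    cid <- cid + 1L
    sgn <- sign(t[s])
    stack <- s
    members <- integer(0)
    lab[s] <- cid
    while (length(stack) > 0) {
      cell <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, cell)
      for (nb in nb_fun(cell)) {
        if (lab[nb] == -1L && sign(t[nb]) == sgn) {
          lab[nb] <- cid
          stack <- c(stack, nb)
        }
      }
    }
    clusters[[cid]] <- list(
      members = data.frame(
        channel = rownames(t)[(members - 1L) %% nch + 1L],
        bin = (members - 1L) %/% nch + 1L),
      mass = sum(t[members]),
      sign = sgn)
  }
  clusters
}

# max |cluster mass| of a t matrix (internal, for the permutation null)
max_cluster_mass <- function(t, df, adj, threshold_alpha, freq_adjacent) {
  cl <- find_clusters(structure(list(t = t, df = df), class = "sbc_tmap"),
                      adj, threshold_alpha, freq_adjacent)
  if (length(cl) == 0) return(0)
  max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

#' Cluster-based permutation test for a paired design
#'
#' Builds the observed t-map and clusters from per-subject condition arrays
#' `a` and `b`, then forms the null distribution by randomly exchanging
#' `a`/`b` within subjects (sign-flips of the differences), rebuilding the
#' t-map, and recording the maximum absolute cluster mass of each
#' permutation. Each observed cluster gets the Monte-Carlo p-value
#' `(count of permutation maxima >= |mass| + 1) / (n_perm + 1)`; since the
#' null spans both signs through the absolute mass, this correction is
#' two-sided as it stands. If the smallest p falls in `[0.03, 0.10]`, the
#' test is rerun with `escalate_to` permutations.
#'
#' @param a,b Subjects x channels (x bins) arrays.
#' @param adj An `sbc_adjacency`.
#' @param n_perm Permutations (default 1000).
#' @param escalate_to Permutations used on escalation (default 10000; set
#'   equal to `n_perm` to disable).
#' @param seed Optional seed.
#' @param threshold_alpha Cluster-forming alpha.
#' @param freq_adjacent Join adjacent bins of one electrode.
#' @return An `sbc_clustertest`: list with `clusters` (members, mass, sign,
#'   `p`), `tmap`, `n_perm` (actually used), `threshold_alpha`, `seed`,
#'   `max_null` (permutation maxima).
#' @export
permutation_test <- function(a, b, adj, n_perm = 1000,
                             escalate_to = 10000, seed = NULL,
                             threshold_alpha = 0.05, freq_adjacent = TRUE) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value resolution")
  a <- as_subj_array(a); b <- as_subj_array(b)
  if (!is.null(seed)) set.seed(seed)
  tmap <- paired_tmap(a, b)
  clusters <- find_clusters(tmap, adj, threshold_alpha, freq_adjacent)

  run_null <- function(np) {
    n <- dim(a)[1]
    d <- matrix(a - b, nrow = n)
    ssq <- colSums(d^2)
    vapply(seq_len(np), function(p) {
      f <- sample(c(-1, 1), n, replace = TRUE)
      m <- as.numeric(crossprod(f, d)) / n
      v <- (ssq - n * m^2) / (n - 1)
      t <- ifelse(v > 0, m / sqrt(v / n), sign(m) * 1e6)
      tm <- matrix(t, dim(a)[2], dim(a)[3],
                   dimnames = list(dimnames(a)[[2]], NULL))
      max_cluster_mass(tm, n - 1, adj, threshold_alpha, freq_adjacent)
    }, numeric(1))
  }

  finish <- function(np) {
    max_null <- run_null(np)
    for (i in seq_along(clusters)) {
      clusters[[i]]$p <-
        (sum(max_null >= abs(clusters[[i]]$mass)) + 1) / (np + 1)
    }
    list(clusters = clusters, max_null = max_null, n_perm = np)
  }

  res <- if (length(clusters) > 0) finish(n_perm)
         else list(clusters = clusters, max_null = numeric(0), n_perm = n_perm)
  if (length(res$clusters) > 0 && escalate_to > n_perm) {
    pmin_obs <- min(vapply(res$clusters, `[[`, numeric(1), "p"))
    if (pmin_obs >= 0.03 && pmin_obs <= 0.10)
      res <- finish(escalate_to)
  }
  structure(list(clusters = res$clusters, tmap = tmap,
                 n_perm = res$n_perm, threshold_alpha = threshold_alpha,
                 seed = seed, max_null = res$max_null),
            class = "sbc_clustertest")
}

#' Smallest cluster p-value of a test (1 if no clusters)
#'
#' @param x An `sbc_clustertest`.
#' @param sign Optional sign filter (+1 / -1).
#' @return Numeric p-value.
#' @export
min_cluster_p <- function(x, sign = NULL) {
  cl <- x$clusters
  if (!is.null(sign)) cl <- Filter(function(c) c$sign == sign, cl)
  if (length(cl) == 0) return(1)
  min(vapply(cl, `[[`, numeric(1), "p"))
}

#' @export
print.sbc_clustertest <- function(x, ...) {
  cat(sprintf("<sbc_clustertest> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  sign %+d  mass %8.2f  cells %3d  p = %.4g\n",
                cl$sign, cl$mass, nrow(cl$members), cl$p))
  invisible(x)
}
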