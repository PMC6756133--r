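# The statistical battery: SNR binning, dependent-correlation comparison,
# per-SNR paired sign-flip permutation tests with Holm adjustment,
# Brown-Forsythe variance homogeneity, and channel x lag cluster-based
# permutation testing.

#' Cluster SNR values with 1-D k-means
#'
#' @param snr_values numeric SNRs in dB.
#' @param k number of clusters (default 7); must not exceed the number of
#'   distinct values.
#' @param seed integer seed for the k-means initialisation.
#' @return list with integer `labels` (cluster index per value, clusters
#'   ordered by ascending center) and sorted `centers`.
#' @export
bin_snrs <- function(snr_values, k = 7L, seed = 1L) {
  distinct <- unique(snr_values)
  if (k > length(distinct))
    stop_invalid("`k` exceeds the number of distinct SNR values")
  if (k == length(distinct)) {
    centers <- sort(distinct)
    return(list(labels = match(snr_values, centers), centers = centers))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  km <- kmeans(snr_values, centers = k, nstart = 25L, iter.max = 100L)
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[km$cluster], centers = as.numeric(km$centers[ord]))
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether two correlations sharing one variable (e.g. SNR versus
#' tracking in two conditions measured on the same units) differ, using the
#' back-transformed-average modification of Dunn and Clark's z
#' (Hittner-style): the covariance term is evaluated at the inverse-Fisher
#' mean of the two correlations.
#'
#' @param r_a,r_b the two correlations to compare (each sharing a variable).
#' @param r_ab correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @return list with `statistic` (z) and `p.value` (two-sided).
#' @export
compare_dependent_correlations <- function(r_a, r_b, r_ab, n) {
  for (r in c(r_a, r_b, r_ab))
    if (!is.finite(r) || abs(r) >= 1)
      stop_invalid("correlations must lie strictly inside (-1, 1)")
  if (n < 4) stop_invalid("`n` must be at least 4")
  z1 <- atanh(r_a)
  z2 <- atanh(r_b)
  rm <- tanh((z1 + z2) / 2)
  cov_num <- r_ab * (1 - 2 * rm^2) - 0.5 * rm^2 * (1 - 2 * rm^2 - r_ab^2)
  c12 <- cov_num / (1 - rm^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - c12)))
  list(statistic = z, p.value = 2 * pnorm(-abs(z)))
}

#' Paired sign-flip permutation tests per SNR bin, Holm adjusted
#'
#' For each bin the statistic is the mean paired difference; its null
#' distribution is generated by randomly flipping the sign of each
#' subject's difference (exhaustively when `2^n_subjects <= n_perm`).
#' Holm-Bonferroni adjustment is applied across bins.
#'
#' @param x,y subjects x bins matrices of paired values (same dimensions,
#'   same subject order).
#' @param n_perm permutations per bin (default 5000, minimum 1000).
#' @param seed integer seed.
#' @param statistic `"mean"` (default) or `"t"`.
#' @return list with `p_raw`, `p_adjusted` (Holm), `observed` mean
#'   differences, and `exact` flag.
#' @export
paired_permutation_by_snr <- function(x, y, n_perm = 5000L, seed = 1L,
                                      statistic = c("mean", "t")) {
  statistic <- match.arg(statistic)
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop_invalid("`x` and `y` must be paired (same dimensions)")
  if (n_perm < 1000L) stop_invalid("`n_perm` must be at least 1000")
  d <- x - y
  n <- nrow(d); nb <- ncol(d)
  exact <- n <= 20L && 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  stat_fun <- function(dd, S) {
    m <- (S %*% dd) / n
    if (statistic == "mean") return(drop(m))
    ss <- sum(dd^2)
    v <- (ss - n * m^2) / (n - 1)
    drop(m / sqrt(v / n))
  }
  p_raw <- vapply(seq_len(nb), function(j) {
    obs <- stat_fun(d[, j], matrix(1, 1, n))
    null <- stat_fun(d[, j], signs)
    if (exact) mean(abs(null) >= abs(obs) - 1e-12)
    else (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (nrow(signs) + 1)
  }, 0)
  list(p_raw = p_raw, p_adjusted = p.adjust(p_raw, method = "holm"),
       observed = colMeans(d), exact = exact)
}

#' Brown-Forsythe test for homogeneity of spread
#'
#' Levene-type one-way F test on absolute deviations from the group
#' medians.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return list with `statistic` (F), `df`, and `p.value`.
#' @export
brown_forsythe <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_invalid("`groups` must be a list of at least two groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop_invalid("each group needs at least two values")
  z <- lapply(groups, function(g) abs(g - median(g)))
  ni <- vapply(z, length, 0L)
  k <- length(z)
  N <- sum(ni)
  zi <- vapply(z, mean, 0)
  zbar <- sum(ni * zi) / N
  ssb <- sum(ni * (zi - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), 0))
  df <- c(k - 1L, N - k)
  if (ssw < .Machine$double.eps && ssb < .Machine$double.eps) {
    return(list(statistic = 0, df = df, p.value = 1))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(statistic = f, df = df, p.value = pf(f, df[1], df[2],
                                            lower.tail = FALSE))
}

# ---- cluster-based permutation over channels x lags -------------------------

# Neighbour index list for a channels x lags grid: adjacency across
# channels at the same lag, plus lag contiguity within a channel.
grid_neighbours <- function(labels, n_lags, adjacency) {
  C <- length(labels)
  idx <- function(ch, lg) (lg - 1L) * C + ch
  nb <- vector("list", C * n_lags)
  adj_idx <- lapply(labels, function(l) {
    if (is.null(adjacency)) integer(0) else
      match(intersect(adjacency[[l]], labels), labels)
  })
  for (lg in seq_len(n_lags)) {
    for (ch in seq_len(C)) {
      v <- integer(0)
      if (lg > 1L) v <- c(v, idx(ch, lg - 1L))
      if (lg < n_lags) v <- c(v, idx(ch, lg + 1L))
      v <- c(v, idx(adj_idx[[ch]], lg))
      nb[[idx(ch, lg)]] <- v
    }
  }
  nb
}

# Connected components among `cells` (integer indices) under neighbour list
# nb; returns a list of integer vectors.
connected_components <- function(cells, nb, n_total) {
  inset <- logical(n_total)
  inset[cells] <- TRUE
  seen <- logical(n_total)
  comps <- list()
  for (c0 in cells) {
    if (seen[c0]) next
    comp <- integer(0)
    stack <- c0
    seen[c0] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in nb[[v]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

max_cluster_mass <- function(tvec, crit, nb) {
  m <- 0
  pos <- which(tvec > crit)
  if (length(pos)) {
    for (comp in connected_components(pos, nb, length(tvec)))
      m <- max(m, sum(tvec[comp]))
  }
  neg <- which(tvec < -crit)
  if (length(neg)) {
    for (comp in connected_components(neg, nb, length(tvec)))
      m <- max(m, -sum(tvec[comp]))
  }
  m
}

#' Cluster-based permutation test on paired TRF sets
#'
#' Paired t values are computed per (channel, lag) cell from the per-subject
#' kernel differences; cells exceeding the two-sided critical t at
#' `cluster_alpha` are clustered under channel adjacency and lag contiguity
#' (positive and negative cells separately); each cluster's mass is the sum
#' of its t values, and the familywise-corrected p value is the proportion
#' of sign-flip permutations whose maximal cluster mass is at least as
#' large.
#'
#' @param trf_a,trf_b lists of [train_forward()] TRFs (one per subject,
#'   paired), or 3-D arrays `subjects x channels x lags`.
#' @param adjacency channel adjacency as from [channel_adjacency()]; `NULL`
#'   degenerates to lag-contiguity clustering within each channel.
#' @param cluster_alpha cluster-forming alpha (two-sided, default 0.05).
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param seed integer seed.
#' @param labels,lag_ms channel labels and lag axis; taken from the TRFs
#'   when lists are supplied.
#' @return object of class `cluster_result`: data.frame of clusters
#'   (channels, lag interval, mass, p) plus the observed t map.
#' @export
cluster_permutation <- function(trf_a, trf_b, adjacency = NULL,
                                cluster_alpha = 0.05, n_perm = 5000L,
                                seed = 1L, labels = NULL, lag_ms = NULL) {
  if (is.list(trf_a) && inherits(trf_a[[1]], "forward_trf")) {
    labels <- rownames(trf_a[[1]]$kernel)
    lag_ms <- trf_a[[1]]$lag_ms
    to_arr <- function(l) aperm(simplify2array(lapply(l, `[[`, "kernel")),
                                c(3L, 1L, 2L))
    trf_a <- to_arr(trf_a)
    trf_b <- to_arr(trf_b)
  }
  if (!all(dim(trf_a) == dim(trf_b)))
    stop_invalid("TRF sets must be paired with identical dimensions")
  n <- dim(trf_a)[1]; C <- dim(trf_a)[2]; L <- dim(trf_a)[3]
  if (n < 5L) stop_invalid("fewer than 5 subjects: permutation resolution too coarse")
  if (is.null(labels)) labels <- paste0("Ch", seq_len(C))
  if (is.null(lag_ms)) lag_ms <- seq_len(L)
  D <- matrix(trf_a - trf_b, nrow = n) # subjects x (C*L), channel fastest
  crit <- qt(1 - cluster_alpha / 2, df = n - 1)
  nb <- grid_neighbours(labels, L, adjacency)
  ss <- colSums(D^2)
  tstat_rows <- function(S) {
    m <- (S %*% D) / n
    v <- sweep(-n * m^2, 2L, ss, `+`) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  t_obs <- drop(tstat_rows(matrix(1, 1, n)))
  # observed clusters
  find_signed <- function(cells, sign) {
    comps <- connected_components(cells, nb, length(t_obs))
    lapply(comps, function(comp) {
      ch <- ((comp - 1L) %% C) + 1L
      lg <- ((comp - 1L) %/% C) + 1L
      data.frame(channels = I(list(unique(labels[ch]))),
                 lag_low_ms = min(lag_ms[lg]), lag_high_ms = max(lag_ms[lg]),
                 mass = sum(t_obs[comp]), n_cells = length(comp),
                 sign = sign)
    })
  }
  clus <- c(find_signed(which(t_obs > crit), 1L),
            find_signed(which(t_obs < -crit), -1L))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  exact <- n <= 16L && 2^n <= n_perm
  S <- if (exact) as.matrix(expand.grid(rep(list(c(-1, 1)), n))) else
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Tn <- tstat_rows(S)
  null_max <- vapply(seq_len(nrow(S)), function(i)
    max_cluster_mass(Tn[i, ], crit, nb), 0)
  out <- if (length(clus)) do.call(rbind, clus) else
    data.frame(channels = I(list()), lag_low_ms = numeric(0),
               lag_high_ms = numeric(0), mass = numeric(0),
               n_cells = integer(0), sign = integer(0))
  out$p <- vapply(out$mass, function(m) {
    if (exact) mean(null_max >= abs(m) - 1e-12)
    else (1 + sum(null_max >= abs(m) - 1e-12)) / (nrow(S) + 1)
  }, 0)
  structure(list(clusters = out[order(out$p, -abs(out$mass)), ],
                 t_map = matrix(t_obs, C, L, dimnames = list(labels, NULL)),
                 crit = crit, lag_ms = lag_ms, alpha_level = cluster_alpha,
                 n_perm = nrow(S), exact = exact),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster permutation: %d cluster(s), |t| > %.2f, %d permutations\n",
              nrow(x$clusters), x$crit, x$n_perm))
  if (nrow(x$clusters)) {
    df <- head(x$clusters, 8L)
    df$channels <- vapply(df$channels, function(ch)
      paste(head(ch, 5), collapse = ","), "")
    print(df, row.names = FALSE)
    if (nrow(x$clusters) > 8L)
      cat(sprintf("  ... and %d smaller cluster(s)\n",
                  nrow(x$clusters) - 8L))
  }
  invisible(x)
}
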