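#' Differential donation vector between two donor groups
#'
#' For each recipient r, `d_r = c_{r,X} - c_{r,ref}`: the expected chunk
#' count donated by donor group X minus that donated by a reference donor
#' group. Contrasting a distal against a proximal hunter-gatherer donor in
#' this way localizes which forager lineage contributed to each later
#' individual.
#'
#' @param cm a `coancestry_matrix`.
#' @param donor_x,donor_ref donor population names (aggregated over their
#'   member individuals).
#' @param what `"chunks"` (default) or `"lengths_cM"`.
#' @param exclude_donor_recipients drop recipients belonging to either
#'   donor population from the result.
#' @return named numeric vector `d_r` over recipients.
#' @export
donation_differential <- function(cm, donor_x, donor_ref,
                                  what = c("chunks", "lengths_cM"),
                                  exclude_donor_recipients = TRUE) {
  what <- match.arg(what)
  bypop <- donation_by_population(cm, what)
  for (p in c(donor_x, donor_ref))
    if (!p %in% colnames(bypop)) stop("unknown donor population: ", p)
  d <- bypop[, donor_x] - bypop[, donor_ref]
  names(d) <- rownames(bypop)
  if (exclude_donor_recipients) {
    keep <- !cm$recipient_info$population %in% c(donor_x, donor_ref)
    d <- d[keep]
  }
  d
}

#' Mann-Whitney contrast of donation differentials between recipient groups
#'
#' Two-sided Mann-Whitney U test of `d` values between two recipient
#' groups: exact enumeration when the combined sample size is at most 20
#' (and there are no ties), the tie-corrected normal approximation
#' otherwise.
#'
#' @param d named vector of per-recipient values (e.g. from
#'   [donation_differential()]).
#' @param group_a,group_b character vectors of recipient ids.
#' @return list with `U`, `p_value`, `median_a`, `median_b`, `exact`.
#' @export
donation_contrast_test <- function(d, group_a, group_b) {
  xa <- d[group_a]; xb <- d[group_b]
  if (any(is.na(xa)) || any(is.na(xb))) stop("missing recipients in d")
  n <- length(xa) + length(xb)
  exact <- n <= 20 && !any(duplicated(c(xa, xb)))
  wt <- suppressWarnings(
    wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_a = median(xa), median_b = median(xb), exact = exact)
}

#' Total variation distance between group donation vectors
#'
#' For each recipient group, takes the per-target-population median
#' donation across group members, normalizes the median vector to sum 1,
#' and returns `TVD = 0.5 * sum |p1_t - p2_t|` together with the per-target
#' signed raw (unnormalized) differences.
#'
#' @param cm a `coancestry_matrix`.
#' @param group1,group2 character vectors of recipient ids.
#' @param targets donor population names to compare over (default: all).
#' @param what `"chunks"` or `"lengths_cM"`.
#' @return list with `tvd`, `median1`, `median2` (normalized vectors) and
#'   `raw_difference` (unnormalized per-target medians differenced).
#' @export
tvd_donation <- function(cm, group1, group2, targets = NULL,
                         what = c("chunks", "lengths_cM")) {
  what <- match.arg(what)
  if (!length(group1) || !length(group2)) stop("groups must be non-empty")
  bypop <- donation_by_population(cm, what)
  if (is.null(targets)) targets <- colnames(bypop)
  if (!all(targets %in% colnames(bypop)))
    stop("unknown target populations: ",
         paste(setdiff(targets, colnames(bypop)), collapse = ", "))
  med <- function(g) apply(bypop[g, targets, drop = FALSE], 2, median)
  m1 <- med(group1); m2 <- med(group2)
  p1 <- m1 / sum(m1); p2 <- m2 / sum(m2)
  list(tvd = 0.5 * sum(abs(p1 - p2)), median1 = p1, median2 = p2,
       raw_difference = m1 - m2)
}

#' PCA of a coancestry matrix
#'
#' Column-centres the recipients x donors chunk-count matrix and takes the
#' singular value decomposition. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' deterministic.
#'
#' @param cm a `coancestry_matrix`.
#' @param n_components number of leading components returned.
#' @return list with `scores` (recipients x components), `loadings`,
#'   `explained_variance` (per component) and `total_variance`.
#' @export
coancestry_pca <- function(cm, n_components = 5L) {
  X <- scale(cm$chunks, center = TRUE, scale = FALSE)
  sv <- svd(X)
  k <- min(n_components, length(sv$d))
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(cm$chunks)
  rownames(loadings) <- colnames(cm$chunks)
  ev <- sv$d^2 / (nrow(X) - 1)
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)], total_variance = sum(ev))
}

# Dirichlet-multinomial marginal log-likelihood of a (possibly real-valued)
# chunk-count vector under a symmetric Dirichlet(concentration) prior.
dirichlet_multinomial_logml <- function(counts, concentration) {
  D <- length(counts)
  N <- sum(counts)
  lgamma(D * concentration) - lgamma(D * concentration + N) +
    sum(lgamma(concentration + counts) - lgamma(concentration))
}

#' Greedy marginal-likelihood clustering of recipients
#'
#' A deterministic agglomerative stand-in for MCMC coancestry clustering:
#' starting from singleton clusters, repeatedly merges the pair of clusters
#' whose pooled donation counts most increase the multinomial-Dirichlet
#' marginal log-likelihood (shared versus separate cluster parameters),
#' stopping when no merge improves it. Ties break on the smallest index
#' pair.
#'
#' @param cm a `coancestry_matrix`.
#' @param concentration symmetric Dirichlet concentration of the donation
#'   profile prior.
#' @return list with `partition` (named integer cluster assignment),
#'   `n_clusters` and `merges` (data frame of accepted merges with their
#'   log-marginal-likelihood gains).
#' @export
greedy_cluster <- function(cm, concentration = 1) {
  X <- cm$chunks
  n <- nrow(X)
  members <- as.list(seq_len(n))
  counts <- lapply(seq_len(n), function(i) X[i, ])
  logml <- vapply(counts, dirichlet_multinomial_logml, numeric(1),
                  concentration = concentration)
  merges <- list()
  repeat {
    k <- length(members)
    if (k < 2) break
    best <- c(NA, NA); best_delta <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      delta <- dirichlet_multinomial_logml(counts[[i]] + counts[[j]],
                                           concentration) -
        logml[i] - logml[j]
      if (delta > best_delta + 1e-12) { best <- c(i, j); best_delta <- delta }
    }
    if (is.na(best[1])) break
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- data.frame(
      cluster_a = paste(rownames(X)[members[[i]]], collapse = "+"),
      cluster_b = paste(rownames(X)[members[[j]]], collapse = "+"),
      delta_logml = best_delta)
    members[[i]] <- c(members[[i]], members[[j]])
    counts[[i]] <- counts[[i]] + counts[[j]]
    logml[i] <- dirichlet_multinomial_logml(counts[[i]], concentration)
    members[[j]] <- NULL
    counts[[j]] <- NULL
    logml <- logml[-j]
  }
  partition <- integer(n)
  for (c_id in seq_along(members)) partition[members[[c_id]]] <- c_id
  names(partition) <- rownames(X)
  list(partition = partition, n_clusters = length(members),
       merges = if (length(merges)) do.call(rbind, merges) else NULL)
}
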