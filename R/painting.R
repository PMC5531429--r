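#' Parameters of the Li-Stephens copying model
#'
#' @param rho switch-rate scale per cM (> 0). Default `NULL`: chosen at
#'   painting time as `K / 100` for K donor haplotypes, i.e. an expected
#'   one switch per cM per 100 donors.
#' @param theta mismatch (emission error) probability in (0, 0.5). Default
#'   `NULL`: a Watterson-style `1 / sum(1/k, k = 1..K)`, clamped to
#'   `[1e-4, 0.49]`.
#' @return a `painting_params` list.
#' @export
painting_params <- function(rho = NULL, theta = NULL) {
  if (!is.null(rho) && rho <= 0) stop("rho must be > 0")
  if (!is.null(theta) && (theta <= 0 || theta >= 0.5))
    stop("theta must lie in (0, 0.5)")
  structure(list(rho = rho, theta = theta), class = "painting_params")
}

resolve_params <- function(params, K) {
  rho <- if (is.null(params$rho)) K / 100 else params$rho
  theta <- if (is.null(params$theta))
    min(max(1 / sum(1 / seq_len(K)), 1e-4), 0.49) else params$theta
  list(rho = rho, theta = theta)
}

#' Paint one haplotype against a donor set (Li-Stephens HMM)
#'
#' Hidden Markov copying model over K donor haplotypes: across an interval
#' of g cM the chain keeps its donor with probability `exp(-rho * g)` and
#' otherwise switches to a donor drawn uniformly (1/K, self-return
#' included); the emission matches the donor allele with probability
#' `1 - theta`. Scaled forward-backward recursions give, per donor, the
#' expected copied map length (posterior mass times the site's map
#' interval) and the expected chunk count (posterior switch-in events plus
#' the first site's donor posterior). Expected lengths over donors sum to
#' the total map length exactly.
#'
#' @param recipient 0/1 vector of recipient alleles (one haplotype).
#' @param donors 0/1 matrix of donor haplotypes (rows) x sites (columns);
#'   the recipient must not be among the donors.
#' @param gpos_cM genetic positions of the sites (cM, increasing).
#' @param total_cM total map length (defaults to the spanned range; pass
#'   the chromosome length so edge sites carry their full flanking
#'   interval).
#' @param params a [painting_params()].
#' @return list with per-donor `chunks` and `lengths_cM` (named by donor
#'   row names) and the model `loglik`.
#' @export
ls_paint <- function(recipient, donors, gpos_cM,
                     total_cM = NULL, params = painting_params()) {
  if (is.null(dim(donors))) donors <- matrix(donors, nrow = 1)
  K <- nrow(donors)
  S <- length(recipient)
  if (K < 1) stop("at least one donor haplotype is required")
  stopifnot(ncol(donors) == S, length(gpos_cM) == S)
  pr <- resolve_params(params, K)
  rho <- pr$rho; theta <- pr$theta

  # emission: K x S
  em <- matrix(theta, K, S)
  em[donors == matrix(recipient, K, S, byrow = TRUE)] <- 1 - theta
  gaps <- diff(gpos_cM)
  r <- 1 - exp(-rho * gaps)              # switch probability per interval

  # site map weights: midpoints between sites, extended to [0, total_cM]
  if (is.null(total_cM)) total_cM <- max(gpos_cM)
  mids <- c(0, (gpos_cM[-1] + gpos_cM[-S]) / 2, total_cM)
  w <- diff(mids)

  # scaled forward
  A <- matrix(0, K, S)                   # normalized filtering probs
  cvec <- numeric(S)
  a <- em[, 1] / K
  cvec[1] <- sum(a)
  A[, 1] <- a / cvec[1]
  if (S > 1) for (s in 2:S) {
    pred <- (1 - r[s - 1]) * A[, s - 1] + r[s - 1] / K
    a <- pred * em[, s]
    cvec[s] <- sum(a)
    if (!is.finite(cvec[s]) || cvec[s] <= 0)
      stop("non-finite likelihood at site ", s)
    A[, s] <- a / cvec[s]
  }

  # scaled backward, accumulating posteriors and switch-in expectations
  b <- rep(1, K)
  lengths <- numeric(K)
  chunks <- numeric(K)
  gamma_s <- A[, S] * b
  lengths <- lengths + gamma_s * w[S]
  if (S > 1) for (s in (S - 1):1) {
    term <- em[, s + 1] * b
    # expected switch-in at interval (s, s+1): recombination lands on donor j
    # coming from a different donor (self-return does not open a new chunk)
    chunks <- chunks + (1 - A[, s]) * (r[s] / K) * term / cvec[s + 1]
    b <- ((1 - r[s]) * term + (r[s] / K) * sum(term)) / cvec[s + 1]
    gamma_s <- A[, s] * b
    lengths <- lengths + gamma_s * w[s]
  }
  chunks <- chunks + gamma_s               # first site's donor
  nm <- rownames(donors)
  if (!is.null(nm)) { names(chunks) <- nm; names(lengths) <- nm }
  list(chunks = chunks, lengths_cM = lengths, loglik = sum(log(cvec)))
}

#' Coancestry matrix by all-vs-all painting
#'
#' Paints both haplotypes of every recipient individual against the
#' haplotypes of all other individuals (leave-self-out: both of the
#' recipient's haplotypes are excluded from its donor set), aggregates
#' donor haplotypes to donor individuals and sums over the recipient's two
#' haplotypes. Row sums of expected copied length equal
#' `2 * total map length` per recipient.
#'
#' @param panel a `haplotype_panel`.
#' @param params a [painting_params()].
#' @param recipients recipient individuals (default: all).
#' @param donors donor individuals (default: all); a recipient appearing in
#'   the donor pool is excluded from its own donor set.
#' @param site_subset optional integer site indices to paint on (thinning).
#' @return a `coancestry_matrix`: list with matrices `chunks` and
#'   `lengths_cM` (recipients x donor individuals), `recipient_info`,
#'   `donor_info` and `total_cM`.
#' @export
paint_all <- function(panel, params = painting_params(),
                      recipients = NULL, donors = NULL, site_subset = NULL) {
  info <- panel$hap_info
  all_ind <- unique(info$individual)
  if (is.null(recipients)) recipients <- all_ind
  if (is.null(donors)) donors <- all_ind
  if (length(unique(c(recipients, donors))) < 3L)
    stop("painting needs at least 3 individuals")
  sel <- if (is.null(site_subset)) seq_len(nrow(panel$sites)) else site_subset
  gpos <- panel$sites$genetic_pos_cM[sel]
  total_cM <- panel$chrom_length_morgans * 100
  H <- panel$haps[, sel, drop = FALSE]

  donor_rows <- which(info$individual %in% donors)
  donor_ind <- info$individual[donor_rows]
  chunks <- matrix(0, length(recipients), length(donors),
                   dimnames = list(recipients, donors))
  lengths <- chunks
  for (i in seq_along(recipients)) {
    rec <- recipients[i]
    dr <- donor_rows[donor_ind != rec]
    if (!length(dr)) stop("recipient ", rec, " has an empty donor set")
    dmat <- H[dr, , drop = FALSE]
    agg <- factor(info$individual[dr], levels = donors)
    for (hr in which(info$individual == rec)) {
      res <- ls_paint(H[hr, ], dmat, gpos, total_cM, params)
      chunks[i, ] <- chunks[i, ] +
        as.numeric(tapply(res$chunks, agg, sum, default = 0))
      lengths[i, ] <- lengths[i, ] +
        as.numeric(tapply(res$lengths_cM, agg, sum, default = 0))
    }
  }
  pop_of <- info$population[match(c(recipients, donors), info$individual)]
  structure(list(
    chunks = chunks, lengths_cM = lengths,
    recipient_info = data.frame(individual = recipients,
                                population = pop_of[seq_along(recipients)],
                                stringsAsFactors = FALSE),
    donor_info = data.frame(individual = donors,
                            population = pop_of[-seq_along(recipients)],
                            stringsAsFactors = FALSE),
    total_cM = total_cM
  ), class = "coancestry_matrix")
}

#' Aggregate coancestry columns by donor population
#'
#' @param cm a `coancestry_matrix`.
#' @param what `"chunks"` or `"lengths_cM"`.
#' @return matrix recipients x donor populations.
#' @export
donation_by_population <- function(cm, what = c("chunks", "lengths_cM")) {
  what <- match.arg(what)
  m <- cm[[what]]
  pops <- unique(cm$donor_info$population)
  out <- sapply(pops, function(p) {
    cols <- which(cm$donor_info$population == p)
    rowSums(m[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(m), pops))
  out
}
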