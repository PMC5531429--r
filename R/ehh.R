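#' Extended haplotype homozygosity at a target site
#'
#' Among the carriers of `core_allele` at the core site, haplotypes are
#' partitioned by identity over the closed site interval between core and
#' target; `EHH = sum_h C(n_h, 2) / C(n_c, 2)`, the probability that two
#' randomly chosen carrier chromosomes are homozygous over that stretch.
#' No carrier-frequency floor is applied (low-frequency cores are allowed,
#' as with a keep-low-frequency scan).
#'
#' @param haps 0/1 haplotype matrix (haplotypes x sites), no missing data.
#' @param core_idx core site column.
#' @param core_allele 0 or 1.
#' @param target_idx target site column.
#' @return EHH value in `[0, 1]`; `NA` with a warning when fewer than two
#'   carriers exist.
#' @export
ehh_at <- function(haps, core_idx, core_allele, target_idx) {
  carriers <- which(haps[, core_idx] == core_allele)
  n_c <- length(carriers)
  if (n_c < 2) {
    warning("fewer than 2 carriers of the core allele; EHH undefined")
    return(NA_real_)
  }
  rng <- min(core_idx, target_idx):max(core_idx, target_idx)
  key <- apply(haps[carriers, rng, drop = FALSE], 1, paste, collapse = "")
  nh <- table(key)
  sum(choose(nh, 2)) / choose(n_c, 2)
}

#' EHH decay curves around a core site
#'
#' Computes EHH for both core alleles at every site within `max_dist` bp of
#' the core, in both directions. EHH is 1 at the core and non-increasing
#' moving away from it (identity partitions only refine).
#'
#' @param haps 0/1 haplotype matrix.
#' @param sites site table with `position_bp`.
#' @param core_idx core site column.
#' @param max_dist window half-width in bp; default 5 Mb.
#' @return list with one data frame per core allele (`derived` = allele 1,
#'   `ancestral` = allele 0), columns `site`, `position_bp`, `distance_bp`,
#'   `ehh`; and the carrier counts `n_carriers`.
#' @export
ehh_decay <- function(haps, sites, core_idx, max_dist = 5e6) {
  pos <- sites$position_bp
  win <- which(abs(pos - pos[core_idx]) <= max_dist)
  curve_for <- function(allele) {
    n_c <- sum(haps[, core_idx] == allele)
    if (n_c < 2) return(NULL)
    # incremental partition refinement outward in each direction
    ehh <- rep(NA_real_, length(win))
    for (dir in c(-1, 1)) {
      idx <- win[if (dir < 0) win <= core_idx else win >= core_idx]
      idx <- idx[order(abs(idx - core_idx))]
      carriers <- which(haps[, core_idx] == allele)
      grp <- rep(1L, length(carriers))
      denom <- choose(n_c, 2)
      for (t in idx) {
        grp <- as.integer(interaction(grp, haps[carriers, t], drop = TRUE))
        ehh[match(t, win)] <- sum(choose(table(grp), 2)) / denom
      }
    }
    data.frame(site = win, position_bp = pos[win],
               distance_bp = pos[win] - pos[core_idx], ehh = ehh)
  }
  list(derived = curve_for(1L), ancestral = curve_for(0L),
       n_carriers = c(derived = sum(haps[, core_idx] == 1L),
                      ancestral = sum(haps[, core_idx] == 0L)))
}

#' Haplotype furcation structure from a core site
#'
#' Walks outward from the core, splitting the carriers of the core allele
#' at each successive site. Nodes that reach a single carrier are pruned
#' from the rendered structure (unique haplotypes are not drawn) but remain
#' in the per-depth counts, which always sum to the carrier count.
#'
#' @param haps 0/1 haplotype matrix.
#' @param sites site table with `position_bp`.
#' @param core_idx core site column.
#' @param core_allele 0 or 1.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @param max_steps number of sites to walk.
#' @return list with `nodes` (data frame: `depth`, `site`, `node_id`,
#'   `parent_id`, `n_carriers`, `rendered`) and `n_carriers` at the core.
#' @export
furcation <- function(haps, sites, core_idx, core_allele,
                      direction = c("right", "left"), max_steps = 20L) {
  direction <- match.arg(direction)
  carriers <- which(haps[, core_idx] == core_allele)
  n_c <- length(carriers)
  if (n_c < 2) stop("fewer than 2 carriers of the core allele")
  step <- if (direction == "right") 1L else -1L
  path <- seq(core_idx + step, by = step,
              length.out = min(max_steps,
                               if (step > 0) ncol(haps) - core_idx
                               else core_idx - 1L))
  nodes <- data.frame(depth = 0L, site = core_idx, node_id = 1L,
                      parent_id = NA_integer_, n_carriers = n_c,
                      rendered = n_c > 1)
  grp <- rep(1L, n_c)
  next_id <- 2L
  for (k in seq_along(path)) {
    t <- path[k]
    new_grp <- integer(n_c)
    for (g in unique(grp)) {
      members <- which(grp == g)
      alleles <- haps[carriers[members], t]
      for (a in unique(alleles)) {
        sub <- members[alleles == a]
        new_grp[sub] <- next_id
        nodes <- rbind(nodes, data.frame(
          depth = k, site = t, node_id = next_id, parent_id = g,
          n_carriers = length(sub), rendered = length(sub) > 1))
        next_id <- next_id + 1L
      }
    }
    grp <- new_grp
  }
  list(nodes = nodes, n_carriers = n_c)
}
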