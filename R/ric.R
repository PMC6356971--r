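#' Refined instance-cluster association matrix
#'
#' Fills the zero entries of the binary instance-cluster matrix with
#' normalized cluster similarity. Within each base clustering's block of
#' columns, an instance's own cluster keeps association 1; every other
#' cluster C gets
#' `sim(C, C*) / sum_{C' != C*, C' in same clustering} sim(C', C*) * dc`,
#' where C* is the instance's cluster in that clustering. Normalization is
#' strictly per clustering; similarity mass never crosses blocks.
#'
#' With the default `dc = 1` the non-member entries of each block sum to 1.
#' In a 2-cluster block this makes the single non-member entry equal to the
#' member entry — kept for fidelity to the definition. A 1-cluster block has
#' no non-members and stays at its single 1.
#'
#' @param ic Binary instance-cluster matrix from [pool_to_ic()].
#' @param sim Cluster-cluster similarity from [kernel_similarity()].
#' @param dc Total association mass given to non-member clusters (> 0).
#' @param sim_floor Similarities below this tolerance are treated as absent
#'   links. Normalizing a similarity mass that is numerically negligible
#'   would inflate the ratio of near-zero values into the full dc mass on an
#'   arbitrary cluster; below the floor the hidden associations stay 0, the
#'   same behavior as the exact zero-denominator guard.
#' @return An n x K_total matrix with entries in `[0, 1]`, same dimnames and
#'   `blocks` attribute as `ic`.
#' @export
build_ric <- function(ic, sim, dc = 1, sim_floor = 1e-8) {
  if (dc <= 0) stop("dc must be > 0", call. = FALSE)
  blocks <- attr(ic, "blocks")
  if (is.null(blocks)) stop("ic must carry a 'blocks' attribute (use pool_to_ic())",
                            call. = FALSE)
  if (nrow(sim) != ncol(ic)) stop("sim dimension must match ic columns", call. = FALSE)
  ric <- matrix(0, nrow(ic), ncol(ic))
  for (idx in blocks) {
    k_m <- length(idx)
    if (k_m == 1) {                       # degenerate single-cluster block
      ric[, idx] <- ic[, idx]
      next
    }
    s_b <- sim[idx, idx, drop = FALSE]
    for (j in seq_len(k_m)) {
      members <- which(ic[, idx[j]] == 1)
      if (length(members) == 0) next
      w <- s_b[, j]
      w[j] <- 0
      w[w < sim_floor] <- 0
      tot <- sum(w)
      vals <- if (tot > 0) w / tot * dc else rep(0, k_m)
      vals[j] <- 1
      ric[members, idx] <- matrix(vals, length(members), k_m, byrow = TRUE)
    }
  }
  ric <- pmin(pmax(ric, 0), 1)
  restore_ic_attrs(ric, ic)
}
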