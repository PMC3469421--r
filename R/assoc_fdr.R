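#' Decay-expression association with permutation FDR
#'
#' Runs [decayExpressionAssociation()] on the observed data and on
#' `nPerms` copies in which the individual labels of the decay matrix
#' are shuffled (one shuffle per permutation, shared across genes so
#' gene-gene correlation is preserved).  The pooled permuted p-values
#' form the empirical null for [permutationFdr()].
#'
#' @param steadyState,decay matched genes x individuals matrices.
#' @param nPerms permutations (default 3).
#' @param seed RNG seed.
#' @param targetFdr FDR level for significance calls (default 0.10).
#' @return the association data.frame with columns `q` and
#'   `significant` appended; the pooled null p-values are in attribute
#'   `"nullP"`.
#' @export
associationFdr <- function(steadyState, decay, nPerms = 3L, seed = 1L,
                           targetFdr = 0.10) {
  obs <- decayExpressionAssociation(steadyState, decay)
  N <- ncol(decay)
  set.seed(as.integer(seed))
  nullP <- unlist(lapply(seq_len(nPerms), function(b) {
    decayExpressionAssociation(steadyState,
                               decay[, sample.int(N), drop = FALSE])$p
  }))
  fdr <- permutationFdr(obs$p, nullP, nPerms, targetFdr = targetFdr)
  obs$q <- fdr$q
  obs$significant <- fdr$significant
  attr(obs, "nullP") <- nullP
  obs
}
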