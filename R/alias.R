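# Walker alias method: constant-time sampling from an arbitrary finite
# discrete distribution after O(M) setup.

#' Build an alias table
#'
#' @param weights Nonnegative weights, at least one positive.
#' @return An object of class `alias_table`: `prob` (acceptance probability
#'   per slot), `alias` (alternative outcome per slot), `p_norm` (exact
#'   normalized weights), `total` (sum of weights).
#' @export
build_alias <- function(weights) {
  m <- length(weights)
  if (any(weights < 0)) stop("build_alias: negative weight")
  tot <- sum(weights)
  if (tot <= 0) stop("build_alias: all weights are zero")
  p <- weights / tot * m
  prob <- numeric(m); alias <- integer(m)
  small <- which(p < 1); large <- which(p >= 1)
  ns <- length(small); nl <- length(large)
  while (ns > 0 && nl > 0) {
    s <- small[ns]; l <- large[nl]
    prob[s] <- p[s]; alias[s] <- l
    p[l] <- p[l] - (1 - p[s])
    ns <- ns - 1L
    if (p[l] < 1) {
      nl <- nl - 1L
      ns <- ns + 1L
      small[ns] <- l
    }
  }
  prob[large[seq_len(nl)]] <- 1
  alias[large[seq_len(nl)]] <- large[seq_len(nl)]
  prob[small[seq_len(ns)]] <- 1
  alias[small[seq_len(ns)]] <- small[seq_len(ns)]
  structure(list(prob = prob, alias = alias,
                 p_norm = weights / tot, total = tot),
            class = "alias_table")
}

#' Sample outcomes from an alias table
#'
#' @param table An [build_alias()] result.
#' @param n Number of draws.
#' @return Integer vector of outcomes in `1:length(weights)`, distributed
#'   exactly proportionally to the input weights.
#' @export
alias_sample <- function(table, n = 1L) {
  m <- length(table$prob)
  slot <- 1L + as.integer(floor(stats::runif(n) * m))
  take <- stats::runif(n) < table$prob[slot]
  ifelse(take, slot, table$alias[slot])
}
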