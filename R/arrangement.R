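# The published 42-element arrangement for the 10-channel wristband. Note:
# it does NOT make every channel pair adjacent — pairs (2,7), (3,8), (4,9)
# and (5,10) never occur side by side. It is reproduced verbatim as a
# fixture; use mode = "pair_complete" for a genuinely pair-complete
# arrangement.
.FIXTURE_10 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 1, 3, 5, 7, 9, 1, 4, 6, 8,
                 10, 2, 4, 7, 10, 3, 6, 9, 2, 5, 8, 1, 5, 9, 3, 7, 1, 6,
                 10, 4, 8, 2, 6)
.FIXTURE_3 <- c(1, 2, 3, 1)

#' Build a channel arrangement
#'
#' An arrangement is the ordered, repeating sequence of channel indices that
#' defines the columns of the expanded signal array (and hence of the
#' movement image). Three modes:
#' \describe{
#'   \item{\code{paper_fixture}}{the published sequences, verbatim:
#'     \code{[1,2,3,1]} for N = 3 (M = 4) and the 42-element sequence for
#'     N = 10 (M = 42). Only these two N are defined. The N = 10 fixture
#'     leaves four channel pairs non-adjacent — (2,7), (3,8), (4,9),
#'     (5,10) — a documented property of the published sequence.}
#'   \item{\code{pair_complete}}{a sequence in which every unordered channel
#'     pair occurs adjacently at least once, built as an Eulerian path on
#'     the complete graph K_N with minimal edge duplication ((N-2)/2 extra
#'     edges when N is even, none when N is odd). Deterministic for fixed
#'     N; length C(N,2) + 1 for odd N and C(N,2) + (N-2)/2 + 1 for even N
#'     (so 8 for N = 4, the provable minimum).}
#'   \item{\code{identity}}{the channels in raw order, M = N (used by the
#'     no-augmentation CNN and the GRU).}
#' }
#'
#' @param nChannels N, the number of source channels (>= 2).
#' @param mode construction mode, see above.
#' @return a [ChannelArrangement-class].
#' @examples
#' buildArrangement(3, "paper_fixture")   # [1, 2, 3, 1]
#' length(buildArrangement(4, "pair_complete"))  # 8
#' @export
buildArrangement <- function(nChannels,
                             mode = c("pair_complete", "paper_fixture",
                                      "identity")) {
  mode <- match.arg(mode)
  n <- as.integer(nChannels)
  if (n < 2L && mode != "identity")
    stop("nChannels must be >= 2 (identity arrangements allow N = 1)")
  if (n < 1L) stop("nChannels must be >= 1")
  ch <- switch(mode,
    paper_fixture = {
      if (n == 3L) .FIXTURE_3
      else if (n == 10L) .FIXTURE_10
      else stop("unsupported fixture: paper_fixture is defined for N = 3 or 10")
    },
    pair_complete = .eulerianArrangement(n),
    identity = seq_len(n))
  new("ChannelArrangement", channels = as.integer(ch),
      nChannels = n, mode = mode)
}

# Eulerian path over K_N plus, for even N, (N-2)/2 duplicated edges pairing
# off all odd-degree vertices except 1 and 2 (duplicates (3,4), (5,6), ...).
# Hierholzer's algorithm with smallest-neighbour tie-break -> deterministic.
.eulerianArrangement <- function(n) {
  if (n == 2L) return(c(1L, 2L))
  adj <- matrix(0L, n, n)  # multi-edge counts
  adj[upper.tri(adj)] <- 1L
  adj <- adj + t(adj)
  if (n %% 2L == 0L && n > 2L) {
    for (v in seq(3L, n - 1L, by = 2L)) {
      adj[v, v + 1L] <- adj[v, v + 1L] + 1L
      adj[v + 1L, v] <- adj[v + 1L, v] + 1L
    }
  }
  start <- 1L
  stack <- c(start)
  path <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    nb <- which(adj[v, ] > 0L)
    if (length(nb)) {
      u <- nb[1L]
      adj[v, u] <- adj[v, u] - 1L
      adj[u, v] <- adj[u, v] - 1L
      stack <- c(stack, u)
    } else {
      path <- c(path, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(path)
}

#' Check which channel pairs are adjacent in an arrangement
#'
#' @param arr a [ChannelArrangement-class].
#' @return logical N x N matrix; entry (i, j) is TRUE when channels i and j
#'   occur in adjacent columns somewhere in the arrangement.
#' @export
adjacentPairs <- function(arr) {
  n <- nChannels(arr)
  ch <- channels(arr)
  adj <- matrix(FALSE, n, n)
  if (length(ch) >= 2) {
    a <- ch[-length(ch)]
    b <- ch[-1]
    adj[cbind(a, b)] <- TRUE
    adj[cbind(b, a)] <- TRUE
  }
  diag(adj) <- TRUE
  adj
}

#' Expand a signal array along an arrangement
#'
#' Column j of the output is a copy of input column
#' \code{channels(arrangement)[j]}; rows (time) are untouched. The expansion
#' is lossless: the original array is recovered by taking the first
#' occurrence of each channel.
#'
#' @param pressures L x N signal matrix.
#' @param arrangement a [ChannelArrangement-class] with
#'   \code{nChannels(arrangement) == ncol(pressures)}.
#' @return L x M expanded matrix, M = \code{length(arrangement)}.
#' @export
expandSignals <- function(pressures, arrangement) {
  if (ncol(pressures) != nChannels(arrangement))
    stop("shape error: arrangement expects ", nChannels(arrangement),
         " channels, got ", ncol(pressures))
  out <- pressures[, channels(arrangement), drop = FALSE]
  colnames(out) <- NULL
  out
}
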