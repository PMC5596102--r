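#' Minimal positive-feedback cover of a strategy
#'
#' The smallest number of target paths whose positive-feedback exposures
#' complete a strategy's knowledge of the BDT, found by brute-force subset
#' search over the `2^depth` root-to-leaf paths in increasing subset size.
#' A rewarded path reveals, under the spatial strategy, the path itself
#' (every one of the 16 paths must be seen); under the generative strategy,
#' the icons clicked along it (all 16 icons must be revealed); under the
#' discriminative strategy, each clicked icon together with its on-screen
#' complement (one rewarded click per choice context suffices). At depth 4
#' the covers are 16, 8 and 4 paths respectively; the random strategy has
#' no knowledge to complete.
#'
#' @param kind `"spatial"`, `"generative"` or `"discriminative"`.
#' @param interface A [build_interface()] object.
#' @return The minimal cover size (integer).
#' @export
#' @examples
#' iface <- build_interface(seed = 1)
#' minimal_positive_cover("discriminative", iface)   # 4
minimal_positive_cover <- function(kind, interface) {
  kind <- match.arg(kind, c("spatial", "generative", "discriminative"))
  stopifnot(inherits(interface, "bdt_interface"))
  paths <- all_paths(interface$depth)
  npaths <- length(paths)

  # universe of items to reveal, as bit positions
  if (kind == "spatial") {
    items <- paths                         # each path reveals its own leaf
  } else {
    items <- unique(unname(interface$icon_of))
  }
  if (length(items) > 30L) stopf("bitmask cover search supports at most 30 items")
  full_mask <- sum(2^(seq_along(items) - 1L))

  reveal <- function(path) {
    if (kind == "spatial") return(path)
    icons <- unname(interface$icon_of[path_locations(path)])
    if (kind == "discriminative") {
      icons <- unique(c(icons, vapply(icons, icon_complement, character(1))))
    }
    icons
  }
  path_mask <- vapply(paths, function(p) {
    sum(2^(match(reveal(p), items) - 1L))
  }, numeric(1))

  for (k in seq_len(npaths)) {
    combos <- utils::combn(npaths, k)
    cover <- rep(0, ncol(combos))
    for (r in seq_len(k)) {
      cover <- bitwOr(as.integer(cover), as.integer(path_mask[combos[r, ]]))
    }
    if (any(cover == full_mask)) return(k)
  }
  npaths
}
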